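#' Amsler grid specification
#'
#' Geometry of the conceptual Amsler grid used for self-assessment and as the
#' coordinate frame for exercise stimuli. The default is the clinical standard:
#' a 10 x 10 cm grid of lines spaced 5 mm apart viewed at 30 cm, so that each
#' square subtends approximately one degree of visual angle. The origin of the
#' coordinate system is the central fixation point; x grows rightward and y
#' upward on the display.
#'
#' @param width_cm,height_cm grid extent in cm (positive)
#' @param spacing_cm line spacing in cm; must divide both dimensions exactly
#' @param working_distance_cm eye-to-screen distance in cm
#' @param diagonal_lines draw diagonal guide lines (revised design variant)
#' @param thick_center thicker central fixation point (revised design variant)
#' @return an object of class `grid_spec`
#' @examples
#' g <- grid_spec()
#' g$n_cols # 20 one-degree cells per axis
#' @export
grid_spec <- function(width_cm = 10, height_cm = 10, spacing_cm = 0.5,
                      working_distance_cm = 30, diagonal_lines = FALSE,
                      thick_center = FALSE) {
  if (width_cm <= 0 || height_cm <= 0 || spacing_cm <= 0 || working_distance_cm <= 0) {
    stop_rehab("grid dimensions, spacing and working distance must be positive",
               "eyerehab_domain_error")
  }
  for (d in c(width_cm, height_cm)) {
    r <- d / spacing_cm
    if (abs(r - round(r)) > 1e-9) {
      stop_rehab("spacing_cm must divide width_cm and height_cm exactly",
                 "eyerehab_domain_error")
    }
  }
  structure(
    list(
      width_cm = width_cm, height_cm = height_cm, spacing_cm = spacing_cm,
      working_distance_cm = working_distance_cm,
      diagonal_lines = isTRUE(diagonal_lines), thick_center = isTRUE(thick_center),
      n_cols = as.integer(round(width_cm / spacing_cm)),
      n_rows = as.integer(round(height_cm / spacing_cm))
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Amsler grid: %g x %g cm, %g mm spacing (%d x %d cells) at %g cm\n",
              x$width_cm, x$height_cm, x$spacing_cm * 10, x$n_rows, x$n_cols,
              x$working_distance_cm))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$width_cm, b$width_cm)) &&
    isTRUE(all.equal(a$height_cm, b$height_cm)) &&
    isTRUE(all.equal(a$spacing_cm, b$spacing_cm))
}

#' Cell centers of a grid
#'
#' Cell indices are 0-based `(row, col)` from the top-left corner; positions
#' are centimetre offsets from the fixation point at the grid center.
#'
#' @param grid a [grid_spec()]
#' @return data.frame with columns `row`, `col`, `x_cm`, `y_cm`
#' @export
cell_centers <- function(grid) {
  g <- expand.grid(col = seq_len(grid$n_cols) - 1L, row = seq_len(grid$n_rows) - 1L)
  data.frame(
    row = g$row, col = g$col,
    x_cm = -grid$width_cm / 2 + (g$col + 0.5) * grid$spacing_cm,
    y_cm = grid$height_cm / 2 - (g$row + 0.5) * grid$spacing_cm
  )
}

# Map a centered-cm point to its 0-based (row, col) cell.
point_to_cell <- function(grid, x_cm, y_cm) {
  col <- floor((x_cm + grid$width_cm / 2) / grid$spacing_cm)
  row <- floor((grid$height_cm / 2 - y_cm) / grid$spacing_cm)
  data.frame(
    row = pmin(pmax(as.integer(row), 0L), grid$n_rows - 1L),
    col = pmin(pmax(as.integer(col), 0L), grid$n_cols - 1L)
  )
}

in_grid <- function(grid, x_cm, y_cm) {
  abs(x_cm) <= grid$width_cm / 2 + 1e-9 & abs(y_cm) <= grid$height_cm / 2 + 1e-9
}

#' Convert a centimetre offset to visual angle
#'
#' Uses the inverse tangent of offset over viewing distance, applied per
#' component, so a 0.5 cm grid square at the default 30 cm distance subtends
#' 0.955 degrees (the conventional "one degree per square").
#'
#' @param offset_cm offset from fixation in cm (vectorized; signed)
#' @param distance_cm viewing distance in cm (positive)
#' @return visual angle in degrees, same sign as `offset_cm`
#' @examples
#' round(cm_to_deg(0.5, 30)) # 1 degree per square
#' @export
cm_to_deg <- function(offset_cm, distance_cm) {
  if (any(distance_cm <= 0)) {
    stop_rehab("viewing distance must be positive", "eyerehab_domain_error")
  }
  atan(offset_cm / distance_cm) * 180 / pi
}

#' Convert a visual angle to a centimetre offset
#'
#' Exact inverse of [cm_to_deg()]; only defined for angles strictly inside
#' (-90, 90) degrees.
#'
#' @param angle_deg visual angle in degrees
#' @param distance_cm viewing distance in cm (positive)
#' @return offset from fixation in cm
#' @export
deg_to_cm <- function(angle_deg, distance_cm) {
  if (any(distance_cm <= 0)) {
    stop_rehab("viewing distance must be positive", "eyerehab_domain_error")
  }
  if (any(abs(angle_deg) >= 90)) {
    stop_rehab("angle must lie strictly inside (-90, 90) degrees",
               "eyerehab_domain_error")
  }
  tan(angle_deg * pi / 180) * distance_cm
}

#' Check whether a screen can host the grid test or the exercises
#'
#' The full-grid self-assessment needs a screen at least as large as the grid;
#' exercises run on any screen, but stimulus positions stay in absolute
#' centimetres (they are not rescaled on narrow devices, so the retinal
#' projection is preserved as long as the working distance is kept).
#'
#' @param screen_width_cm,screen_height_cm physical screen size in cm
#' @param mode `"test"` (full grid must fit) or `"exercise"`
#' @param grid the reference [grid_spec()]
#' @return list with `eligible` (logical), `reasons` (character),
#'   `absolute_positions` (logical flag for undersized exercise screens)
#' @export
validate_screen <- function(screen_width_cm, screen_height_cm,
                            mode = c("test", "exercise"), grid = grid_spec()) {
  mode <- match.arg(mode)
  if (screen_width_cm <= 0 || screen_height_cm <= 0) {
    stop_rehab("screen dimensions must be positive", "eyerehab_domain_error")
  }
  reasons <- character()
  fits <- screen_width_cm >= grid$width_cm && screen_height_cm >= grid$height_cm
  eligible <- TRUE
  if (mode == "test" && !fits) {
    eligible <- FALSE
    reasons <- c(reasons, "grid does not fit")
  }
  absolute <- mode == "exercise" && !fits
  if (absolute) {
    reasons <- c(reasons,
                 "stimulus positions kept in absolute cm; keep working distance constant")
  }
  list(eligible = eligible, mode = mode, reasons = reasons,
       absolute_positions = absolute)
}

#' Treatment area (trained peripheral retinal zone)
#'
#' The practitioner-entered location of the peripheral retinal area to train
#' (the candidate preferred retinal locus), expressed as a centred offset in cm
#' from the fixation point. Exercise stimuli are projected at this offset from
#' the active fixation point.
#'
#' @param x_cm,y_cm center of the area relative to fixation (cm)
#' @param extent_cm radius of the trained zone in cm
#' @param entered_by role identifier of who entered the coordinates
#' @return an object of class `treatment_area`
#' @export
treatment_area <- function(x_cm, y_cm, extent_cm = 1, entered_by = "practitioner") {
  if (!is.numeric(x_cm) || !is.numeric(y_cm) || extent_cm <= 0) {
    stop_rehab("treatment area needs numeric coordinates and positive extent",
               "eyerehab_domain_error")
  }
  structure(list(x_cm = x_cm, y_cm = y_cm, extent_cm = extent_cm,
                 entered_by = entered_by),
            class = "treatment_area")
}
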