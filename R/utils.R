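#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp01 <- function(x) pmin(1, pmax(0, x))

cell_key <- function(row, col) sprintf("r%d_c%d", row, col)

#' Signal a classed package error
#'
#' All domain errors raised by the engine carry a subclass of `eyerehab_error`
#' so callers (and the CLI) can map failure modes to exit codes.
#'
#' @param msg message text
#' @param class specific condition class, e.g. `"eyerehab_permission_error"`
#' @noRd
stop_rehab <- function(msg, class = "eyerehab_error") {
  cond <- structure(
    class = c(class, "eyerehab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Combine two small seeds into one 32-bit seed (Lehmer-style mix); keeps
# derived seeds strictly below 2^31 - 1.
combine_seeds <- function(a, b) {
  as.integer((as.numeric(a) * 48271 + as.numeric(b)) %% 2147483646) + 1L
}

#' Jaccard index between two sets
#'
#' Similarity between two sets given as character vectors (duplicates ignored).
#' Returns 1 when both sets are empty.
#'
#' @param a,b character vectors of set members
#' @return numeric scalar in \[0, 1\]
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}
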