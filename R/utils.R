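#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# column names carrying coordinates, in order, present in a track-like tibble
coord_cols <- function(df) {
  cols <- intersect(c("x", "y", "z"), names(df))
  if ("z" %in% cols && all(is.na(df$z))) cols <- setdiff(cols, "z")
  cols
}

coord_matrix <- function(df) {
  as.matrix(df[coord_cols(df)])
}

vec_norm <- function(m) {
  if (is.null(dim(m))) sqrt(sum(m^2)) else sqrt(rowSums(m^2))
}

# step lengths of an ordered coordinate matrix
step_lengths <- function(m) {
  if (nrow(m) < 2) return(numeric(0))
  vec_norm(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
}

# angle between rows of two matrices of vectors, in [0, pi]; NA where either
# vector has zero length
angle_between <- function(a, b) {
  na <- vec_norm(a); nb <- vec_norm(b)
  dp <- rowSums(a * b)
  out <- acos(pmin(1, pmax(-1, dp / (na * nb))))
  out[na == 0 | nb == 0] <- NA_real_
  out
}

# uniform-sampling check used by MSD-type operations
assert_uniform_dt <- function(t, tol = 1e-6, what = "track") {
  dt <- diff(t)
  if (length(dt) == 0) abort(sprintf("%s has fewer than 2 frames", what))
  if (any(dt <= 0)) abort(sprintf("%s has non-increasing time stamps", what))
  if (diff(range(dt)) > tol * max(dt)) {
    abort(sprintf(
      "%s is not uniformly sampled (frame intervals range %.6g-%.6g min); resample before calling",
      what, min(dt), max(dt)
    ))
  }
  dt[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
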