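#' Mean migration speed per track
#'
#' Speed is the cumulative path length (the sum of per-step Euclidean
#' displacements, i.e. total displacement *along* the track, not the net
#' start-to-end displacement) divided by total tracking time. An out-and-back
#' excursion therefore has non-zero mean speed even though it returns to its
#' origin.
#'
#' @param tracks A track table ([as_tracks()] layout).
#' @return A tibble with one row per object: `object_id`, `speed_um_min`,
#'   `speed_um_s`, `path_length_um`, `duration_min`.
#' @examples
#' tr <- data.frame(object_id = "a", t = 0:10, x = 0:10, y = 0)
#' mean_speed(tr) # 1 um/min
#' @export
mean_speed <- function(tracks) {
  tracks <- as_tracks(tracks)
  one <- function(df) {
    if (nrow(df) < 2) {
      abort(paste0("undefined speed: track ", df$object_id[1], " has a single frame"))
    }
    path <- sum(step_lengths(coord_matrix(df)))
    dur <- df$t[nrow(df)] - df$t[1]
    tibble(path_length_um = path, duration_min = dur,
           speed_um_min = path / dur, speed_um_s = path / dur / 60)
  }
  tracks %>%
    dplyr::group_by(.data$object_id) %>%
    dplyr::group_modify(~ one(dplyr::bind_cols(tibble(object_id = .y$object_id), .x))) %>%
    dplyr::ungroup() %>%
    dplyr::select("object_id", "speed_um_min", "speed_um_s",
                  "path_length_um", "duration_min")
}

# xi(n) for one coordinate matrix: time-averaged MSD over all window
# placements, xi(n) = mean over i of |x_{i+n} - x_i|^2, n = 1..N steps
msd_one <- function(m, n_max = NULL) {
  n_frames <- nrow(m)
  N <- n_frames - 1
  n_top <- min(N, n_max %||% N)
  xi <- numeric(n_top)
  for (n in seq_len(n_top)) {
    d <- m[(1 + n):n_frames, , drop = FALSE] - m[1:(n_frames - n), , drop = FALSE]
    xi[n] <- sum(d * d) / (N - n + 1)
  }
  tibble(n = seq_len(n_top), xi = xi)
}

#' Mean-square-displacement curve
#'
#' For a uniformly sampled track with N steps, the time-averaged mean square
#' displacement at integer step size n is
#' \deqn{\xi(n) = \frac{1}{N-n+1} \sum_{i=0}^{N-n} \|x_{i+n} - x_i\|^2,}
#' a measure of the area or volume a cell explores within a lag of n frames.
#' All integer n in 1..N are computed unless `n_max` restricts the range
#' (large-n estimates average few displacement pairs and are noisy).
#'
#' @param tracks A track table; each track must be uniformly sampled (constant
#'   frame interval to relative tolerance 1e-6). Irregularly sampled tracks
#'   are rejected with advice to resample.
#' @param n_max Optional largest step size to evaluate.
#' @return A tibble `object_id, n, xi` (xi in um^2), class `effero_msd`.
#' @export
msd <- function(tracks, n_max = NULL) {
  tracks <- as_tracks(tracks)
  out <- tracks %>%
    dplyr::group_by(.data$object_id) %>%
    dplyr::group_modify(function(df, key) {
      assert_uniform_dt(df$t, what = paste0("track ", key$object_id))
      msd_one(coord_matrix(df), n_max = n_max)
    }) %>%
    dplyr::ungroup()
  class(out) <- c("effero_msd", class(out))
  out
}

#' Anomalous-diffusion exponent from an MSD curve
#'
#' Ordinary least-squares slope of log xi(n) against log n: the MSD exponent
#' alpha. Points with xi(n) = 0 are excluded (log undefined); the default fit
#' uses every remaining step size, matching the convention of fitting over all
#' integer n, and `n_range` restricts it (e.g. `c(1, N/4)`) when the noisy
#' large-n tail should be ignored.
#'
#' @param msd_result Output of [msd()].
#' @param n_range Optional `c(lo, hi)` bounds on the step sizes used.
#' @return A tibble per object: `object_id`, `alpha`, `intercept`,
#'   `r_squared`, `n_used`.
#' @export
msd_alpha <- function(msd_result, n_range = NULL) {
  one <- function(df, key) {
    use <- df$xi > 0
    if (!is.null(n_range)) use <- use & df$n >= n_range[1] & df$n <= n_range[2]
    if (!any(df$xi > 0)) {
      abort(paste0("degenerate track ", key$object_id, ": all xi(n) = 0"))
    }
    if (sum(use) < 2) {
      abort(paste0("fewer than 2 usable MSD points for object ", key$object_id))
    }
    fit <- stats::lm.fit(cbind(1, log(df$n[use])), log(df$xi[use]))
    res <- fit$residuals
    y <- log(df$xi[use])
    r2 <- if (stats::var(y) == 0) 1 else 1 - sum(res^2) / sum((y - mean(y))^2)
    tibble(alpha = unname(fit$coefficients[2]),
           intercept = unname(fit$coefficients[1]),
           r_squared = r2, n_used = sum(use))
  }
  as_tibble(msd_result) %>%
    dplyr::group_by(.data$object_id) %>%
    dplyr::group_modify(one) %>%
    dplyr::ungroup()
}

#' Classify a migration regime from the MSD exponent
#'
#' Standard single-particle-tracking convention: alpha around 1 is ordinary
#' diffusion (random walk), alpha below 1 subdiffusion (spatially constrained
#' motion), 1 < alpha < 2 superdiffusion (diffusion plus directed movement)
#' and alpha = 2 ballistic (straight tracks). A half-width `epsilon` band
#' around the point thresholds 1 and 2 avoids knife-edge classification of
#' estimated exponents.
#'
#' @param alpha Numeric vector of MSD exponents; must be finite.
#' @param epsilon Band half-width around the thresholds (default 0.1).
#' @return Character vector: `subdiffusive`, `diffusive`, `superdiffusive` or
#'   `ballistic`.
#' @export
classify_regime <- function(alpha, epsilon = 0.1) {
  if (any(!is.finite(alpha))) abort("alpha must be finite")
  dplyr::case_when(
    alpha < 1 - epsilon ~ "subdiffusive",
    alpha <= 1 + epsilon ~ "diffusive",
    alpha < 2 - epsilon ~ "superdiffusive",
    TRUE ~ "ballistic"
  )
}

#' Fit MSD exponents for a set of tracks
#'
#' Convenience wrapper running [msd()], [msd_alpha()] and [classify_regime()]
#' in one step and keeping curve and fits together for plotting and
#' broom-style summaries ([generics::tidy()], [generics::glance()],
#' [ggplot2::autoplot()]).
#'
#' @inheritParams msd
#' @inheritParams msd_alpha
#' @inheritParams classify_regime
#' @return An object of class `msd_fit`.
#' @export
fit_msd <- function(tracks, n_max = NULL, n_range = NULL, epsilon = 0.1) {
  curve <- msd(tracks, n_max = n_max)
  fits <- msd_alpha(curve, n_range = n_range)
  fits$regime <- classify_regime(fits$alpha, epsilon = epsilon)
  structure(list(curve = curve, fits = fits, n_range = n_range,
                 epsilon = epsilon),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat("<msd_fit> ", nrow(x$fits), " tracks, median alpha = ",
      signif(stats::median(x$fits$alpha), 3), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_msd
#' @param x An `msd_fit` object.
#' @param ... Unused.
#' @export
tidy.msd_fit <- function(x, ...) x$fits

#' @rdname fit_msd
#' @export
glance.msd_fit <- function(x, ...) {
  tibble(
    n_tracks = nrow(x$fits),
    median_alpha = stats::median(x$fits$alpha),
    mean_alpha = mean(x$fits$alpha),
    sd_alpha = stats::sd(x$fits$alpha),
    median_r_squared = stats::median(x$fits$r_squared)
  )
}
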