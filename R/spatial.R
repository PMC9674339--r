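#' Nearest-neighbour distances in a point set
#'
#' For each point, the Euclidean distance to its closest other point
#' (first-nearest-neighbour, k = 1). Used e.g. for microglia spacing in the
#' optic tectum. Duplicate coordinates are allowed and yield distance 0.
#' Distances are computed from the full pairwise distance matrix
#' ([stats::dist()]), which is vectorised and adequate at tissue scale
#' (hundreds of cells).
#'
#' @param points Data frame with columns `x, y[, z]` (um); optional `label`
#'   column is carried through.
#' @return A tibble with the input columns plus `nn_distance_um` and
#'   `nn_index` (row index of the nearest neighbour).
#' @examples
#' nearest_neighbour_distances(data.frame(x = c(0, 30), y = 0))
#' @export
nearest_neighbour_distances <- function(points) {
  points <- as_tibble(points)
  n <- nrow(points)
  if (n < 2) abort("need at least 2 points for a nearest-neighbour search")
  m <- coord_matrix(points)
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  nn_index <- apply(d, 1, which.min)
  points$nn_distance_um <- d[cbind(seq_len(n), nn_index)]
  points$nn_index <- as.integer(nn_index)
  points
}

#' Consecutive successful-event pair table
#'
#' Within each cell, successful events are sorted by onset time and each
#' consecutive pair contributes one row: the waiting time `dt_min` between
#' the two engulfments and the spatial separation `dd_um` of the two
#' engulfment positions. Only consecutive pairs are formed (3 successes give
#' 2 rows), and cells with fewer than 2 successes contribute nothing.
#'
#' By default positions are expressed relative to the microglia before
#' differencing: the cell-centre position at each event time is subtracted,
#' so `dd_um` measures how far apart the two targets were *as seen from the
#' cell*. Set `relative_to_cell = FALSE` for the raw tissue-frame separation.
#'
#' @param events Event table.
#' @param dataset Optional [effero_dataset()] providing centre tracks
#'   (required when `relative_to_cell = TRUE`).
#' @param relative_to_cell Subtract the cell-centre position at each event
#'   time (default `TRUE`).
#' @return A tibble `cell_id, event_id_1, event_id_2, t1, t2, dt_min, dd_um`,
#'   ordered by cell then time.
#' @export
event_pair_table <- function(events, dataset = NULL, relative_to_cell = TRUE) {
  events <- as_events(events)
  succ <- events[events$outcome == "successful", ]
  if (relative_to_cell && is.null(dataset)) {
    abort("relative_to_cell = TRUE requires a dataset with centre tracks")
  }
  one_cell <- function(df) {
    df <- df[order(df$t_onset), ]
    if (nrow(df) < 2) return(NULL)
    pos <- as.matrix(df[coord_cols(df)])
    if (relative_to_cell) {
      cc <- cell_track(dataset, df$cell_id[1], "centre")
      if (nrow(cc) == 0) abort(paste0("no centre track for cell ", df$cell_id[1]))
      cc_m <- coord_matrix(cc)
      at <- vapply(df$t_onset, function(tt) which.min(abs(cc$t - tt)), 1L)
      pos <- pos - cc_m[at, , drop = FALSE]
    }
    i <- seq_len(nrow(df) - 1)
    tibble(
      cell_id = df$cell_id[1],
      event_id_1 = df$event_id[i], event_id_2 = df$event_id[i + 1],
      t1 = df$t_onset[i], t2 = df$t_onset[i + 1],
      dt_min = diff(df$t_onset),
      dd_um = vec_norm(pos[i + 1, , drop = FALSE] - pos[i, , drop = FALSE])
    )
  }
  out <- succ %>%
    dplyr::group_split(.data$cell_id) %>%
    lapply(one_cell) %>%
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(cell_id = character(), event_id_1 = character(),
                  event_id_2 = character(), t1 = numeric(), t2 = numeric(),
                  dt_min = numeric(), dd_um = numeric())
  }
  out
}

#' Spatiotemporal correlation of sequential engulfments
#'
#' Ordinary least-squares regression of the waiting time between consecutive
#' successful engulfments (`dt_min`) on their spatial separation (`dd_um`),
#' with the Pearson correlation and a pointwise 95% confidence band for the
#' mean response. The causal orientation (time delay explained by distance)
#' reflects the hypothesis that repolarising toward a farther target takes
#' longer. Fits are reported pooled over cells and, when several cells
#' contribute enough pairs, per cell.
#'
#' @param pair_table Output of [event_pair_table()]; at least 3 rows.
#' @param conf_level Confidence level for the band (default 0.95).
#' @return An object of class `spacetime_fit` with elements `model` (the
#'   pooled [stats::lm()] fit), `slope`, `intercept`, `r`, `band` (tibble
#'   `dd_um, fit, lwr, upr`), `per_cell` (tibble of per-cell fits) and
#'   `pairs`. Has [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
spacetime_correlation <- function(pair_table, conf_level = 0.95) {
  if (nrow(pair_table) < 3) abort("need at least 3 event pairs")
  if (stats::var(pair_table$dd_um) == 0) {
    abort("zero variance in spatial separation; regression undefined")
  }
  fit <- stats::lm(dt_min ~ dd_um, data = pair_table)
  grid <- tibble(dd_um = seq(min(pair_table$dd_um), max(pair_table$dd_um),
                             length.out = 100))
  band <- cbind(grid, as_tibble(stats::predict(fit, newdata = grid,
                                               interval = "confidence",
                                               level = conf_level)))
  per_cell <- pair_table %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::filter(dplyr::n() >= 3, stats::var(.data$dd_um) > 0) %>%
    dplyr::summarise(
      slope = stats::coef(stats::lm(dt_min ~ dd_um,
                                    data = dplyr::pick("dt_min", "dd_um")))[2],
      r = stats::cor(.data$dd_um, .data$dt_min),
      n_pairs = dplyr::n(), .groups = "drop"
    )
  structure(
    list(model = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = stats::cor(pair_table$dd_um, pair_table$dt_min),
         band = as_tibble(band), per_cell = per_cell,
         pairs = pair_table, conf_level = conf_level),
    class = "spacetime_fit"
  )
}

#' @export
print.spacetime_fit <- function(x, ...) {
  cat("<spacetime_fit> dt ~ dd on ", nrow(x$pairs), " pairs\n",
      "  slope = ", signif(x$slope, 4), " min/um, r = ", signif(x$r, 3),
      "\n", sep = "")
  invisible(x)
}

#' @rdname spacetime_correlation
#' @param x A `spacetime_fit` object.
#' @param ... Unused.
#' @export
tidy.spacetime_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std_error = unname(s[, 2]), statistic = unname(s[, 3]),
         p_value = unname(s[, 4]))
}

#' @rdname spacetime_correlation
#' @export
glance.spacetime_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r = x$r,
         r_squared = x$r^2, n_pairs = nrow(x$pairs))
}
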