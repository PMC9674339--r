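#' Phagosome position at a requested time
#'
#' Phagosome tracking typically starts only at cup/phagosome formation, so
#' positions before the first tracked frame are undefined; the temporally
#' closest known location is used instead. Within the tracked span, the frame
#' whose time stamp is nearest to `t` is returned (no interpolation). When
#' `t` falls exactly midway between two frames the earlier frame wins (fixed
#' tie-break). Events recorded with a single position return that position
#' for all `t`.
#'
#' @param event One-row event table (with `x, y[, z]`).
#' @param t Time (minutes) at which the position is needed; vectorised.
#' @param p_track Optional phagosome track table for this event.
#' @return Matrix with one row per `t`, columns the coordinate axes.
#' @export
phagosome_position_at <- function(event, t, p_track = NULL) {
  if (!is.null(p_track) && nrow(p_track) > 0) {
    m <- coord_matrix(p_track)
    idx <- vapply(t, function(tt) {
      d <- abs(p_track$t - tt)
      which(d == min(d))[1] # earlier frame on ties (rows sorted by t)
    }, 1L)
    return(m[idx, , drop = FALSE])
  }
  p <- unlist(event[coord_cols(event)])
  if (length(p) == 0 || any(is.na(p))) {
    abort(paste0("event ", event$event_id, " has neither a phagosome track nor a position"))
  }
  matrix(rep(p, each = length(t)), nrow = length(t),
         dimnames = list(NULL, names(p)))
}

#' Event-aligned centrosome-geometry window for one event
#'
#' Analyses the time-resolved triangle formed by the cell centre (cc), the
#' centrosome (cs) and the phagosome (p) around one engulfment attempt. For
#' every frame at which both cc and cs are recorded within `window` minutes
#' of onset, it computes the centrosome's distance from the cell centre
#' `d_cs_cc`, the alignment angle `theta` between the vectors cc->cs and
#' cc->p (radians, in `[0, pi]`; 0 = centrosome exactly on the axis toward
#' the phagosome), and the phagosome distance `d_p_cc`. Frames where cs
#' coincides with cc (or p with cc) have an undefined angle and yield
#' `theta = NA` rather than an error. Windows reaching beyond the track are
#' truncated, not discarded.
#'
#' @param dataset An [effero_dataset()].
#' @param event One-row event table (a row of `dataset$events`).
#' @param window Half-width of the window in minutes (default 10).
#' @param centrosome_id Optional `track_id` selecting one centrosome when the
#'   cell has several; default: the centrosome nearest p at onset.
#' @return A tibble (`event_window`): `event_id, cell_id, outcome, mode,
#'   rel_t, d_cs_cc, theta, d_p_cc`.
#' @export
triangle_series <- function(dataset, event, window = 10, centrosome_id = NULL) {
  cc <- cell_track(dataset, event$cell_id, "centre")
  if (nrow(cc) == 0) abort(paste0("no centre track for cell ", event$cell_id))
  cs_all <- cell_track(dataset, event$cell_id, "centrosome")
  if (nrow(cs_all) == 0) abort(paste0("no centrosome track for cell ", event$cell_id))
  p_track <- cell_track(dataset, event$cell_id, "phagosome", event$event_id)
  if (nrow(p_track) == 0) p_track <- NULL

  cs_ids <- unique(cs_all$track_id)
  if (is.null(centrosome_id)) {
    centrosome_id <- if (length(cs_ids) == 1) cs_ids else {
      # multi-centrosome cell: attribute the event to the cs nearest p at onset
      p0 <- phagosome_position_at(event, event$t_onset, p_track)[1, ]
      d0 <- vapply(cs_ids, function(id) {
        cs <- cs_all[cs_all$track_id == id, ]
        i <- which.min(abs(cs$t - event$t_onset))
        sqrt(sum((coord_matrix(cs)[i, ] - p0)^2))
      }, numeric(1))
      cs_ids[which.min(d0)]
    }
  }
  cs <- cs_all[cs_all$track_id == centrosome_id, ]

  t_grid <- intersect(cc$t, cs$t)
  t_grid <- t_grid[abs(t_grid - event$t_onset) <= window + 1e-9]
  if (length(t_grid) == 0) {
    abort(paste0("no overlapping cc/cs frames within the window of event ",
                 event$event_id))
  }
  cc_m <- coord_matrix(cc)[match(t_grid, cc$t), , drop = FALSE]
  cs_m <- coord_matrix(cs)[match(t_grid, cs$t), , drop = FALSE]
  p_m <- phagosome_position_at(event, t_grid, p_track)
  if (ncol(p_m) != ncol(cc_m)) {
    abort(paste0("mixed dimensionality between tracks and event ", event$event_id))
  }
  v_cs <- cs_m - cc_m
  v_p <- p_m - cc_m
  tibble(
    event_id = event$event_id, cell_id = event$cell_id,
    outcome = event$outcome, mode = event$mode,
    rel_t = t_grid - event$t_onset,
    d_cs_cc = vec_norm(v_cs),
    theta = angle_between(v_cs, v_p),
    d_p_cc = vec_norm(v_p)
  )
}

#' Event-aligned windows for every event in a dataset
#'
#' Maps [triangle_series()] over all (or a filtered subset of) events and
#' pools the windows into one tibble keyed by `event_id`. Events that cannot
#' be resolved (no centrosome overlap within the window) are skipped with a
#' warning rather than failing the whole batch.
#'
#' @inheritParams triangle_series
#' @param outcome Optional filter, `"successful"` or `"aborted"`.
#' @return A tibble of pooled event windows.
#' @export
event_windows <- function(dataset, window = 10, outcome = NULL) {
  ev <- dataset$events
  if (!is.null(outcome)) ev <- ev[ev$outcome %in% outcome, ]
  out <- lapply(seq_len(nrow(ev)), function(i) {
    tryCatch(triangle_series(dataset, ev[i, ], window = window),
             error = function(e) {
               warn(paste0("skipping event ", ev$event_id[i], ": ",
                           conditionMessage(e)))
               NULL
             })
  })
  dplyr::bind_rows(out)
}

#' Align windows on event onset and average
#'
#' Windows are aligned at `rel_t = 0` (event onset) and averaged pointwise to
#' give the "typical" centrosomal dynamics around an engulfment attempt. By
#' default the native frame times act as the common grid (frames are matched
#' by rounding `rel_t` to the grid spacing); alternatively an explicit grid
#' spacing can be supplied. Truncated windows contribute only at the grid
#' points they cover, so the per-point `n` records how many windows entered
#' each average.
#'
#' @param windows Pooled windows from [event_windows()].
#' @param outcome Optional filter, `"successful"` or `"aborted"`.
#' @param grid_dt Grid spacing in minutes; default: the smallest positive
#'   spacing observed in the windows.
#' @return A tibble of class `aligned_windows`: `rel_t`, then mean, SD and
#'   `n` for each of `d_cs_cc`, `theta`, `d_p_cc`.
#' @export
align_and_average_windows <- function(windows, outcome = NULL, grid_dt = NULL) {
  if (!is.null(outcome)) windows <- windows[windows$outcome %in% outcome, ]
  if (nrow(windows) == 0) abort("no windows left after filtering")
  if (is.null(grid_dt)) {
    steps <- windows %>%
      dplyr::group_by(.data$event_id) %>%
      dplyr::summarise(dt = if (dplyr::n() > 1) min(diff(sort(.data$rel_t))) else NA_real_,
                       .groups = "drop")
    grid_dt <- min(steps$dt, na.rm = TRUE)
    if (!is.finite(grid_dt)) grid_dt <- 1
  }
  out <- windows %>%
    dplyr::mutate(rel_t = round(.data$rel_t / grid_dt) * grid_dt) %>%
    dplyr::group_by(.data$rel_t) %>%
    dplyr::summarise(
      d_cs_cc_mean = mean(.data$d_cs_cc, na.rm = TRUE),
      d_cs_cc_sd = stats::sd(.data$d_cs_cc, na.rm = TRUE),
      theta_mean = mean(.data$theta, na.rm = TRUE),
      theta_sd = stats::sd(.data$theta, na.rm = TRUE),
      d_p_cc_mean = mean(.data$d_p_cc, na.rm = TRUE),
      d_p_cc_sd = stats::sd(.data$d_p_cc, na.rm = TRUE),
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$rel_t)
  class(out) <- c("aligned_windows", class(out))
  attr(out, "grid_dt") <- grid_dt
  out
}

#' Alignment angles at a fixed offset after onset
#'
#' For every event window, the alignment angle theta at the grid point
#' nearest `rel_t = offset` (default +1 min after onset, where successful
#' engulfments show tight alignment). Nearest-frame lookup is used rather
#' than interpolation, since interpolating angles risks wrap artefacts.
#' Events whose window does not reach the offset (within half the window's
#' own frame spacing, or `tol` if given) are omitted with a warning.
#'
#' @param windows Pooled windows from [event_windows()].
#' @param offset Offset from onset in minutes (default +1).
#' @param tol Optional maximum |rel_t - offset| accepted.
#' @return A tibble `cell_id, event_id, outcome, mode, rel_t, theta`, one row
#'   per event that covers the offset.
#' @export
angles_at_offset <- function(windows, offset = 1, tol = NULL) {
  one <- function(df) {
    d <- abs(df$rel_t - offset)
    i <- which(d == min(d))[1]
    dt_native <- if (nrow(df) > 1) min(diff(sort(df$rel_t))) else Inf
    lim <- tol %||% (dt_native / 2 + 1e-9)
    if (d[i] > lim) return(NULL)
    df[i, c("cell_id", "event_id", "outcome", "mode", "rel_t", "theta")]
  }
  out <- windows %>%
    dplyr::group_split(.data$event_id) %>%
    lapply(one) %>%
    dplyr::bind_rows()
  n_in <- length(unique(windows$event_id))
  if (nrow(out) < n_in) {
    warn(sprintf("%d of %d windows do not cover rel_t = %g min and were omitted",
                 n_in - nrow(out), n_in, offset))
  }
  out
}

#' Circular variance of a set of angles
#'
#' The Jammalamadaka-SenGupta sample circular variance `1 - Rbar`, where
#' `Rbar` is the mean resultant length of the unit vectors
#' `(cos(theta_i), sin(theta_i))`. It is 0 when all angles coincide
#' (fully concentrated) and approaches 1 for angles spread evenly around the
#' circle (e.g. `{0, pi}` or the four quadrant axes give exactly 1).
#'
#' @param angles Numeric vector of angles in radians; at least one.
#' @return Circular variance in `[0, 1]`.
#' @examples
#' circular_variance(rep(0.7, 5)) # 0
#' circular_variance(c(0, pi))    # 1
#' @export
circular_variance <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) abort("no angles supplied")
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  1 - rbar
}

#' Centrosome track in a per-event polar frame
#'
#' Re-expresses the centrosome positions of an event window in a polar frame
#' anchored on the cell: origin at the cell centre cc(t), zero-angle axis
#' along cc->p(t), both re-derived at every time point. `r` is the
#' centrosome's distance from the cell centre and `phi` its signed angle from
#' the phagosome axis. For 2D data `phi` is the standard signed planar angle.
#' For 3D data the sign is fixed by a deterministic reference normal: the
#' unit cross product p-cc x cs-cc at the first frame where it is non-zero
#' (rotating all inputs rigidly rotates the normal with them, so `(r, phi)`
#' are rigid-motion invariant). Where the plane is degenerate (cs on the p
#' axis) the unsigned angle is reported.
#'
#' @inheritParams triangle_series
#' @return A tibble `event_id, rel_t, r, phi`.
#' @export
polar_track <- function(dataset, event, window = 10, centrosome_id = NULL) {
  cc <- cell_track(dataset, event$cell_id, "centre")
  cs_all <- cell_track(dataset, event$cell_id, "centrosome")
  if (nrow(cc) == 0 || nrow(cs_all) == 0) {
    abort(paste0("missing cc or cs track for cell ", event$cell_id))
  }
  tri <- triangle_series(dataset, event, window = window,
                         centrosome_id = centrosome_id)
  cs_ids <- unique(cs_all$track_id)
  cs <- if (length(cs_ids) == 1 || !is.null(centrosome_id)) {
    cs_all[cs_all$track_id == (centrosome_id %||% cs_ids[1]), ]
  } else {
    cs_all[cs_all$track_id == cs_ids[1], ]
  }
  p_track <- cell_track(dataset, event$cell_id, "phagosome", event$event_id)
  if (nrow(p_track) == 0) p_track <- NULL
  t_grid <- tri$rel_t + event$t_onset
  cc_m <- coord_matrix(cc)[match(t_grid, cc$t), , drop = FALSE]
  cs_m <- coord_matrix(cs)[match(t_grid, cs$t), , drop = FALSE]
  p_m <- phagosome_position_at(event, t_grid, p_track)
  v_cs <- cs_m - cc_m
  v_p <- p_m - cc_m
  if (ncol(cc_m) == 2) {
    phi <- atan2(v_cs[, 2], v_cs[, 1]) - atan2(v_p[, 2], v_p[, 1])
    phi <- atan2(sin(phi), cos(phi)) # wrap to (-pi, pi]
    phi[vec_norm(v_cs) == 0 | vec_norm(v_p) == 0] <- NA_real_
  } else {
    normals <- cbind(
      v_p[, 2] * v_cs[, 3] - v_p[, 3] * v_cs[, 2],
      v_p[, 3] * v_cs[, 1] - v_p[, 1] * v_cs[, 3],
      v_p[, 1] * v_cs[, 2] - v_p[, 2] * v_cs[, 1]
    )
    nn <- vec_norm(normals)
    ref <- which(nn > 1e-12)[1]
    if (is.na(ref)) {
      phi <- tri$theta # fully degenerate: unsigned angle everywhere
    } else {
      n0 <- normals[ref, ] / nn[ref]
      e1 <- v_p / pmax(vec_norm(v_p), .Machine$double.eps)
      # e2 = n0 x e1 completes a right-handed frame in each frame's plane
      e2 <- cbind(
        n0[2] * e1[, 3] - n0[3] * e1[, 2],
        n0[3] * e1[, 1] - n0[1] * e1[, 3],
        n0[1] * e1[, 2] - n0[2] * e1[, 1]
      )
      phi <- atan2(rowSums(v_cs * e2), rowSums(v_cs * e1))
      phi[vec_norm(v_cs) == 0 | vec_norm(v_p) == 0] <- NA_real_
    }
  }
  tibble(event_id = event$event_id, rel_t = tri$rel_t,
         r = tri$d_cs_cc, phi = phi)
}

#' Radial probability map of centrosome position
#'
#' Histogram of the centrosome's distance from the cell centre, normalised by
#' the cell radius R, expressed as a probability mass per radial bin (masses
#' sum to 1). This is the radial location map used to compare centrosome
#' positioning across drug treatments.
#'
#' @param cs_positions,cc_positions Matrices or data frames of paired
#'   positions (same number of rows); alternatively `cs_positions` may be a
#'   numeric vector of precomputed distances and `cc_positions` omitted.
#' @param R Cell radius in um, positive.
#' @param bins Number of bins, or a vector of bin edges on the r/R axis
#'   (default 10 bins from 0 to the maximum observed r/R).
#' @return A tibble of class `radial_map`: `bin_low, bin_high, mass`.
#' @export
radial_probability_map <- function(cs_positions, cc_positions = NULL, R,
                                   bins = 10) {
  if (R <= 0) abort("cell radius R must be positive")
  if (is.null(dim(cs_positions)) && is.null(cc_positions)) {
    d <- as.numeric(cs_positions)
  } else {
    cs_m <- as.matrix(as_tibble(as.data.frame(cs_positions)))
    cc_m <- as.matrix(as_tibble(as.data.frame(cc_positions)))
    if (!all(dim(cs_m) == dim(cc_m))) {
      abort("cs and cc position sets must be paired (same dimensions)")
    }
    d <- vec_norm(cs_m - cc_m)
  }
  rr <- d / R
  if (length(bins) == 1) {
    edges <- seq(0, max(rr) + .Machine$double.eps, length.out = bins + 1)
  } else {
    edges <- bins
    if (min(rr) < edges[1] || max(rr) > edges[length(edges)]) {
      abort("bin edges do not cover the observed r/R range")
    }
  }
  counts <- graphics::hist(rr, breaks = edges, plot = FALSE)$counts
  out <- tibble(bin_low = edges[-length(edges)], bin_high = edges[-1],
                mass = counts / sum(counts))
  class(out) <- c("radial_map", class(out))
  out
}

#' Centrosome-cell-centre distance at event onset
#'
#' For every resolvable event, the centrosome's distance from the cell
#' centre at the frame nearest onset, grouped by outcome (and an optional
#' per-event treatment label), ready for [compare_groups()]. Unresolvable
#' events are skipped with a warning.
#'
#' @param dataset An [effero_dataset()].
#' @param group Optional character vector (length `nrow(dataset$events)`) of
#'   treatment labels.
#' @return A tibble `event_id, cell_id, outcome, group, d_cs_cc_um`.
#' @export
centrosome_distance_at_events <- function(dataset, group = NULL) {
  ev <- dataset$events
  if (!is.null(group) && length(group) != nrow(ev)) {
    abort("group labels must match the number of events")
  }
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    w <- tryCatch(triangle_series(dataset, ev[i, ], window = 10),
                  error = function(e) {
                    warn(paste0("skipping event ", ev$event_id[i], ": ",
                                conditionMessage(e)))
                    NULL
                  })
    if (is.null(w)) return(NULL)
    j <- which.min(abs(w$rel_t))
    tibble(event_id = ev$event_id[i], cell_id = ev$cell_id[i],
           outcome = ev$outcome[i],
           group = if (is.null(group)) NA_character_ else group[i],
           d_cs_cc_um = w$d_cs_cc[j])
  })
  dplyr::bind_rows(rows)
}

#' Centrosome speed relative to the cell centre
#'
#' Mean per-step speed of the relative position cs - cc over the frames the
#' two uniformly sampled tracks share: the speed of centrosomal movements in
#' the cell frame, insensitive to whole-cell migration.
#'
#' @param cs_track,cc_track Track tables of the centrosome and cell centre.
#' @return Mean speed in um/min (scalar).
#' @export
centrosome_speed <- function(cs_track, cc_track) {
  t_common <- intersect(cs_track$t, cc_track$t)
  if (length(t_common) < 2) abort("tracks share fewer than 2 frames")
  t_common <- sort(t_common)
  assert_uniform_dt(t_common, what = "shared cs/cc time base")
  rel <- coord_matrix(cs_track)[match(t_common, cs_track$t), , drop = FALSE] -
    coord_matrix(cc_track)[match(t_common, cc_track$t), , drop = FALSE]
  sum(step_lengths(rel)) / (max(t_common) - min(t_common))
}
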