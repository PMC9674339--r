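#' Sphericity of a 3D shape from its volume and surface area
#'
#' \deqn{\psi = \pi^{1/3} (6V)^{2/3} / A.}
#' By the isoperimetric inequality psi = 1 for a sphere and < 1 for every
#' other closed surface, so psi measures how compact (amoeboid) versus
#' branched a segmented cell is. Vectorised over `V` and `A`.
#'
#' @param V Volume(s), um^3, positive.
#' @param A Surface area(s), um^2, positive.
#' @return Dimensionless sphericity in (0, 1] for physical surfaces.
#' @examples
#' sphericity(4 * pi / 3, 4 * pi) # unit sphere -> 1
#' sphericity(1, 6)               # unit cube -> ~0.806
#' @export
sphericity <- function(V, A) {
  if (any(!is.finite(V)) || any(!is.finite(A)) || any(V <= 0) || any(A <= 0)) {
    abort("V and A must be positive and finite")
  }
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Sphericity time series, optionally paired around a treatment time
#'
#' Computes psi(t) for each frame of a cell's shape table. If a treatment
#' time `t0` is given, a paired before/after comparison is added: by default
#' the single nearest frame on each side of `t0`; with `before_window` /
#' `after_window` (minutes) the mean psi over those windows instead.
#'
#' @param shapes Shape table `cell_id, t, V, A` (or the `shapes` element of an
#'   [effero_dataset()]; a dataset may be passed directly).
#' @param t0 Optional treatment time (minutes).
#' @param before_window,after_window Optional window widths (minutes) for the
#'   paired means.
#' @return A tibble `cell_id, t, psi`; when `t0` is given, the result carries
#'   a `paired` attribute: tibble `cell_id, psi_before, psi_after`.
#' @export
sphericity_series <- function(shapes, t0 = NULL, before_window = NULL,
                              after_window = NULL) {
  if (inherits(shapes, "effero_dataset")) shapes <- shapes$shapes
  if (is.null(shapes) || nrow(shapes) == 0) abort("no shape_frames available")
  shapes <- as_tibble(shapes)
  bad <- which(shapes$V <= 0 | shapes$A <= 0)
  if (length(bad) > 0) {
    abort(sprintf("non-positive V or A for cell %s at frame t = %g",
                  shapes$cell_id[bad[1]], shapes$t[bad[1]]))
  }
  out <- shapes %>%
    dplyr::mutate(psi = sphericity(.data$V, .data$A)) %>%
    dplyr::select("cell_id", "t", "psi") %>%
    dplyr::arrange(.data$cell_id, .data$t)
  if (!is.null(t0)) {
    paired <- out %>%
      dplyr::group_by(.data$cell_id) %>%
      dplyr::summarise(
        psi_before = pick_side(.data$t, .data$psi, t0, before_window, "before"),
        psi_after = pick_side(.data$t, .data$psi, t0, after_window, "after"),
        .groups = "drop"
      )
    attr(out, "paired") <- paired
  }
  out
}

pick_side <- function(t, psi, t0, window, side) {
  if (side == "before") sel <- t < t0 else sel <- t >= t0
  if (!any(sel)) return(NA_real_)
  ts <- t[sel]; ps <- psi[sel]
  if (is.null(window)) {
    # single nearest frame to t0 on this side
    ps[which.min(abs(ts - t0))]
  } else {
    inwin <- abs(ts - t0) <= window
    if (!any(inwin)) NA_real_ else mean(ps[inwin])
  }
}

#' Phagocytic branch length
#'
#' Distance between the cell-body centre and the phagosome at the first time
#' point of the phagosome track (or at event onset when the phagosome has a
#' single recorded position): the operational length of the branch that
#' served a branch-mediated engulfment. The cell centre is taken at its
#' nearest recorded frame.
#'
#' @param dataset An [effero_dataset()].
#' @param events Optional subset of the dataset's events (default: all).
#' @return A tibble `event_id, cell_id, mode, outcome, t_ref,
#'   branch_length_um`.
#' @export
branch_length <- function(dataset, events = NULL) {
  events <- events %||% dataset$events
  one <- function(i) {
    ev <- events[i, ]
    cc <- cell_track(dataset, ev$cell_id, "centre")
    if (nrow(cc) == 0) abort(paste0("no centre track for cell ", ev$cell_id))
    p_track <- cell_track(dataset, ev$cell_id, "phagosome", ev$event_id)
    if (nrow(p_track) > 0) {
      t_ref <- p_track$t[1]
      p <- coord_matrix(p_track)[1, ]
    } else {
      t_ref <- ev$t_onset
      p <- unlist(ev[coord_cols(ev)])
    }
    if (t_ref < min(cc$t) - (max(cc$t) - min(cc$t)) || t_ref > max(cc$t) + (max(cc$t) - min(cc$t))) {
      abort(paste0("no temporal overlap between centre track and event ", ev$event_id))
    }
    cc_m <- coord_matrix(cc)
    if (ncol(cc_m) != length(p)) {
      abort(paste0("mixed dimensionality between centre track and event ", ev$event_id))
    }
    cc_at <- cc_m[which.min(abs(cc$t - t_ref)), ]
    tibble(event_id = ev$event_id, cell_id = ev$cell_id, mode = ev$mode,
           outcome = ev$outcome, t_ref = t_ref,
           branch_length_um = sqrt(sum((cc_at - p)^2)))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(events)), one))
}

#' Branch-tip speeds per extension/retraction phase
#'
#' Mean tip speed (path length within the phase divided by phase duration)
#' for caller-annotated extension and retraction intervals of a tip track.
#' Phase boundaries are supplied by the analyst; [split_phases_radial()]
#' offers an automatic split by the sign of the radial tip velocity for
#' exploratory use.
#'
#' @param tip_track Track table of a single branch tip.
#' @param phases Tibble `phase, t_start, t_end`; phases must be non-empty
#'   sub-intervals of the track's time span.
#' @return A tibble `phase, t_start, t_end, speed_um_min`.
#' @export
tip_speeds <- function(tip_track, phases) {
  tip_track <- as_tracks(tip_track)
  m <- coord_matrix(tip_track)
  one <- function(i) {
    ph <- phases[i, ]
    sel <- tip_track$t >= ph$t_start & tip_track$t <= ph$t_end
    if (sum(sel) < 2) {
      abort(sprintf("phase '%s' covers fewer than 2 frames", ph$phase))
    }
    path <- sum(step_lengths(m[sel, , drop = FALSE]))
    dur <- max(tip_track$t[sel]) - min(tip_track$t[sel])
    tibble(phase = ph$phase, t_start = ph$t_start, t_end = ph$t_end,
           speed_um_min = path / dur)
  }
  dplyr::bind_rows(lapply(seq_len(nrow(phases)), one))
}

#' @rdname tip_speeds
#' @param centre Fixed reference point (numeric vector) from which the radial
#'   coordinate is measured.
#' @export
split_phases_radial <- function(tip_track, centre) {
  tip_track <- as_tracks(tip_track)
  m <- coord_matrix(tip_track)
  r <- vec_norm(sweep(m, 2, centre))
  sgn <- sign(diff(r))
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  tibble(
    phase = ifelse(runs$values >= 0, "extension", "retraction"),
    t_start = tip_track$t[starts],
    t_end = tip_track$t[ends + 1]
  )
}

#' Engulfment-attempt summary
#'
#' Attempt rate and composition of a set of phagocytic events: attempts per
#' hour (total count over observation time), the fraction of attempts whose
#' cup closed successfully, and the branch-mediated fraction among events
#' with a known engulfment mode. With zero events the rate is 0 and the
#' fractions are `NA` (undefined, not zero).
#'
#' @param events Event table.
#' @param observation_hours Total observation time in hours, positive.
#' @return One-row tibble: `n_attempts, n_success, n_aborted, n_bm, n_nbm,
#'   attempts_per_hour, success_fraction, bm_fraction`.
#' @export
event_summary <- function(events, observation_hours) {
  if (observation_hours <= 0) abort("observation_hours must be positive")
  if (nrow(events) == 0) {
    return(tibble(n_attempts = 0L, n_success = 0L, n_aborted = 0L,
                  n_bm = 0L, n_nbm = 0L, attempts_per_hour = 0,
                  success_fraction = NA_real_, bm_fraction = NA_real_))
  }
  events <- as_events(events)
  n <- nrow(events)
  n_succ <- sum(events$outcome == "successful")
  n_bm <- sum(events$mode == "BM")
  n_nbm <- sum(events$mode == "NBM")
  tibble(
    n_attempts = n, n_success = n_succ, n_aborted = n - n_succ,
    n_bm = n_bm, n_nbm = n_nbm,
    attempts_per_hour = n / observation_hours,
    success_fraction = n_succ / n,
    bm_fraction = if (n_bm + n_nbm > 0) n_bm / (n_bm + n_nbm) else NA_real_
  )
}

#' Per-cell vesicle summaries
#'
#' Count and diameter statistics of manually measured vesicles (endosomes or
#' lysosomes), one input row per vesicle.
#'
#' @param vesicles Tibble `cell_id, diameter` (um, positive).
#' @return Per-cell tibble `cell_id, n_vesicles, mean_diameter_um,
#'   median_diameter_um, sd_diameter_um`.
#' @export
vesicle_summary <- function(vesicles) {
  vesicles <- as_tibble(vesicles)
  if (any(vesicles$diameter <= 0)) abort("vesicle diameters must be positive")
  vesicles %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::summarise(
      n_vesicles = dplyr::n(),
      mean_diameter_um = mean(.data$diameter),
      median_diameter_um = stats::median(.data$diameter),
      sd_diameter_um = stats::sd(.data$diameter),
      .groups = "drop"
    )
}
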