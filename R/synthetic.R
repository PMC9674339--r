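#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' list. Defaults emulate the magnitudes of the live-imaging study the
#' package analyses: 30 s sampling (`dt = 0.5` min), phagocytic branches of
#' ~20 um, a soma radius of ~5 um, slow cell-centre motion (~0.6 um/min),
#' centrosome movement of ~2 um/min relative to the cell centre, ~60%
#' successful attempts of which ~70% are branch-mediated, and a tectum-like
#' volume holding ~30 microglia spaced ~30 um apart.
#'
#' @param seed Integer RNG seed; every generator is a pure function of its
#'   config, so equal configs give bit-identical output.
#' @param dt Frame interval, minutes.
#' @param n_cells Cells per scenario.
#' @param n_events_per_cell Engulfment attempts per cell.
#' @param event_spacing Minutes between consecutive attempts of a cell.
#' @param branch_length_mean,branch_length_sd Branch length distribution, um.
#' @param bias_strength Pre-onset centrosome drift strength `b` in `[0, 1]`
#'   (fraction of `approach_speed` directed at the phagosome).
#' @param bias_leadtime Minutes before onset at which the drift starts.
#' @param approach_speed Full-strength drift speed, um/min.
#' @param cell_radius Soma radius R, um.
#' @param diffusion_coefficient Brownian/OU diffusion coefficient, um^2/min.
#' @param drift_speed Ballistic/mixed drift speed, um/min.
#' @param confinement_stiffness OU relaxation rate, 1/min.
#' @param cs_sigma Centrosome OU noise intensity, um/sqrt(min).
#' @param cs_stiffness Centrosome OU relaxation rate, 1/min.
#' @param cc_speed Cell-centre speed scale, um/min.
#' @param success_fraction,bm_fraction Event mix.
#' @param n_steps Frames per walker track.
#' @param n_cells_population,n_neurons,box,min_separation Point-population
#'   parameters: microglia count, dead-neuron count, box dimensions (um) and
#'   microglia hard-core minimum separation (um).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       dt = 0.5,
                       n_cells = 10L,
                       n_events_per_cell = 8L,
                       event_spacing = 22,
                       branch_length_mean = 20,
                       branch_length_sd = 3,
                       bias_strength = 0.8,
                       bias_leadtime = 5,
                       approach_speed = 4,
                       cell_radius = 5,
                       diffusion_coefficient = 0.5,
                       drift_speed = 1,
                       confinement_stiffness = 1,
                       cs_sigma = 1,
                       cs_stiffness = 0.2,
                       cc_speed = 0.6,
                       success_fraction = 0.6,
                       bm_fraction = 0.7,
                       n_steps = 100L,
                       n_cells_population = 30L,
                       n_neurons = 60L,
                       box = c(160, 160, 80),
                       min_separation = 20) {
  cfg <- as.list(environment())
  if (cfg$dt <= 0) abort("dt must be positive")
  if (cfg$bias_strength < 0 || cfg$bias_strength > 1) {
    abort("bias_strength must lie in [0, 1]")
  }
  scales <- c("branch_length_mean", "approach_speed", "cell_radius",
              "diffusion_coefficient", "cs_sigma", "event_spacing")
  for (s in scales) if (cfg[[s]] <= 0) abort(paste0(s, " must be positive"))
  if (cfg$event_spacing < cfg$dt) abort("event times closer than dt")
  class(cfg) <- "sim_config"
  cfg
}

random_unit_vectors <- function(n, dim = 3) {
  m <- matrix(stats::rnorm(n * dim), ncol = dim)
  m / vec_norm(m)
}

#' Single random-walk track
#'
#' Uniformly sampled synthetic trajectory in one of four motility regimes:
#' `brownian` (isotropic Gaussian steps, MSD exponent 1), `ballistic`
#' (constant velocity, exponent 2), `confined` (Ornstein-Uhlenbeck
#' relaxation around a fixed point, exponent < 1 at large lags) and `mixed`
#' (Brownian plus constant drift, exponent between 1 and 2).
#'
#' @param config A [sim_config()]; `seed`, `dt`, `n_steps`,
#'   `diffusion_coefficient`, `drift_speed` and `confinement_stiffness` are
#'   used.
#' @param regime One of `brownian`, `ballistic`, `confined`, `mixed`.
#' @param dim 2 or 3.
#' @param object_id Track id for the output table.
#' @return An `effero_tracks` tibble with one track.
#' @export
walker_track <- function(config, regime = c("brownian", "ballistic",
                                            "confined", "mixed"),
                         dim = 3, object_id = "walker") {
  regime <- match.arg(regime)
  set.seed(config$seed)
  n <- config$n_steps
  dt <- config$dt
  sd_step <- sqrt(2 * config$diffusion_coefficient * dt)
  pos <- switch(regime,
    brownian = apply(matrix(stats::rnorm(n * dim, sd = sd_step), ncol = dim),
                     2, cumsum),
    ballistic = {
      u <- random_unit_vectors(1, dim)
      outer(seq_len(n) * dt * config$drift_speed, u[1, ])
    },
    confined = {
      x <- matrix(0, n, dim)
      cur <- rep(0, dim)
      k <- config$confinement_stiffness
      for (i in seq_len(n)) {
        cur <- cur - k * cur * dt + stats::rnorm(dim, sd = sd_step)
        x[i, ] <- cur
      }
      x
    },
    mixed = {
      u <- random_unit_vectors(1, dim)
      apply(matrix(stats::rnorm(n * dim, sd = sd_step), ncol = dim), 2, cumsum) +
        outer(seq_len(n) * dt * config$drift_speed, u[1, ])
    }
  )
  pos <- rbind(rep(0, dim), pos)
  out <- tibble(object_id = object_id, t = (0:n) * dt,
                x = pos[, 1], y = pos[, 2])
  if (dim == 3) out$z <- pos[, 3]
  as_tracks(out)
}

#' Labelled point populations in a tectum-like volume
#'
#' Places `n_cells_population` microglia positions with a hard-core minimum
#' separation (dart throwing) and an independent uniform scatter of
#' `n_neurons` "apoptotic neuron" points inside the box.
#'
#' @param config A [sim_config()].
#' @return A tibble `label, x, y, z` with labels `microglia` and `neuron`.
#' @export
cell_population <- function(config) {
  set.seed(config$seed)
  box <- config$box
  n <- config$n_cells_population
  s <- config$min_separation
  # crude feasibility guard: each hard-core sphere of radius s/2 must fit
  if (n * (4 / 3) * pi * (s / 2)^3 > 0.55 * prod(box)) {
    abort("infeasible packing: min_separation too large for the box")
  }
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 10000L * n) {
      abort("infeasible packing: min_separation too large for the box")
    }
    cand <- stats::runif(3) * box
    if (placed == 0L ||
        min(vec_norm(sweep(pts[seq_len(placed), , drop = FALSE], 2, cand))) >= s) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  neurons <- matrix(stats::runif(3 * config$n_neurons), ncol = 3) %*% diag(box)
  tibble(
    label = rep(c("microglia", "neuron"), c(n, config$n_neurons)),
    x = c(pts[, 1], neurons[, 1]),
    y = c(pts[, 2], neurons[, 2]),
    z = c(pts[, 3], neurons[, 3])
  )
}

# OU update step for a position matrix row
ou_step <- function(cur, target, k, sigma, dt, drift = c(0, 0, 0)) {
  cur + k * (target - cur) * dt + drift * dt + stats::rnorm(3, sd = sigma * sqrt(dt))
}

#' Synthetic efferocytosis scenario with known ground truth
#'
#' Generates a full dataset emulating the study design: per cell a slow
#' cell-centre (cc) track; engulfment attempts at branch tips (BM, target
#' distance ~`branch_length_mean`) or near the soma (NBM, ~`cell_radius`);
#' and a centrosome (cs) trajectory simulated as an Ornstein-Uhlenbeck walk
#' around the cell centre that, for *successful* events only, acquires a
#' drift of strength `bias_strength` toward the phagosome from
#' `bias_leadtime` minutes before onset until onset and then returns to the
#' soma. Aborted attempts get no bias, so their centrosome geometry is the
#' null the study contrasts against. Successful events carry a short
#' phagosome track (transport toward the soma); aborted events carry a
#' single marked position (the cup, stamped 30 s after initial contact).
#'
#' Outcome and mode labels are assigned in fixed per-cell proportions
#' (`success_fraction`, `bm_fraction`) with randomised order, so every cell
#' contributes both outcomes.
#'
#' @param config A [sim_config()].
#' @return An [effero_dataset()] whose `metadata$truth` records the
#'   generator's ground truth (per-event bias, branch vectors, config).
#' @export
efferocytosis_scenario <- function(config) {
  set.seed(config$seed)
  n_ev <- config$n_events_per_cell
  dt <- config$dt
  t_end <- config$event_spacing * (n_ev + 0.5)
  t_grid <- seq(0, t_end, by = dt)
  nt <- length(t_grid)
  onsets <- config$event_spacing * seq_len(n_ev)
  if (any(diff(onsets) < dt)) abort("event times closer than dt")

  tracks <- list()
  events <- list()
  truth_events <- list()
  cells <- tibble(cell_id = sprintf("cell%02d", seq_len(config$n_cells)),
                  radius = config$cell_radius)

  n_succ <- round(config$success_fraction * n_ev)
  n_bm <- round(config$bm_fraction * n_ev)

  for (ci in seq_len(config$n_cells)) {
    cid <- cells$cell_id[ci]
    origin <- stats::runif(3, 0, 100)
    # slow cell-centre wander: OU around the origin scaled to ~cc_speed
    cc <- matrix(0, nt, 3)
    cur <- origin
    sigma_cc <- config$cc_speed / 2
    for (i in seq_len(nt)) {
      cur <- ou_step(cur, origin, k = 0.05, sigma = sigma_cc, dt = dt)
      cc[i, ] <- cur
    }
    tracks[[length(tracks) + 1]] <- tibble(
      cell_id = cid, role = "centre", track_id = "cc",
      t = t_grid, x = cc[, 1], y = cc[, 2], z = cc[, 3]
    )

    outcome <- sample(rep(c("successful", "aborted"), c(n_succ, n_ev - n_succ)))
    mode <- sample(rep(c("BM", "NBM"), c(n_bm, n_ev - n_bm)))

    # event target positions: branch tips for BM, soma edge for NBM
    p_pos <- matrix(0, n_ev, 3)
    for (ei in seq_len(n_ev)) {
      u <- random_unit_vectors(1)[1, ]
      len <- if (mode[ei] == "BM") {
        max(10, stats::rnorm(1, config$branch_length_mean, config$branch_length_sd))
      } else {
        config$cell_radius
      }
      i_on <- which.min(abs(t_grid - onsets[ei]))
      p_pos[ei, ] <- cc[i_on, ] + len * u
    }

    # centrosome: OU around cc with pre-onset drift toward successful targets
    cs <- matrix(0, nt, 3)
    cs_rel <- random_unit_vectors(1)[1, ] * 1
    returning <- FALSE
    for (i in seq_len(nt)) {
      tt <- t_grid[i]
      drift <- c(0, 0, 0)
      active <- which(outcome == "successful" &
                        tt >= onsets - config$bias_leadtime & tt <= onsets)
      if (length(active) > 0) {
        ei <- active[1]
        to_p <- (p_pos[ei, ] - cc[i, ]) - cs_rel
        nrm <- sqrt(sum(to_p^2))
        if (nrm > 1e-9) {
          drift <- config$bias_strength * config$approach_speed * to_p / nrm
        }
        returning <- TRUE
      } else if (returning) {
        # return leg after onset: drift back toward the cell centre
        nrm <- sqrt(sum(cs_rel^2))
        if (nrm > 2) {
          drift <- -config$bias_strength * config$approach_speed * cs_rel / nrm
        } else {
          returning <- FALSE
        }
      }
      cs_rel <- cs_rel + (-config$cs_stiffness * cs_rel + drift) * dt +
        stats::rnorm(3, sd = config$cs_sigma * sqrt(dt))
      cs[i, ] <- cc[i, ] + cs_rel
    }
    tracks[[length(tracks) + 1]] <- tibble(
      cell_id = cid, role = "centrosome", track_id = "cs1",
      t = t_grid, x = cs[, 1], y = cs[, 2], z = cs[, 3]
    )

    for (ei in seq_len(n_ev)) {
      eid <- sprintf("%s_ev%02d", cid, ei)
      events[[length(events) + 1]] <- tibble(
        event_id = eid, cell_id = cid, t_onset = onsets[ei],
        x = p_pos[ei, 1], y = p_pos[ei, 2], z = p_pos[ei, 3],
        outcome = outcome[ei], mode = mode[ei]
      )
      if (outcome[ei] == "successful") {
        # phagosome transported toward the soma over ~3 min after closure
        tp <- seq(onsets[ei], min(onsets[ei] + 3, t_end), by = dt)
        frac <- seq(0, 1, length.out = length(tp))
        i_on <- which.min(abs(t_grid - onsets[ei]))
        pp <- outer(1 - frac, p_pos[ei, ]) + outer(frac, cc[i_on, ])
        tracks[[length(tracks) + 1]] <- tibble(
          cell_id = cid, role = "phagosome", track_id = eid,
          t = tp, x = pp[, 1], y = pp[, 2], z = pp[, 3]
        )
      }
      ev_bias <- if (outcome[ei] == "successful") config$bias_strength else 0
      ev_dist <- sqrt(sum((p_pos[ei, ] -
        cc[which.min(abs(t_grid - onsets[ei])), ])^2))
      truth_events[[length(truth_events) + 1]] <- tibble(
        event_id = eid, cell_id = cid, outcome = outcome[ei], mode = mode[ei],
        bias = ev_bias, target_distance = ev_dist, served_by = "cs1"
      )
    }
  }

  effero_dataset(
    tracks = dplyr::bind_rows(tracks),
    events = dplyr::bind_rows(events),
    cells = cells,
    metadata = list(dt = dt, truth = list(config = config,
                                          events = dplyr::bind_rows(truth_events)))
  )
}

#' Synthetic shape (volume, area) series
#'
#' Emulates the branched-to-amoeboid morphology switch: volume `V` is held
#' constant while the surface area starts at `a_factor` times the spherical
#' minimum `A_min = pi^(1/3) (6V)^(2/3)` and relaxes exponentially toward
#' `A_min` after `t_switch`, so sphericity rises strictly across the switch.
#' `constant` keeps (V, A) fixed.
#'
#' @param config A [sim_config()] (uses `dt`, `seed`).
#' @param scenario `branched_to_amoeboid` or `constant`.
#' @param V Cell volume, um^3.
#' @param a_factor Initial area as a multiple of the spherical minimum;
#'   must be >= 1 (an area below the spherical bound is unphysical).
#' @param t_switch,t_total Switch time and series length, minutes.
#' @param relax_tau Area relaxation time constant, minutes.
#' @param cell_id Label for the output.
#' @return A tibble `cell_id, t, V, A`.
#' @export
shape_series <- function(config, scenario = c("branched_to_amoeboid", "constant"),
                         V = 500, a_factor = 2.5, t_switch = 10, t_total = 20,
                         relax_tau = 2, cell_id = "cell01") {
  scenario <- match.arg(scenario)
  if (a_factor < 1) {
    abort("a_factor < 1 requests an area below the spherical bound")
  }
  t <- seq(0, t_total, by = config$dt)
  a_min <- pi^(1 / 3) * (6 * V)^(2 / 3)
  A <- if (scenario == "constant") {
    rep(a_factor * a_min, length(t))
  } else {
    ifelse(t < t_switch,
           a_factor * a_min,
           a_min + (a_factor - 1) * a_min * exp(-(t - t_switch + config$dt) / relax_tau))
  }
  tibble(cell_id = cell_id, t = t, V = V, A = A)
}

#' Add a second centrosome to selected cells
#'
#' Emulates double-centrosome microglia: each flagged cell receives a second
#' centrosome track and additional successful events that overlap in time
#' with existing successful events, each served by one centrosome (the new
#' events bias the new centrosome; the original events keep the first). The
#' per-cell attempt rate of flagged cells therefore rises by roughly
#' `rate_factor`. The ground-truth table records which centrosome served
#' which event.
#'
#' @param dataset A dataset from [efferocytosis_scenario()].
#' @param config The same [sim_config()] (its `seed` is re-derived so the
#'   addition is deterministic).
#' @param cell_ids Cells to flag; default: the first half.
#' @param rate_factor Target multiple of the original per-cell event count
#'   (default 1.5).
#' @return The augmented dataset; `metadata$truth$events$served_by` names the
#'   serving centrosome.
#' @export
two_centrosome_variant <- function(dataset, config, cell_ids = NULL,
                                   rate_factor = 1.5) {
  all_cells <- unique(dataset$tracks$cell_id[dataset$tracks$role == "centre"])
  cell_ids <- cell_ids %||% all_cells[seq_len(ceiling(length(all_cells) / 2))]
  unknown <- setdiff(cell_ids, all_cells)
  if (length(unknown) > 0) {
    abort(paste0("flag set on unknown cell: ", unknown[1]))
  }
  set.seed(config$seed + 104729L) # deterministic offset from the base seed
  new_tracks <- list()
  new_events <- list()
  new_truth <- list()
  truth_ev <- dataset$metadata$truth$events

  for (cid in cell_ids) {
    cc_tr <- cell_track(dataset, cid, "centre")
    t_grid <- cc_tr$t
    dt <- config$dt
    nt <- length(t_grid)
    cc <- coord_matrix(cc_tr)
    ev_cell <- dataset$events[dataset$events$cell_id == cid &
                                dataset$events$outcome == "successful", ]
    n_extra <- max(1L, round((rate_factor - 1) * config$n_events_per_cell))
    n_extra <- min(n_extra, nrow(ev_cell))
    pick <- ev_cell[sample(nrow(ev_cell), n_extra), ]

    # overlapping partner events, each at its own branch tip
    extra <- lapply(seq_len(n_extra), function(k) {
      u <- random_unit_vectors(1)[1, ]
      len <- max(10, stats::rnorm(1, config$branch_length_mean,
                                  config$branch_length_sd))
      i_on <- which.min(abs(t_grid - pick$t_onset[k]))
      p <- cc[i_on, ] + len * u
      tibble(event_id = paste0(pick$event_id[k], "b"), cell_id = cid,
             t_onset = pick$t_onset[k], x = p[1], y = p[2], z = p[3],
             outcome = "successful", mode = "BM")
    })
    extra <- dplyr::bind_rows(extra)
    new_events[[length(new_events) + 1]] <- extra

    # second centrosome biased toward the extra events only
    cs <- matrix(0, nt, 3)
    cs_rel <- random_unit_vectors(1)[1, ]
    returning <- FALSE
    for (i in seq_len(nt)) {
      tt <- t_grid[i]
      drift <- c(0, 0, 0)
      act <- which(tt >= extra$t_onset - config$bias_leadtime &
                     tt <= extra$t_onset)
      if (length(act) > 0) {
        p <- unlist(extra[act[1], c("x", "y", "z")])
        to_p <- (p - cc[i, ]) - cs_rel
        nrm <- sqrt(sum(to_p^2))
        if (nrm > 1e-9) {
          drift <- config$bias_strength * config$approach_speed * to_p / nrm
        }
        returning <- TRUE
      } else if (returning) {
        nrm <- sqrt(sum(cs_rel^2))
        if (nrm > 2) {
          drift <- -config$bias_strength * config$approach_speed * cs_rel / nrm
        } else returning <- FALSE
      }
      cs_rel <- cs_rel + (-config$cs_stiffness * cs_rel + drift) * dt +
        stats::rnorm(3, sd = config$cs_sigma * sqrt(dt))
      cs[i, ] <- cc[i, ] + cs_rel
    }
    new_tracks[[length(new_tracks) + 1]] <- tibble(
      cell_id = cid, role = "centrosome", track_id = "cs2",
      t = t_grid, x = cs[, 1], y = cs[, 2], z = cs[, 3]
    )
    new_truth[[length(new_truth) + 1]] <- tibble(
      event_id = extra$event_id, cell_id = cid, outcome = "successful",
      mode = "BM", bias = config$bias_strength,
      target_distance = NA_real_, served_by = "cs2"
    )
  }

  out <- effero_dataset(
    tracks = dplyr::bind_rows(dataset$tracks, dplyr::bind_rows(new_tracks)),
    events = dplyr::bind_rows(dataset$events, dplyr::bind_rows(new_events)),
    shapes = dataset$shapes, cells = dataset$cells, points = dataset$points,
    metadata = dataset$metadata
  )
  out$metadata$truth$events <- dplyr::bind_rows(truth_ev,
                                                dplyr::bind_rows(new_truth))
  out$metadata$two_centrosome_cells <- cell_ids
  out
}
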