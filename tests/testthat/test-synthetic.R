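test_that("walker tracks realise their motility regimes deterministically", {
  cfg <- sim_config(seed = 11)
  # same seed twice -> bit-identical output
  expect_identical(walker_track(cfg, "brownian"), walker_track(cfg, "brownian"))
  # ballistic is exactly straight: alpha = 2
  b <- walker_track(cfg, "ballistic")
  expect_equal(msd_alpha(msd(b))$alpha, 2, tolerance = 1e-9)
  # mixed drift sits between diffusion and ballistic over moderate lags
  a_mixed <- vapply(1:10, function(s) {
    cfg_i <- sim_config(seed = s, n_steps = 200, drift_speed = 2)
    msd_alpha(msd(walker_track(cfg_i, "mixed"), n_max = 50))$alpha
  }, numeric(1))
  expect_gt(median(a_mixed), 1)
  expect_lt(median(a_mixed), 2)
  expect_error(walker_track(cfg, "hovering"))
})

test_that("cell populations respect the hard-core separation rule", {
  cfg <- sim_config(seed = 14)
  pop <- cell_population(cfg)
  mg <- pop[pop$label == "microglia", ]
  expect_equal(nrow(mg), cfg$n_cells_population)
  nn <- nearest_neighbour_distances(mg)
  expect_true(all(nn$nn_distance_um >= cfg$min_separation))
  expect_error(cell_population(sim_config(seed = 1, min_separation = 200)),
               "infeasible")
  # larger box at fixed n raises the mean nearest-neighbour distance
  mean_nn <- function(box, seeds) {
    mean(vapply(seeds, function(s) {
      p <- cell_population(sim_config(seed = s, box = box, min_separation = 5))
      mean(nearest_neighbour_distances(p[p$label == "microglia", ])$nn_distance_um)
    }, numeric(1)))
  }
  expect_gt(mean_nn(c(320, 320, 160), 1:5), mean_nn(c(160, 160, 80), 1:5))
})

test_that("scenario datasets are reproducible and pass validation", {
  cfg <- sim_config(seed = 6, n_cells = 3, n_events_per_cell = 4)
  ds1 <- efferocytosis_scenario(cfg)
  ds2 <- efferocytosis_scenario(cfg)
  expect_identical(ds1$tracks, ds2$tracks)
  expect_identical(ds1$events, ds2$events)
  expect_equal(nrow(validate_dataset(ds1)), 0)
  # event mix follows the configured proportions exactly (per cell)
  per_cell <- table(ds1$events$cell_id, ds1$events$outcome)
  expect_true(all(per_cell[, "successful"] == round(0.6 * 4)))
  # ground truth records a bias for successful events only
  truth <- ds1$metadata$truth$events
  expect_true(all(truth$bias[truth$outcome == "successful"] == cfg$bias_strength))
  expect_true(all(truth$bias[truth$outcome == "aborted"] == 0))
  expect_error(efferocytosis_scenario(sim_config(seed = 1, event_spacing = 0.1)),
               "closer than dt")
})

test_that("noise-free full bias drives theta at onset to zero", {
  cfg <- sim_config(seed = 2, n_cells = 2, n_events_per_cell = 4,
                    bias_strength = 1, cs_sigma = 1e-9, cc_speed = 1e-9,
                    approach_speed = 8)
  ds <- efferocytosis_scenario(cfg)
  w <- suppressWarnings(event_windows(ds))
  at0 <- w[w$rel_t == 0 & w$outcome == "successful", ]
  expect_true(all(at0$theta < 0.05, na.rm = TRUE))
})

test_that("shape series guarantee the monotone sphericity switch", {
  cfg <- sim_config(seed = 3)
  sw <- shape_series(cfg, "branched_to_amoeboid", t_switch = 10)
  psi <- sphericity(sw$V, sw$A)
  expect_lt(max(psi[sw$t < 10]), min(psi[sw$t >= 10]))
  expect_true(all(diff(psi[sw$t >= 10]) >= -1e-12))
  expect_true(all(psi <= 1 + 1e-12))
  const <- shape_series(cfg, "constant")
  expect_equal(length(unique(sphericity(const$V, const$A))), 1)
  expect_error(shape_series(cfg, "branched_to_amoeboid", a_factor = 0.5),
               "spherical bound")
  # area at the spherical bound gives psi = 1 at the endpoint
  end <- shape_series(cfg, "branched_to_amoeboid", a_factor = 1)
  expect_equal(sphericity(end$V[1], end$A[1]), 1, tolerance = 1e-12)
})

test_that("two-centrosome cells gain overlapping events served by the nearer cs", {
  cfg <- sim_config(seed = 10, n_cells = 4, n_events_per_cell = 6)
  base <- efferocytosis_scenario(cfg)
  aug <- two_centrosome_variant(base, cfg, cell_ids = c("cell01", "cell02"),
                                rate_factor = 1.5)
  expect_error(two_centrosome_variant(base, cfg, cell_ids = "nope"),
               "unknown cell")
  # only flagged cells have a second centrosome and extra events
  cs2_cells <- unique(aug$tracks$cell_id[aug$tracks$track_id == "cs2"])
  expect_setequal(cs2_cells, c("cell01", "cell02"))
  counts <- table(aug$events$cell_id)
  expect_true(all(counts[c("cell01", "cell02")] > counts[c("cell03", "cell04")]))
  # overlapping onsets occur only in flagged cells
  overlaps <- dplyr::filter(dplyr::count(aug$events, cell_id, t_onset), n > 1)
  expect_true(all(overlaps$cell_id %in% c("cell01", "cell02")))
  # the geometry analysis attributes each added event to its serving cs
  truth <- aug$metadata$truth$events
  added <- truth[truth$served_by == "cs2", ]
  expect_gt(nrow(added), 0)
  ok <- vapply(seq_len(nrow(added)), function(i) {
    ev <- aug$events[aug$events$event_id == added$event_id[i], ]
    cs_all <- aug$tracks[aug$tracks$cell_id == ev$cell_id &
                           aug$tracks$role == "centrosome", ]
    p0 <- unlist(ev[c("x", "y", "z")])
    d_at_onset <- vapply(c("cs1", "cs2"), function(id) {
      cs <- cs_all[cs_all$track_id == id, ]
      j <- which.min(abs(cs$t - ev$t_onset))
      sqrt(sum((unlist(cs[j, c("x", "y", "z")]) - p0)^2))
    }, numeric(1))
    names(which.min(d_at_onset)) == "cs2"
  }, logical(1))
  # the biased cs is the nearer one at onset for the events it serves
  expect_true(mean(ok) > 0.8)
})
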