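test_that("sphericity attains known closed-form values", {
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1, tolerance = 1e-12)
  # unit cube, independently evaluated closed form
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-12)
  expect_error(sphericity(-1, 6), "positive")
  expect_error(sphericity(1, 0), "positive")
})

test_that("mesh-derived (V, A) respect the isoperimetric bound", {
  sphere <- star_mesh(function(th, ph) rep(1, length(th)), 200, 400)
  va <- mesh_volume_area(sphere)
  expect_equal(va$V, 4 * pi / 3, tolerance = 1e-3)
  expect_equal(va$A, 4 * pi, tolerance = 1e-3)
  expect_equal(sphericity(va$V, va$A), 1, tolerance = 1e-3)
  # 2:1:1 ellipsoid is strictly less spherical
  ell <- mesh_volume_area(ellipsoid_mesh(2, 1, 1))
  expect_lt(sphericity(ell$V, ell$A), 1)
  # random closed star shapes never exceed 1
  for (seed in 1:20) {
    va <- mesh_volume_area(random_star_mesh(seed))
    expect_lte(sphericity(va$V, va$A), 1)
  }
})

test_that("sphericity_series tracks psi over time and pairs around t0", {
  cfg <- sim_config(seed = 5)
  sh <- shape_series(cfg, "constant")
  ser <- sphericity_series(sh)
  expect_equal(length(unique(ser$psi)), 1)

  sw <- shape_series(cfg, "branched_to_amoeboid", t_switch = 10)
  ser <- sphericity_series(sw, t0 = 10)
  paired <- attr(ser, "paired")
  expect_gt(paired$psi_after, paired$psi_before)
  # monotone non-decreasing across the switch
  after <- ser$psi[sw$t >= 10]
  expect_true(all(diff(after) >= -1e-12))

  bad <- sw
  bad$A[3] <- 0
  expect_error(sphericity_series(bad), "t = 1")
  expect_error(sphericity_series(NULL), "shape_frames")
})

test_that("branch length is the cc-p distance at the phagosome's first frame", {
  ds <- toy_dataset(p_pos = c(20, 0, 0))
  bl <- branch_length(ds)
  expect_equal(bl$branch_length_um, 20)
  # with a phagosome track, its first frame defines the reference time
  ds2 <- toy_dataset()
  ds2$tracks <- dplyr::bind_rows(
    ds2$tracks,
    tibble::tibble(cell_id = "c1", role = "phagosome", track_id = "e1",
                   t = c(20, 20.5), x = c(12, 8), y = 0, z = 0)
  )
  expect_equal(branch_length(ds2)$branch_length_um, 12)
  expect_equal(branch_length(ds2)$t_ref, 20)
  # randomized fixture equals direct recomputation
  set.seed(31)
  p <- rnorm(3, sd = 15)
  ds3 <- toy_dataset(p_pos = p)
  expect_equal(branch_length(ds3)$branch_length_um, sqrt(sum(p^2)),
               tolerance = 1e-12)
  # 2D event on a 3D centre track
  ds4 <- toy_dataset()
  ds4$events$z <- NULL
  expect_error(branch_length(ds4), "dimensionality")
})

test_that("tip speeds are per-phase path length over duration", {
  tip <- data.frame(object_id = "tip", t = 0:4 * 0.5,
                    x = c(0, 3, 6, 3, 0), y = 0)
  phases <- tibble::tibble(phase = c("extension", "retraction"),
                           t_start = c(0, 1), t_end = c(1, 2))
  sp <- tip_speeds(tip, phases)
  expect_equal(sp$speed_um_min, c(6, 6)) # symmetric out/back -> equal speeds
  expect_error(tip_speeds(tip, tibble::tibble(phase = "x", t_start = 9,
                                              t_end = 10)), "fewer than 2")
  # automatic radial splitter finds the turning point
  auto <- split_phases_radial(tip, centre = c(0, 0))
  expect_setequal(auto$phase, c("extension", "retraction"))
})

test_that("event_summary reports rates and fractions per the counting rules", {
  ev <- tibble::tibble(
    cell_id = "c1", t_onset = seq_len(10), x = 0, y = 0,
    outcome = rep(c("successful", "aborted"), c(6, 4)),
    mode = rep(c("BM", "NBM", "unknown"), c(7, 2, 1))
  )
  s <- event_summary(ev, observation_hours = 1)
  expect_equal(s$attempts_per_hour, 10)
  expect_equal(s$success_fraction, 0.6)
  expect_equal(s$bm_fraction, 7 / 9) # unknown-mode events leave the denominator
  # reordering leaves every fraction unchanged
  s2 <- event_summary(ev[sample(10), ], observation_hours = 1)
  expect_equal(s2$success_fraction, s$success_fraction)
  expect_equal(s2$bm_fraction, s$bm_fraction)
  s0 <- event_summary(ev[0, ], observation_hours = 2)
  expect_equal(s0$attempts_per_hour, 0)
  expect_true(is.na(s0$success_fraction) && is.na(s0$bm_fraction))
})

test_that("vesicle_summary aggregates per cell and rejects bad diameters", {
  v <- tibble::tibble(cell_id = c("a", "a", "b"), diameter = c(1, 2, 3))
  s <- vesicle_summary(v)
  expect_equal(s$n_vesicles, c(2L, 1L))
  expect_equal(s$mean_diameter_um, c(1.5, 3))
  expect_error(vesicle_summary(tibble::tibble(cell_id = "a", diameter = 0)))
})
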