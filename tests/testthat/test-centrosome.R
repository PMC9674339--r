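test_that("phagosome position lookup uses temporally closest frame", {
  ev <- tibble::tibble(event_id = "e1", cell_id = "c1", t_onset = 10,
                       x = 1, y = 2, z = 3, outcome = "successful", mode = "BM")
  p_track <- tibble::tibble(cell_id = "c1", role = "phagosome", track_id = "e1",
                            t = c(10, 11, 12), x = c(5, 6, 7), y = 0, z = 0)
  # exact frame
  expect_equal(phagosome_position_at(ev, 11, p_track)[1, "x"], c(x = 6))
  # before the first tracked frame -> first frame's position
  expect_equal(phagosome_position_at(ev, 2, p_track)[1, "x"], c(x = 5))
  # equidistant tie -> earlier frame
  expect_equal(phagosome_position_at(ev, 10.5, p_track)[1, "x"], c(x = 5))
  # single-position event returns that position for all t
  m <- phagosome_position_at(ev, c(0, 50))
  expect_equal(unname(m[, "x"]), c(1, 1))
  ev_bad <- dplyr::mutate(ev, x = NA_real_, y = NA_real_, z = NA_real_)
  expect_error(phagosome_position_at(ev_bad, 5), "neither")
})

test_that("triangle geometry hits the canonical angles", {
  # cs on the cc->p ray
  ds <- toy_dataset(cs_offset = c(3, 0, 0), p_pos = c(20, 0, 0))
  w <- triangle_series(ds, ds$events[1, ])
  expect_true(all(abs(w$theta) < 1e-12))
  expect_true(all(w$d_cs_cc == 3))
  expect_true(all(w$d_p_cc == 20))
  # diametrically opposite
  ds <- toy_dataset(cs_offset = c(-3, 0, 0))
  expect_true(all(abs(triangle_series(ds, ds$events[1, ])$theta - pi) < 1e-12))
  # perpendicular
  ds <- toy_dataset(cs_offset = c(0, 3, 0))
  expect_true(all(abs(triangle_series(ds, ds$events[1, ])$theta - pi / 2) < 1e-12))
  # cs coincident with cc: angle missing, not an error
  ds <- toy_dataset(cs_offset = c(0, 0, 0))
  w <- triangle_series(ds, ds$events[1, ])
  expect_true(all(is.na(w$theta)))
  expect_true(all(w$d_cs_cc == 0))
})

test_that("windows are clipped to +/- 10 min and truncated at track edges", {
  ds <- toy_dataset(t_grid = seq(0, 40, 0.5), t_onset = 20)
  w <- triangle_series(ds, ds$events[1, ])
  expect_equal(range(w$rel_t), c(-10, 10))
  expect_equal(nrow(w), 41)
  # onset near the start: left side truncated, not discarded
  ds2 <- toy_dataset(t_grid = seq(0, 40, 0.5), t_onset = 3)
  w2 <- triangle_series(ds2, ds2$events[1, ])
  expect_equal(range(w2$rel_t), c(-3, 10))
})

test_that("averaging identical windows returns the template with SD 0", {
  ds <- toy_dataset()
  w1 <- triangle_series(ds, ds$events[1, ])
  windows <- dplyr::bind_rows(
    dplyr::mutate(w1, event_id = "a"),
    dplyr::mutate(w1, event_id = "b"),
    dplyr::mutate(w1, event_id = "c")
  )
  av <- align_and_average_windows(windows)
  expect_equal(av$d_cs_cc_mean, w1$d_cs_cc, tolerance = 1e-12)
  expect_true(all(av$d_cs_cc_sd == 0))
  expect_true(all(av$n == 3))
  expect_error(align_and_average_windows(windows, outcome = "aborted"),
               "no windows")
})

test_that("truncated windows contribute only where defined", {
  ds_full <- toy_dataset(t_onset = 20)
  ds_trunc <- toy_dataset(t_onset = 3)
  w <- dplyr::bind_rows(
    dplyr::mutate(triangle_series(ds_full, ds_full$events[1, ]), event_id = "full"),
    dplyr::mutate(triangle_series(ds_trunc, ds_trunc$events[1, ]), event_id = "trunc")
  )
  av <- align_and_average_windows(w)
  # hand-computed coverage: both windows on [-3, 10], only the full one below
  expect_true(all(av$n[av$rel_t < -3] == 1))
  expect_true(all(av$n[av$rel_t >= -3] == 2))
  # mean of theta 0 and pi is pi/2 at shared grid points
  w2 <- dplyr::bind_rows(
    dplyr::mutate(triangle_series(toy_dataset(cs_offset = c(3, 0, 0)),
                                  ds_full$events[1, ]), event_id = "a"),
    dplyr::mutate(triangle_series(toy_dataset(cs_offset = c(-3, 0, 0)),
                                  ds_full$events[1, ]), event_id = "b")
  )
  av2 <- align_and_average_windows(w2)
  expect_equal(av2$theta_mean, rep(pi / 2, nrow(av2)), tolerance = 1e-12)
})

test_that("angles_at_offset picks the nearest grid point per event", {
  ds <- toy_dataset(cs_offset = c(0, 3, 0), t_grid = seq(0, 40, 0.5))
  w <- event_windows(ds)
  ang <- angles_at_offset(w, offset = 1)
  expect_equal(nrow(ang), 1)
  expect_equal(ang$rel_t, 1)
  expect_equal(ang$theta, pi / 2, tolerance = 1e-12)
  # 0.5-min grid: offset 1.2 snaps to the 1.0 frame
  ang2 <- angles_at_offset(w, offset = 1.2)
  expect_equal(ang2$rel_t, 1)
  # offset beyond all windows: empty result with a warning
  expect_warning(out <- angles_at_offset(w, offset = 99), "omitted")
  expect_equal(nrow(out), 0)
})

test_that("circular variance follows the mean-resultant-length estimator", {
  expect_equal(circular_variance(rep(1.3, 8)), 0, tolerance = 1e-12)
  expect_equal(circular_variance(c(0, pi)), 1, tolerance = 1e-12)
  expect_equal(circular_variance(c(0, pi / 2, pi, 3 * pi / 2)), 1,
               tolerance = 1e-12)
  expect_error(circular_variance(numeric(0)), "no angles")
  # always inside [0, 1]
  for (seed in 1:10) {
    set.seed(seed)
    cv <- circular_variance(runif(sample(1:30, 1), 0, 2 * pi))
    expect_gte(cv, 0)
    expect_lte(cv, 1)
  }
})

test_that("polar tracks put the phagosome axis at phi = 0 and are rigid-invariant", {
  ds <- toy_dataset(cs_offset = c(3, 0, 0), p_pos = c(20, 0, 0))
  pt <- polar_track(ds, ds$events[1, ])
  expect_true(all(abs(pt$phi) < 1e-12))
  expect_true(all(pt$r == 3))
  ds_side <- toy_dataset(cs_offset = c(0, 3, 0), p_pos = c(20, 0, 0))
  pt_side <- polar_track(ds_side, ds_side$events[1, ])
  expect_true(all(abs(abs(pt_side$phi) - pi / 2) < 1e-12))
  # rigid rotation + translation leaves (r, phi) unchanged
  rot <- random_rotation(5)
  ds_rot <- rigid_dataset(ds_side, rot, c(7, -4, 2))
  pt_rot <- polar_track(ds_rot, ds_rot$events[1, ])
  expect_equal(pt_rot$r, pt_side$r, tolerance = 1e-9)
  expect_equal(pt_rot$phi, pt_side$phi, tolerance = 1e-9)
})

test_that("radial probability map normalises and localises correctly", {
  # all cs at cc: everything in the innermost bin
  cs <- matrix(0, 50, 3)
  cc <- matrix(0, 50, 3)
  map <- radial_probability_map(cs, cc, R = 5, bins = seq(0, 2, 0.2))
  expect_equal(map$mass[1], 1)
  expect_equal(sum(map$mass), 1, tolerance = 1e-12)
  # random input still sums to 1
  set.seed(4)
  cs <- matrix(rnorm(300), 100, 3)
  map <- radial_probability_map(cs, matrix(0, 100, 3), R = 3)
  expect_equal(sum(map$mass), 1, tolerance = 1e-9)
  expect_error(radial_probability_map(cs, matrix(0, 100, 3), R = -1),
               "positive")
  expect_s3_class(ggplot2::autoplot(map), "ggplot")
})

test_that("distances at onset match triangle series at rel_t = 0", {
  ds <- toy_dataset(cs_offset = c(12, 0, 0))
  d <- centrosome_distance_at_events(ds)
  expect_equal(d$d_cs_cc_um, 12)
  cfg <- sim_config(seed = 21, n_cells = 3, n_events_per_cell = 4)
  sc <- efferocytosis_scenario(cfg)
  d <- centrosome_distance_at_events(sc)
  expect_setequal(unique(d$outcome), c("successful", "aborted"))
  for (i in seq_len(nrow(d))) {
    ev <- sc$events[sc$events$event_id == d$event_id[i], ]
    w <- triangle_series(sc, ev)
    expect_equal(d$d_cs_cc_um[i], w$d_cs_cc[which.min(abs(w$rel_t))],
                 tolerance = 1e-12)
  }
})

test_that("centrosome speed is measured in the cell frame", {
  t <- seq(0, 10, 0.5)
  # cc drifts, cs rides along at fixed offset: relative speed 0
  cc <- tibble::tibble(object_id = "cc", t = t, x = t, y = 2 * t, z = 0)
  cs <- dplyr::mutate(cc, x = x + 3)
  expect_equal(centrosome_speed(cs, cc), 0)
  # cs orbits cc on a circle of radius r at angular rate w:
  # per-step chord speed = 2 r sin(w dt / 2) / dt
  r <- 4; omega <- 0.6; dt <- 0.5
  orbit <- tibble::tibble(object_id = "cs", t = t,
                          x = t + r * cos(omega * t),
                          y = 2 * t + r * sin(omega * t), z = 0)
  expect_equal(centrosome_speed(orbit, cc),
               2 * r * sin(omega * dt / 2) / dt, tolerance = 1e-9)
  # equals the path-length/duration oracle on a random pair
  set.seed(9)
  cs_r <- dplyr::mutate(cc, x = x + cumsum(rnorm(length(t), sd = 0.3)),
                        y = y + cumsum(rnorm(length(t), sd = 0.3)))
  rel <- cbind(cs_r$x - cc$x, cs_r$y - cc$y, cs_r$z - cc$z)
  oracle <- sum(sqrt(rowSums(diff(rel)^2))) / (max(t) - min(t))
  expect_equal(centrosome_speed(cs_r, cc), oracle, tolerance = 1e-12)
  expect_error(centrosome_speed(dplyr::mutate(cc, t = t + 100), cc),
               "fewer than 2")
})
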