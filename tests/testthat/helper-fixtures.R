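# shared fixture builders; everything is generated in code at test time

straight_track <- function(n_frames = 61, v = 1, dt = 0.5,
                           u = c(1, 0, 0), id = "straight") {
  u <- u / sqrt(sum(u^2))
  i <- seq_len(n_frames) - 1
  tibble::tibble(object_id = id, t = i * dt,
                 x = i * v * dt * u[1], y = i * v * dt * u[2],
                 z = i * v * dt * u[3])
}

random_track <- function(seed, n_frames = 20, dim = 3, dt = 0.5, id = "rnd") {
  set.seed(seed)
  m <- apply(matrix(rnorm(n_frames * dim), ncol = dim), 2, cumsum)
  out <- tibble::tibble(object_id = id, t = (seq_len(n_frames) - 1) * dt,
                        x = m[, 1], y = m[, 2])
  if (dim == 3) out$z <- m[, 3]
  out
}

# independent O(N^2) double-loop MSD oracle
msd_oracle <- function(m) {
  n_frames <- nrow(m)
  N <- n_frames - 1
  vapply(seq_len(N), function(n) {
    acc <- 0
    for (i in 0:(N - n)) {
      d <- m[i + n + 1, ] - m[i + 1, ]
      acc <- acc + sum(d^2)
    }
    acc / (N - n + 1)
  }, numeric(1))
}

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed, dim = 3) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(dim^2), dim))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(df, rot, shift) {
  m <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
  df$x <- m[, 1] + shift[1]
  df$y <- m[, 2] + shift[2]
  df$z <- m[, 3] + shift[3]
  df
}

rigid_dataset <- function(ds, rot, shift) {
  ds$tracks <- apply_rigid(ds$tracks, rot, shift)
  ds$events <- apply_rigid(ds$events, rot, shift)
  ds
}

# minimal hand-built dataset: one cell, constant cc at origin, cs orbit-free,
# configurable event geometry
toy_dataset <- function(cs_offset = c(3, 0, 0), p_pos = c(20, 0, 0),
                        t_grid = seq(0, 40, by = 0.5), t_onset = 20,
                        outcome = "successful", mode = "BM") {
  tracks <- dplyr::bind_rows(
    tibble::tibble(cell_id = "c1", role = "centre", track_id = "cc",
                   t = t_grid, x = 0, y = 0, z = 0),
    tibble::tibble(cell_id = "c1", role = "centrosome", track_id = "cs1",
                   t = t_grid, x = cs_offset[1], y = cs_offset[2],
                   z = cs_offset[3])
  )
  events <- tibble::tibble(event_id = "e1", cell_id = "c1", t_onset = t_onset,
                           x = p_pos[1], y = p_pos[2], z = p_pos[3],
                           outcome = outcome, mode = mode)
  effero_dataset(tracks, events, metadata = list(dt = 0.5))
}
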