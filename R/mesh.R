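# Minimal triangle-mesh utilities for star-shaped (radial) surfaces.
# These exist to supply exact polyhedral (V, A) pairs to the sphericity
# analysis: for any closed polyhedron the isoperimetric inequality gives
# psi < 1, and a refined sphere mesh converges to psi = 1, so they act as a
# discrete-geometry oracle for shape tests.

#' Triangulated star-shaped surface
#'
#' Builds a closed lat-long triangulation of the surface
#' `r(theta, phi) * (sin t cos p, sin t sin p, cos t)` for a positive radius
#' function of the polar angle `theta` in `[0, pi]` and azimuth `phi` in
#' `[0, 2 pi)`. The mesh is closed (pole fans plus split quads) and
#' consistently oriented outward, so [mesh_volume_area()] returns the exact
#' volume and area of the polyhedron.
#'
#' @param radius_fn Function `(theta, phi) -> r > 0`, vectorised.
#' @param n_theta,n_phi Number of polar and azimuthal subdivisions.
#' @return List with `vertices` (matrix n x 3) and `faces` (integer matrix
#'   m x 3, 1-based, outward orientation).
#' @export
star_mesh <- function(radius_fn, n_theta = 64, n_phi = 128) {
  theta <- seq(0, pi, length.out = n_theta + 1)[-c(1, n_theta + 1)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(phi = phi, theta = theta) # phi varies fastest
  r <- radius_fn(g$theta, g$phi)
  if (any(r <= 0)) abort("radius function must be positive everywhere")
  grid_v <- cbind(
    r * sin(g$theta) * cos(g$phi),
    r * sin(g$theta) * sin(g$phi),
    r * cos(g$theta)
  )
  r_n <- radius_fn(0, 0)
  r_s <- radius_fn(pi, 0)
  vertices <- rbind(c(0, 0, r_n), c(0, 0, -r_s), grid_v)
  idx <- function(i, j) 2L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- vector("list", 3)
  j <- seq_len(n_phi)
  # north pole fan (outward = counter-clockwise seen from +z)
  faces[[1]] <- cbind(1L, idx(1L, j), idx(1L, j + 1L))
  # south pole fan
  nt <- length(theta)
  faces[[2]] <- cbind(2L, idx(nt, j + 1L), idx(nt, j))
  # interior quads
  if (nt > 1) {
    quads <- lapply(seq_len(nt - 1L), function(i) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      a2 <- idx(i, j + 1L); b2 <- idx(i + 1L, j + 1L)
      rbind(cbind(a, b, b2), cbind(a, b2, a2))
    })
    faces[[3]] <- do.call(rbind, quads)
  }
  list(vertices = vertices, faces = do.call(rbind, faces))
}

#' Exact volume and surface area of a closed triangle mesh
#'
#' Surface area is the sum of triangle areas; volume is the sum of signed
#' tetrahedron volumes against the origin (exact for a closed, consistently
#' oriented mesh; the absolute value is returned).
#'
#' @param mesh A list with `vertices` and `faces` as from [star_mesh()].
#' @return Tibble with one row: `V` (volume) and `A` (area).
#' @export
mesh_volume_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  area <- sum(vec_norm(cr)) / 2
  vol <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
             p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
             p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  tibble(V = abs(vol), A = area)
}

#' @rdname star_mesh
#' @param a,b,c Semi-axes of an ellipsoid.
#' @export
ellipsoid_mesh <- function(a = 1, b = 1, c = 1, n_theta = 64, n_phi = 128) {
  m <- star_mesh(function(th, ph) rep(1, length(th)), n_theta, n_phi)
  m$vertices <- m$vertices %*% diag(c(a, b, c))
  m
}

#' @rdname star_mesh
#' @param seed Integer seed for the random smooth radial perturbation.
#' @param roughness Maximum relative radial perturbation (< 1).
#' @export
random_star_mesh <- function(seed, roughness = 0.3, n_theta = 48, n_phi = 96) {
  set.seed(seed)
  k <- sample(1:4, 3, replace = TRUE)
  m_az <- sample(0:4, 3, replace = TRUE)
  amp <- stats::runif(3, 0, roughness / 3)
  ph0 <- stats::runif(3, 0, 2 * pi)
  radius_fn <- function(th, ph) {
    r <- rep(1, length(th))
    for (i in 1:3) {
      # sin(theta) factor keeps the perturbation closed at the poles
      r <- r + amp[i] * sin(th) * cos(k[i] * th) * cos(m_az[i] * ph + ph0[i])
    }
    r
  }
  star_mesh(radius_fn, n_theta, n_phi)
}
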