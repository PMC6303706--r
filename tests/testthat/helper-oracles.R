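# Independent brute-force oracles used across the geometry and KDE tests.
# These deliberately avoid the package's own code paths.

# fan-triangulation polygon area: sum of signed triangle areas (v1, vi, vi+1)
fan_area <- function(p) {
  v1 <- p[1L, ]
  s <- 0
  for (i in 2:(nrow(p) - 1L)) {
    a <- p[i, ] - v1; b <- p[i + 1L, ] - v1
    s <- s + (a[1L] * b[2L] - a[2L] * b[1L]) / 2
  }
  abs(unname(s))
}

# fan-decomposition centroid: signed-area-weighted mean of triangle centroids
fan_centroid <- function(p) {
  v1 <- p[1L, ]
  acc <- c(0, 0); a_tot <- 0
  for (i in 2:(nrow(p) - 1L)) {
    a <- p[i, ] - v1; b <- p[i + 1L, ] - v1
    tri_a <- (a[1L] * b[2L] - a[2L] * b[1L]) / 2
    tri_c <- (v1 + p[i, ] + p[i + 1L, ]) / 3
    acc <- acc + tri_a * tri_c
    a_tot <- a_tot + tri_a
  }
  unname(acc / a_tot)
}

# O(n^3) convex hull vertex set: a point is a hull vertex iff it is the start
# of a directed edge with every other point strictly on (or touching) its left
oracle_hull_vertices <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    e <- pts[j, ] - pts[i, ]
    cr <- (pts[, 1L] - pts[i, 1L]) * e[2L] - (pts[, 2L] - pts[i, 2L]) * e[1L]
    if (all(cr <= tol)) { on_hull[i] <- TRUE; break }
  }
  pts[on_hull, , drop = FALSE]
}

sort_rows <- function(m) m[order(m[, 1L], m[, 2L]), , drop = FALSE]

# exhaustive O(n^2) nearest-neighbor scan
oracle_nnd <- function(pts) {
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    min(sqrt(rowSums(sweep(pts[-i, , drop = FALSE], 2L, pts[i, ])^2)))
  }, numeric(1))
}

# random star-shaped (hence simple) polygon around the origin
random_star_polygon <- function(n = 30L, r_range = c(0.5, 1.5)) {
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_range[1L], r_range[2L])
  cbind(r * cos(theta), r * sin(theta))
}

# grid quadrature of the integrated squared difference of two Gaussian KDEs
quadrature_ise <- function(A, B, H_A, H_B, grid_n = 351L) {
  sdm <- sqrt(max(diag(H_A), diag(H_B)))
  xr <- range(c(A[, 1L], B[, 1L])) + c(-5, 5) * sdm
  yr <- range(c(A[, 2L], B[, 2L])) + c(-5, 5) * sdm
  gx <- seq(xr[1L], xr[2L], length.out = grid_n)
  gy <- seq(yr[1L], yr[2L], length.out = grid_n)
  mix <- function(pts, H) {
    Hi <- solve(H); dt <- det(H)
    z <- matrix(0, grid_n, grid_n)
    for (i in seq_len(nrow(pts))) {
      dx <- outer(gx - pts[i, 1L], rep(1, grid_n))
      dy <- outer(rep(1, grid_n), gy - pts[i, 2L])
      q <- Hi[1, 1] * dx^2 + 2 * Hi[1, 2] * dx * dy + Hi[2, 2] * dy^2
      z <- z + exp(-q / 2) / (2 * pi * sqrt(dt))
    }
    z / nrow(pts)
  }
  d <- (mix(A, H_A) - mix(B, H_B))^2
  sum(d) * diff(gx)[1L] * diff(gy)[1L]
}

# small synthetic study on a reduced site design, for pipeline-level tests
tiny_manifest <- function() {
  as_study_manifest(data.frame(
    population_id = c("A1", "A2", "C1", "C2", "C3"),
    site_name = paste("site", 1:5),
    species = c("E_anna", "E_anna", rep("E_carunculatum", 3)),
    latitude = 40 + 1:5, longitude = -110 - 1:5, year = 2015,
    patry = c("sympatric", "locally_allopatric",
              "sympatric", "locally_allopatric", "allopatric"),
    n_specimens = c(4L, 3L, 4L, 4L, 5L),
    stringsAsFactors = FALSE))
}
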