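test_that("polygon area matches closed forms and the fan-triangulation oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1.0)
  expect_equal(polygon_area(cbind(c(0, 1, 0), c(0, 0, 1))), 0.5)
  # winding invariance
  expect_equal(polygon_area(sq[4:1, ]), 1.0)
  # 12-gon approximating a circle, against the independent fan oracle
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  dodeca <- cbind(2.3 * cos(th), 2.3 * sin(th))
  expect_equal(polygon_area(dodeca), fan_area(dodeca), tolerance = 1e-12)
  expect_error(polygon_area(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
  expect_error(polygon_area(cbind(c(0, 1), c(0, 0))), ">= 3")
})

test_that("polygon centroid is area-weighted and winding-invariant", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(unname(polygon_centroid(sq)), c(0.5, 0.5))
  tri <- cbind(c(0, 3, 0), c(0, 0, 3))
  expect_equal(unname(polygon_centroid(tri)), c(1, 1))
  # L-shape vs rectangle-decomposition oracle:
  # [0,2]x[0,1] (area 2, center (1,.5)) + [0,1]x[1,2] (area 1, center (.5,1.5))
  L <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))
  expect_equal(unname(polygon_centroid(L)),
               c((2 * 1 + 1 * 0.5) / 3, (2 * 0.5 + 1 * 1.5) / 3))
  expect_equal(polygon_centroid(L[6:1, ]), polygon_centroid(L))
  expect_error(polygon_centroid(cbind(0:2, 0:2)), "degenerate")
})

test_that("area scales quadratically and centroid is rigid-motion equivariant", {
  set.seed(11)
  for (rep in 1:20) {
    p <- random_star_polygon(25L)
    k <- runif(1, 0.2, 4)
    expect_equal(polygon_area(p * k), k^2 * polygon_area(p), tolerance = 1e-9)
    ang <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    shift <- runif(2, -5, 5)
    moved <- sweep(p %*% R, 2L, shift, `+`)
    expect_equal(unname(polygon_centroid(moved)),
                 unname(drop(polygon_centroid(p) %*% R) + shift),
                 tolerance = 1e-9)
  }
})

test_that("convex hull matches the brute-force oracle on random point sets", {
  sq_plus <- rbind(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), c(0.5, 0.5))
  h <- convex_hull(sq_plus)
  expect_equal(nrow(h), 4L)
  expect_equal(polygon_area(h), 1.0)
  expect_equal(nrow(convex_hull(cbind(c(0, 2, 1), c(0, 0, 2)))), 3L)
  set.seed(7)
  for (rep in 1:10) {
    pts <- matrix(runif(100), ncol = 2)
    h <- convex_hull(pts)
    expect_equal(unname(sort_rows(h)),
                 unname(sort_rows(oracle_hull_vertices(pts))))
    # all points on or left of every CCW hull edge
    for (i in seq_len(nrow(h))) {
      a <- h[i, ]; b <- h[if (i == nrow(h)) 1L else i + 1L, ]
      cr <- (b[1L] - a[1L]) * (pts[, 2L] - a[2L]) -
        (b[2L] - a[2L]) * (pts[, 1L] - a[1L])
      expect_true(all(cr >= -1e-9))
    }
    # idempotence: hull of hull vertices is the same vertex set
    expect_equal(sort_rows(convex_hull(h)), sort_rows(h))
  }
  expect_error(convex_hull(cbind(c(0, 1), c(0, 0))), ">= 3")
  expect_error(convex_hull(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))), "collinear")
})

test_that("hull output is counterclockwise starting at the smallest vertex", {
  set.seed(21)
  pts <- matrix(rnorm(60), ncol = 2)
  h <- convex_hull(pts)
  expect_gt(sensimorph:::signed_area(h), 0)
  expect_equal(which.min(h[, 1L] * 1e6 + h[, 2L]), 1L)
})

test_that("nearest-neighbor distances match the exhaustive scan", {
  expect_equal(nearest_neighbor_distances(cbind(c(0, 5), c(0, 0))), c(5, 5))
  grid <- as.matrix(expand.grid(0:2, 0:2))
  expect_equal(nearest_neighbor_distances(grid), rep(1, 9))
  set.seed(3)
  pts <- matrix(runif(200), ncol = 2)
  expect_equal(nearest_neighbor_distances(pts), oracle_nnd(pts),
               tolerance = 1e-12)
  expect_equal(min(nearest_neighbor_distances(pts)), min(dist(pts)))
  expect_error(nearest_neighbor_distances(cbind(1, 1)), ">= 2")
  expect_warning(nearest_neighbor_distances(rbind(c(1, 1), c(1, 1), c(3, 3))),
                 "duplicate")
})

test_that("standardize_cloud yields unit area, origin centroid, preserved ratios", {
  sq2 <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  cl <- standardize_cloud(sq2, rbind(c(1, 1)))
  expect_equal(polygon_area(cl$outline), 1.0, tolerance = 1e-12)
  expect_equal(unname(polygon_centroid(cl$outline)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(cl$points[1L, ]), c(0, 0), tolerance = 1e-12)
  # idempotence
  cl2 <- standardize_cloud(cl$outline, cl$points)
  expect_equal(cl2$outline, cl$outline, tolerance = 1e-12)
  expect_equal(cl2$points, cl$points, tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:10) {
    poly <- sweep(random_star_polygon(40L) * runif(1, 50, 400), 2L,
                  runif(2, 0, 500), `+`)
    pts <- sample_sensilla(default_templates()$E_carunculatum, poly, 20L)
    cl <- standardize_cloud(poly, pts)
    expect_equal(polygon_area(cl$outline), 1.0, tolerance = 1e-9)
    expect_lt(max(abs(polygon_centroid(cl$outline))), 1e-9)
    d_pre <- as.numeric(dist(pts)); d_post <- as.numeric(dist(cl$points))
    expect_equal(d_post / d_post[1L], d_pre / d_pre[1L], tolerance = 1e-9)
    # invariance to a prior similarity transform (up to that rotation)
    ang <- runif(1, 0, 2 * pi); k <- runif(1, 0.5, 2)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    cl_t <- standardize_cloud(sweep(poly %*% R * k, 2L, c(7, -3), `+`),
                              sweep(pts %*% R * k, 2L, c(7, -3), `+`))
    expect_equal(polygon_area(cl_t$outline), 1.0, tolerance = 1e-9)
    expect_lt(max(abs(polygon_centroid(cl_t$outline))), 1e-9)
    expect_equal(unname(cl_t$outline), unname(cl$outline %*% R),
                 tolerance = 1e-9)
  }
})

test_that("simplicity checker distinguishes simple from self-intersecting", {
  expect_true(is_simple_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_false(is_simple_polygon(bowtie))
})

test_that("point-in-polygon counts boundary points as inside", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  q <- rbind(c(0.5, 0.5), c(0, 0), c(0.5, 1), c(1.0001, 0.5), c(-0.2, 0.5))
  expect_equal(points_in_polygon(q, sq, tol = 1e-9),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
})
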