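test_that("normal-scale bandwidth follows the closed form and is equivariant", {
  set.seed(17)
  X <- matrix(rnorm(2000), ncol = 2)
  H <- select_bandwidth(X)
  expect_equal(unclass(H), nrow(X)^(-1 / 3) * cov(X), tolerance = 1e-12,
               ignore_attr = TRUE)
  # for a standard normal sample, H ~ n^(-1/3) I entry-wise within 15%
  expect_equal(unname(diag(H)), rep(nrow(X)^(-1 / 3), 2), tolerance = 0.15)
  ang <- pi / 4
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  H_rot <- select_bandwidth(X %*% R)
  expect_equal(unclass(H_rot), t(R) %*% H %*% R, tolerance = 1e-9,
               ignore_attr = TRUE)
  line <- cbind(1:20, 2 * (1:20))
  expect_error(select_bandwidth(line), "singular|jitter")
  expect_error(select_bandwidth(X[1:5, ]), ">= 10")
})

test_that("plug-in bandwidth is positive-definite and data-adaptive", {
  set.seed(23)
  X <- rbind(matrix(rnorm(300, -2, 0.5), ncol = 2),
             matrix(rnorm(300, 2, 0.5), ncol = 2))
  Hp <- select_bandwidth(X, "plugin")
  ev <- eigen(unclass(Hp), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_identical(attr(Hp, "method"), "plugin")
  # bimodal data need less smoothing than the normal reference suggests
  Hn <- select_bandwidth(X, "normal_scale")
  expect_lt(det(unclass(Hp)), det(unclass(Hn)))
})

test_that("KDE evaluation matches the single-kernel closed form", {
  one <- matrix(c(0.3, -0.2), 1)
  dm <- evaluate_kde(one, diag(2), grid_n = 101L)
  at <- function(x, y) {
    i <- which.min(abs(dm$x - x)); j <- which.min(abs(dm$y - y))
    c(dm$z[i, j], dm$x[i] - x, dm$y[j] - y)
  }
  ctr <- at(0.3, -0.2)
  expect_equal(ctr[1L], 1 / (2 * pi), tolerance = 1e-3)
  r <- 1.5
  off <- at(0.3 + r, -0.2)
  expect_equal(off[1L], exp(-(r + off[2L])^2 / 2) / (2 * pi), tolerance = 1e-3)
  # n identical points are equivalent to a single point
  many <- one[rep(1, 7), , drop = FALSE]
  dm2 <- evaluate_kde(many, diag(2), grid_n = 101L)
  expect_equal(dm2$z, dm$z, tolerance = 1e-12)
})

test_that("density models conserve probability mass", {
  set.seed(31)
  X <- matrix(rnorm(1000), ncol = 2)
  dm <- evaluate_kde(X, select_bandwidth(X))
  expect_gte(dm$integral, 0.99); expect_lte(dm$integral, 1.01)
  expect_true(all(dm$z >= 0))
})

test_that("ISE statistic matches analytic and quadrature oracles", {
  H <- diag(2)
  A <- matrix(c(0, 0), 1)
  expect_equal(ise_statistic(A, A, H, H), 0, tolerance = 1e-12)
  # two unit-bandwidth kernels distance delta apart:
  # T = 2 phi_2I(0) - 2 phi_2I(delta) = (1/(4pi)) (2 - 2 exp(-delta^2/4))
  for (delta in c(0.5, 1.3, 2.8)) {
    B <- matrix(c(delta, 0), 1)
    expect_equal(ise_statistic(A, B, H, H),
                 (1 / (4 * pi)) * (2 - 2 * exp(-delta^2 / 4)),
                 tolerance = 1e-12)
    expect_equal(ise_statistic(A, B, H, H), quadrature_ise(A, B, H, H),
                 tolerance = 1e-3)
  }
  set.seed(37)
  X <- matrix(rnorm(40, 0, 0.7), ncol = 2)
  Y <- matrix(rnorm(50, 0.4, 0.9), ncol = 2)
  H_X <- select_bandwidth(X); H_Y <- select_bandwidth(Y)
  T_exact <- ise_statistic(X, Y, H_X, H_Y)
  expect_equal(T_exact, quadrature_ise(X, Y, unclass(H_X), unclass(H_Y)),
               tolerance = 1e-3 * T_exact + 1e-8)
})

test_that("ISE is invariant under simultaneous rotation of both samples", {
  set.seed(41)
  X <- matrix(rnorm(60), ncol = 2); Y <- matrix(rnorm(60, 0.5), ncol = 2)
  T0 <- ise_statistic(X, Y, select_bandwidth(X), select_bandwidth(Y))
  ang <- 1.1
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  T1 <- ise_statistic(X %*% R, Y %*% R,
                      select_bandwidth(X %*% R), select_bandwidth(Y %*% R))
  expect_equal(T1, T0, tolerance = 1e-9)
})

test_that("two-sample test degenerates correctly at the limits", {
  tpl <- default_templates()$E_carunculatum
  A <- simulate_population_clouds(tpl, 4, seed = 2, n_vertices = 150)
  res_same <- kde_two_sample_test(A, A, n_perm = 99, seed = 5)
  expect_equal(res_same$T_obs, 0, tolerance = 1e-12)
  expect_equal(res_same$p_value, 1)
  # a large rigid shift separates the populations; female-level splits can
  # tie with the observed labeling (C(8,4) distinct splits), so the p-value
  # is small but bounded below by the tie rate, while point-level
  # permutation reaches the add-one floor
  B <- lapply(A, function(cl) {
    cl$points <- sweep(cl$points, 2L, c(10, 0), `+`); cl
  })
  res_far <- kde_two_sample_test(A, B, n_perm = 199, seed = 5)
  expect_lte(res_far$p_value, 0.06)
  res_pt <- kde_two_sample_test(A, B, n_perm = 199, seed = 5, unit = "point")
  expect_equal(res_pt$p_value, 1 / 200)
  expect_error(kde_two_sample_test(A[1], A, n_perm = 99), ">= 2 females")
})

test_that("BH adjustment matches the hand-applied step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.5, 4)), rep(0.5, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj <= 1))
  expect_error(fdr_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("pairwise table covers all pairs, applies FDR, honors exclusion", {
  tpl <- default_templates()$E_carunculatum
  pops <- lapply(1:4, function(i)
    simulate_population_clouds(tpl, 4, seed = 10 + i, n_vertices = 150))
  names(pops) <- paste0("P", 1:4)
  # one population with strongly shifted placement
  pops$P4 <- simulate_population_clouds(tpl, 4, seed = 14, n_vertices = 150,
                                        location_shift = c(-0.45, 0))
  tab <- pairwise_kde_tests(pops, min_n = 4, n_perm = 99, seed = 3)
  expect_s3_class(tab, "kde_comparison_table")
  expect_equal(nrow(tab), choose(4, 2))
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15))
  pm <- attr(tab, "p_matrix")
  expect_equal(pm, t(pm))
  # the planted outlier dominates the smallest adjusted p-values
  outlier_rows <- tab$pop_a == "P4" | tab$pop_b == "P4"
  expect_lt(min(tab$p_adj[outlier_rows]), min(tab$p_adj[!outlier_rows]))
  # exclusion switch recomputes FDR on the remaining pairs
  tab2 <- pairwise_kde_tests(pops[c("P1", "P2", "P3")], min_n = 4,
                             n_perm = 99, seed = 3)
  expect_equal(nrow(tab2), 3L)
  sub <- tab[!outlier_rows, ]
  expect_equal(tab2$p_adj, fdr_adjust(sub$p_raw), tolerance = 1e-12)
  expect_error(pairwise_kde_tests(pops[1], min_n = 4, n_perm = 99), ">= 2")
})

test_that("per-pair seeds make the pairwise table reproducible", {
  tpl <- default_templates()$E_carunculatum
  pops <- lapply(1:3, function(i)
    simulate_population_clouds(tpl, 4, seed = 20 + i, n_vertices = 150))
  names(pops) <- c("X", "Y", "Z")
  t1 <- pairwise_kde_tests(pops, min_n = 4, n_perm = 99, seed = 77)
  t2 <- pairwise_kde_tests(pops, min_n = 4, n_perm = 99, seed = 77)
  expect_equal(t1$p_raw, t2$p_raw)
  expect_equal(t1$T, t2$T)
})

test_that("percentile contours nest and enclose the advertised mass", {
  set.seed(53)
  X <- matrix(rnorm(800, 0, 1), ncol = 2)
  dm <- evaluate_kde(X, select_bandwidth(X))
  ct <- percentile_contours(dm)
  expect_equal(names(ct), c("p25", "p50", "p75"))
  expect_true(all(ct$p75$mask <= ct$p50$mask))
  expect_true(all(ct$p50$mask <= ct$p25$mask))
  expect_equal(ct$p75$mass, 0.25, tolerance = 0.02)
  expect_equal(ct$p50$mass, 0.50, tolerance = 0.02)
  expect_true(ct$p75$level >= ct$p50$level)
  all_support <- percentile_contours(dm, percentiles = 0)[[1L]]
  expect_true(all(all_support$mask == (dm$z > 0)))
  # radially symmetric single-Gaussian model: contours concentric and nested
  dm1 <- evaluate_kde(matrix(0, 1, 2), diag(2), grid_n = 101L)
  ct1 <- percentile_contours(dm1)
  expect_true(all(ct1$p75$mask <= ct1$p25$mask))
  expect_equal(length(ct1$p75$polylines), 1L)
})

test_that("equal-distribution permutation p-values are reproducible under seed", {
  tpl <- default_templates()$E_carunculatum
  A <- simulate_population_clouds(tpl, 3, seed = 61, n_vertices = 150)
  B <- simulate_population_clouds(tpl, 3, seed = 62, n_vertices = 150)
  r1 <- kde_two_sample_test(A, B, n_perm = 99, seed = 9)
  r2 <- kde_two_sample_test(A, B, n_perm = 99, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- kde_two_sample_test(A, B, n_perm = 99, seed = 9, unit = "point")
  expect_true(r3$p_value >= 0 && r3$p_value <= 1)
})
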