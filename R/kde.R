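#' Population-level spatial comparison of sensilla clouds
#'
#' Size-standardized sensilla clouds are pooled within populations and
#' compared with a two-sample kernel density test: the statistic is the
#' integrated squared error (ISE) between the two Gaussian-kernel density
#' estimates, computed exactly through the Gaussian convolution identity, and
#' the null distribution is obtained by permuting whole female clouds between
#' the two populations (points within a female share a plate and are not
#' exchangeable). P-values across population pairs are Benjamini-Hochberg
#' adjusted.
#'
#' @name spatial_kde
#' @keywords internal
NULL

# Run code with a temporary RNG state seeded at `seed`; restores the caller's
# stream afterwards so pipeline stages do not perturb each other.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  code
}

# deterministic seed derived from a master seed and a label (polynomial
# rolling hash mod 2^31 - 1); keeps derived seeds in 32-bit integer range
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  h
}

check_bandwidth <- function(H) {
  stopifnot(is.matrix(H), nrow(H) == 2L, ncol(H) == 2L)
  if (max(abs(H - t(H))) > 1e-8 * max(abs(H)))
    stop("bandwidth matrix must be symmetric", call. = FALSE)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("bandwidth matrix must be positive-definite", call. = FALSE)
  invisible(H)
}

#' Select a bandwidth matrix for a bivariate sample
#'
#' \code{normal_scale} (default): the closed-form normal-reference matrix
#' \eqn{H = (4/(d+2))^{2/(d+4)} n^{-2/(d+4)} \hat\Sigma}, which for d = 2
#' reduces to \eqn{n^{-1/3}\hat\Sigma}. \code{plugin}: a two-stage
#' unconstrained plug-in — the order-4 integrated density-derivative
#' functionals are estimated with a normal-reference Gaussian pilot (exact
#' fourth-order Gaussian derivative tensors), and the estimated AMISE is then
#' minimized numerically over symmetric positive-definite matrices in a
#' log-Cholesky parameterization.
#'
#' @param points two-column matrix (>= 10 points, non-singular covariance).
#' @param method \code{"normal_scale"} or \code{"plugin"}.
#' @return 2x2 bandwidth matrix with attribute \code{method}.
#' @export
select_bandwidth <- function(points, method = c("normal_scale", "plugin")) {
  method <- match.arg(method)
  points <- as_xy_matrix(points)
  n <- nrow(points)
  if (n < 10L) stop("bandwidth selection needs >= 10 points", call. = FALSE)
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev) || max(ev) == 0)
    stop("singular sample covariance (collinear points); jitter the data",
         call. = FALSE)
  H <- n^(-1 / 3) * S  # (4/(d+2))^(2/(d+4)) = 1 at d = 2
  if (method == "plugin") H <- plugin_bandwidth(points, S, H)
  structure(H, method = method)
}

# Exact mixed 4th-order partial derivative sums of a centered Gaussian with
# covariance G, evaluated at all pairwise differences; returns the 2x2x2x2
# psi-functional estimate used by the plug-in AMISE.
psi4_hat <- function(points, G) {
  n <- nrow(points)
  A <- solve(G)
  i1 <- rep(seq_len(n), each = n)
  i2 <- rep(seq_len(n), times = n)
  D <- points[i1, , drop = FALSE] - points[i2, , drop = FALSE]
  U <- D %*% A                       # u = G^{-1} d, one row per pair
  quad <- rowSums(D * U)
  phi <- exp(-quad / 2) / (2 * pi * sqrt(det(G)))
  psi <- array(0, c(2, 2, 2, 2))
  pairs2 <- utils::combn(4L, 2L)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    idx <- c(i, j, k, l)
    term_u4 <- U[, i] * U[, j] * U[, k] * U[, l]
    term_au2 <- 0
    for (c2 in seq_len(ncol(pairs2))) {
      sel <- pairs2[, c2]
      rest <- setdiff(1:4, sel)
      term_au2 <- term_au2 +
        A[idx[sel[1L]], idx[sel[2L]]] * U[, idx[rest[1L]]] * U[, idx[rest[2L]]]
    }
    term_a2 <- A[i, j] * A[k, l] + A[i, k] * A[j, l] + A[i, l] * A[j, k]
    psi[i, j, k, l] <- mean(phi * (term_u4 - term_au2 + term_a2)) # n^-2 sum
  }
  psi
}

plugin_bandwidth <- function(points, S, H_init) {
  n <- nrow(points)
  d <- 2
  G <- (4 / ((d + 4) * n))^(2 / (d + 6)) * S  # normal-reference pilot
  psi <- psi4_hat(points, G)
  amise <- function(theta) {
    L <- matrix(c(exp(theta[1L]), theta[2L], 0, exp(theta[3L])), 2, 2)
    H <- L %*% t(L)
    curv <- 0
    for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2)
      curv <- curv + H[i, j] * H[k, l] * psi[i, j, k, l]
    1 / (4 * pi * n * sqrt(det(H))) + curv / 4
  }
  L0 <- t(chol(H_init))
  th0 <- c(log(L0[1L, 1L]), L0[2L, 1L], log(L0[2L, 2L]))
  fit <- stats::optim(th0, amise, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  L <- matrix(c(exp(fit$par[1L]), fit$par[2L], 0, exp(fit$par[3L])), 2, 2)
  L %*% t(L)
}

# Mean over all (x in X, y in Y) pairs of the bivariate Gaussian density
# phi_S(x - y); the building block of the exact ISE.
mean_cross_gauss <- function(X, Y, S) {
  R <- chol(S)
  Xw <- t(backsolve(R, t(X), transpose = TRUE))
  Yw <- t(backsolve(R, t(Y), transpose = TRUE))
  d2 <- outer(rowSums(Xw^2), rowSums(Yw^2), `+`) - 2 * tcrossprod(Xw, Yw)
  d2[d2 < 0] <- 0
  mean(exp(-d2 / 2)) / (2 * pi * prod(diag(R)))
}

#' Integrated squared error between two kernel density estimates
#'
#' \eqn{T = \int (\hat f_A - \hat f_B)^2 dx}, computed exactly (no grid) via
#' the convolution identity
#' \eqn{\int \phi_{H_1}(x-a)\phi_{H_2}(x-b)\,dx = \phi_{H_1+H_2}(a-b)}:
#' the three terms use kernels \eqn{2H_A}, \eqn{2H_B} and \eqn{H_A+H_B}.
#' T is zero iff the two kernel mixtures coincide.
#'
#' @param A,B two-column point matrices.
#' @param H_A,H_B bandwidth matrices for the two samples.
#' @return Non-negative scalar.
#' @export
ise_statistic <- function(A, B, H_A, H_B) {
  A <- as_xy_matrix(A); B <- as_xy_matrix(B)
  check_bandwidth(H_A); check_bandwidth(H_B)
  t_aa <- mean_cross_gauss(A, A, 2 * H_A)
  t_bb <- mean_cross_gauss(B, B, 2 * H_B)
  t_ab <- mean_cross_gauss(A, B, H_A + H_B)
  max(t_aa + t_bb - 2 * t_ab, 0)
}

cloud_points <- function(cl) {
  if (inherits(cl, "standardized_cloud")) cl$points else as_xy_matrix(cl)
}

#' Two-sample permutation KDE test for two populations
#'
#' Pools the per-female standardized clouds of each population, computes the
#' ISE statistic between the two pooled density estimates, and compares it
#' with its permutation distribution. The permutation unit defaults to the
#' female: whole clouds are relabeled between populations, preserving the
#' within-female dependence of points that share a plate (point-level
#' permutation is available for comparison). Bandwidths are re-selected
#' within every permutation replicate. The p-value uses the add-one
#' estimator \eqn{(1 + \#\{T^* \ge T\})/(n_{perm}+1)} and is never exactly
#' zero.
#'
#' @param A_clouds,B_clouds lists of per-female clouds
#'   (\code{standardized_cloud} objects or point matrices).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @param unit \code{"female"} (default) or \code{"point"}.
#' @param bandwidth selector passed to \code{\link{select_bandwidth}}.
#' @return List with \code{T_obs}, \code{p_value}, \code{n_perm},
#'   \code{unit}, and per-side female/point counts.
#' @export
kde_two_sample_test <- function(A_clouds, B_clouds, n_perm = 999, seed = NULL,
                                unit = c("female", "point"),
                                bandwidth = c("normal_scale", "plugin")) {
  unit <- match.arg(unit)
  bandwidth <- match.arg(bandwidth)
  stopifnot(n_perm >= 99)
  A_list <- lapply(A_clouds, cloud_points)
  B_list <- lapply(B_clouds, cloud_points)
  if (unit == "female" && (length(A_list) < 2L || length(B_list) < 2L))
    stop("female-level permutation needs >= 2 females per population",
         call. = FALSE)
  A <- do.call(rbind, A_list)
  B <- do.call(rbind, B_list)
  if (nrow(A) < 10L || nrow(B) < 10L)
    stop("each pooled population needs >= 10 points", call. = FALSE)
  stat <- function(X, Y) ise_statistic(X, Y,
                                       select_bandwidth(X, bandwidth),
                                       select_bandwidth(Y, bandwidth))
  T_obs <- stat(A, B)
  T_perm <- with_seed(seed, {
    if (unit == "female") {
      all_clouds <- c(A_list, B_list)
      nA <- length(A_list); ntot <- length(all_clouds)
      vapply(seq_len(n_perm), function(r) {
        idx <- sample.int(ntot)
        stat(do.call(rbind, all_clouds[idx[seq_len(nA)]]),
             do.call(rbind, all_clouds[idx[-seq_len(nA)]]))
      }, numeric(1))
    } else {
      all_pts <- rbind(A, B)
      nA <- nrow(A); ntot <- nrow(all_pts)
      vapply(seq_len(n_perm), function(r) {
        idx <- sample.int(ntot)
        stat(all_pts[idx[seq_len(nA)], , drop = FALSE],
             all_pts[idx[-seq_len(nA)], , drop = FALSE])
      }, numeric(1))
    }
  })
  eps <- 1e-9 * max(T_obs, T_perm, 1e-300)  # count ties as exceedances
  p <- (1 + sum(T_perm >= T_obs - eps)) / (n_perm + 1)
  list(T_obs = T_obs, p_value = p, n_perm = n_perm, unit = unit,
       n_females = c(A = length(A_list), B = length(B_list)),
       n_points = c(A = nrow(A), B = nrow(B)))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, clipped at 1
#' (wraps \code{stats::p.adjust}).
#'
#' @param p_values numeric vector in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Pool the standardized clouds of one population
#'
#' Concatenates per-female sensilla coordinates, retaining per-point specimen
#' provenance in the \code{"specimen_id"} attribute.
#'
#' @param clouds non-empty list of \code{standardized_cloud}s from one
#'   population.
#' @return Point matrix with a \code{specimen_id} attribute.
#' @export
pool_population <- function(clouds) {
  if (!length(clouds)) stop("no clouds to pool", call. = FALSE)
  pts <- do.call(rbind, lapply(clouds, cloud_points))
  ids <- unlist(lapply(seq_along(clouds), function(i) {
    cl <- clouds[[i]]
    id <- if (inherits(cl, "standardized_cloud") && !is.null(cl$specimen_id))
      cl$specimen_id else paste0("cloud", i)
    rep(id, nrow(cloud_points(cl)))
  }))
  attr(pts, "specimen_id") <- ids
  pts
}

#' Evaluate a kernel density estimate on a grid
#'
#' Gaussian-kernel density of the pooled points on a regular lattice covering
#' the data plus a margin of \code{margin} bandwidth standard deviations. If
#' the Riemann sum of the grid deviates from 1 by more than 1 percent the
#' grid is refined once and a warning is issued.
#'
#' @param points pooled two-column point matrix.
#' @param H bandwidth matrix (see \code{\link{select_bandwidth}}).
#' @param grid_n grid resolution per axis (default 151).
#' @param margin margin in units of the largest bandwidth SD (default 3).
#' @param population_id optional label carried in the result.
#' @return Object of class \code{density_model}: list with \code{points},
#'   \code{H}, grid axes \code{x}, \code{y}, density matrix \code{z}
#'   (\code{z[i, j]} at \code{x[i], y[j]}), and \code{integral}.
#' @export
evaluate_kde <- function(points, H, grid_n = 151L, margin = 3,
                         population_id = NULL) {
  points <- as_xy_matrix(points)
  check_bandwidth(H)
  build <- function(grid_n, margin) {
    sd_max <- sqrt(max(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
    xr <- range(points[, 1L]) + c(-1, 1) * margin * sd_max
    yr <- range(points[, 2L]) + c(-1, 1) * margin * sd_max
    gx <- seq(xr[1L], xr[2L], length.out = grid_n)
    gy <- seq(yr[1L], yr[2L], length.out = grid_n)
    R <- chol(H)
    Pw <- t(backsolve(R, t(points), transpose = TRUE))
    p2 <- rowSums(Pw^2)
    norm_const <- 2 * pi * prod(diag(R)) * nrow(points)
    z <- matrix(0, grid_n, grid_n)
    block <- max(1L, floor(2e6 / nrow(points)))
    grid_xy <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
    for (start in seq(1L, nrow(grid_xy), by = block)) {
      rows <- start:min(start + block - 1L, nrow(grid_xy))
      Gw <- t(backsolve(R, t(grid_xy[rows, , drop = FALSE]), transpose = TRUE))
      d2 <- outer(rowSums(Gw^2), p2, `+`) - 2 * tcrossprod(Gw, Pw)
      d2[d2 < 0] <- 0
      z[rows] <- rowSums(exp(-d2 / 2)) / norm_const
    }
    cell <- (gx[2L] - gx[1L]) * (gy[2L] - gy[1L])
    list(x = gx, y = gy, z = z, integral = sum(z) * cell)
  }
  g <- build(grid_n, margin)
  if (abs(g$integral - 1) > 0.01) {
    warning("KDE grid integral off by >1%; refining grid")
    g <- build(2L * grid_n + 1L, margin + 1)
  }
  structure(list(points = points, H = H, x = g$x, y = g$y, z = g$z,
                 integral = g$integral, population_id = population_id),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat("<density_model>",
      if (!is.null(x$population_id)) paste0(" population ", x$population_id),
      "\n  ", nrow(x$points), " points, ", length(x$x), "x", length(x$y),
      " grid, integral ", format(x$integral, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Highest-density percentile regions of a density model
#'
#' For each percentile q, the highest-density region of grid cells containing
#' the top (100 - q) percent of probability mass — the display convention in
#' which the "75th-percentile" band encloses the densest quarter of the
#' distribution. Regions nest by construction.
#'
#' @param model a \code{density_model}.
#' @param percentiles increasing percentiles (default \code{c(25, 50, 75)}).
#' @return List with one element per percentile: \code{level} (density
#'   threshold), \code{mask} (logical grid matrix), \code{mass} (probability
#'   mass enclosed), and \code{polylines} (closed contour polylines from
#'   \code{grDevices::contourLines}).
#' @export
percentile_contours <- function(model, percentiles = c(25, 50, 75)) {
  stopifnot(inherits(model, "density_model"))
  cell <- (model$x[2L] - model$x[1L]) * (model$y[2L] - model$y[1L])
  mass <- model$z * cell / model$integral
  ord <- order(model$z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  out <- lapply(percentiles, function(q) {
    stopifnot(q >= 0, q < 100)
    target <- (100 - q) / 100
    if (q == 0) {
      level <- 0
      mask <- model$z > 0
    } else {
      k <- which(cum >= target)[1L]
      if (is.na(k)) k <- length(ord)
      level <- model$z[ord[k]]
      mask <- model$z >= level
    }
    polylines <- grDevices::contourLines(model$x, model$y, model$z,
                                         levels = max(level, 1e-300))
    list(percentile = q, level = level, mask = mask,
         mass = sum(mass[mask]), polylines = polylines)
  })
  names(out) <- paste0("p", percentiles)
  out
}

#' Pairwise KDE comparisons across populations
#'
#' Runs the two-sample permutation KDE test for every unordered pair of
#' eligible populations (those with at least \code{min_n} females), then
#' adjusts the raw p-values by Benjamini-Hochberg across the pair set.
#' Per-pair permutation seeds are derived deterministically from the master
#' seed and the sorted pair position, so the table is reproducible and
#' insensitive to evaluation order.
#'
#' @param pop_clouds named list: population_id -> list of that population's
#'   \code{standardized_cloud}s (one per female).
#' @param min_n eligibility threshold on females per population (default 4).
#' @param n_perm permutations per test (default 999).
#' @param seed master seed.
#' @param alpha significance level for the flag column (default 0.05).
#' @param bandwidth,unit passed to \code{\link{kde_two_sample_test}}.
#' @return Data frame of class \code{kde_comparison_table} with one row per
#'   pair: populations, female/point counts, \code{T}, \code{p_raw},
#'   \code{p_adj}, \code{significant}; the symmetric adjusted-p matrix is in
#'   attribute \code{"p_matrix"}.
#' @export
pairwise_kde_tests <- function(pop_clouds, min_n = 4L, n_perm = 999,
                               seed = 1L, alpha = 0.05,
                               bandwidth = c("normal_scale", "plugin"),
                               unit = c("female", "point")) {
  bandwidth <- match.arg(bandwidth)
  unit <- match.arg(unit)
  eligible <- names(pop_clouds)[vapply(pop_clouds, length, 0L) >= min_n]
  if (length(eligible) < 2L)
    stop("need >= 2 populations with at least ", min_n, " females",
         call. = FALSE)
  eligible <- sort(eligible)
  pairs <- utils::combn(eligible, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    pair_seed <- derive_seed(seed, paste(a, b))
    res <- kde_two_sample_test(pop_clouds[[a]], pop_clouds[[b]],
                               n_perm = n_perm, seed = pair_seed,
                               unit = unit, bandwidth = bandwidth)
    data.frame(pop_a = a, pop_b = b,
               n_females_a = res$n_females[["A"]],
               n_females_b = res$n_females[["B"]],
               n_points_a = res$n_points[["A"]],
               n_points_b = res$n_points[["B"]],
               T = res$T_obs, p_raw = res$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- fdr_adjust(tab$p_raw)
  tab$significant <- tab$p_adj < alpha
  pm <- matrix(NA_real_, length(eligible), length(eligible),
               dimnames = list(eligible, eligible))
  diag(pm) <- 1
  for (r in seq_len(nrow(tab))) {
    pm[tab$pop_a[r], tab$pop_b[r]] <- tab$p_adj[r]
    pm[tab$pop_b[r], tab$pop_a[r]] <- tab$p_adj[r]
  }
  attr(tab, "p_matrix") <- pm
  class(tab) <- c("kde_comparison_table", "data.frame")
  tab
}
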