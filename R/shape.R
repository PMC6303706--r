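#' Outline landmarks and generalized Procrustes mean shapes
#'
#' Digitized plate outlines carry many hundreds of vertices, varying between
#' females. Each outline is resampled to a fixed 200-point scheme — the lower
#' and upper medial corners as fixed landmarks plus 198 semilandmarks — and
#' population mean shapes are obtained by generalized Procrustes analysis
#' (GPA): iterative removal of translation, scale, and rotation followed by
#' consensus averaging. Reflections are excluded (plates are
#' orientation-standardized upstream). Optional tangent sliding of the
#' semilandmarks minimizes their Procrustes distance to the consensus.
#'
#' @name shape_gpa
#' @keywords internal
NULL

centroid_size <- function(X) sqrt(sum(sweep(X, 2L, colMeans(X))^2))

# Ensure counterclockwise traversal; keeps track of a vertex index mapping.
ensure_ccw <- function(p) {
  if (signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

chain_lengths <- function(p) {
  nxt <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
  sqrt(rowSums((nxt - p)^2))
}

# Interpolate points at arc-length positions s (strictly inside the chain)
# along an open polyline given by vertices `chain`.
interp_chain <- function(chain, s) {
  seg <- sqrt(rowSums(diff(chain)^2))
  cum <- c(0, cumsum(seg))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(seg)] <- length(seg)
  frac <- (s - cum[idx]) / seg[idx]
  chain[idx, , drop = FALSE] +
    (chain[idx + 1L, , drop = FALSE] - chain[idx, , drop = FALSE]) * frac
}

#' Resample a plate outline to a 200-point landmark set
#'
#' Retains the two designated corner vertices exactly and places
#' \code{n_between} semilandmarks along the two corner-to-corner outline
#' segments. \code{arc_length} (default) spaces them equally by arc length,
#' with the 198 points allocated to the two segments in proportion to their
#' lengths — deterministic and digitization-invariant. \code{random} draws
#' existing vertices uniformly without replacement (the legacy subsampling
#' procedure), reproducibly under \code{seed}. Traversal is normalized to
#' counterclockwise; the output starts at the lower medial corner.
#'
#' @param outline polygon matrix (>= 200 vertices for \code{random} mode).
#' @param corner_indices length-2 integer vector: row indices of the lower
#'   and upper medial corner vertices in \code{outline}.
#' @param n_between number of semilandmarks (default 198).
#' @param mode \code{"arc_length"} or \code{"random"}.
#' @param seed seed for \code{random} mode.
#' @return Landmark matrix of \code{n_between + 2} rows with attributes
#'   \code{corners} (indices of the two fixed landmarks in the output: 1 and
#'   k*) and \code{specimen_id} if supplied.
#' @param specimen_id optional identifier.
#' @export
resample_outline <- function(outline, corner_indices, n_between = 198L,
                             mode = c("arc_length", "random"), seed = NULL,
                             specimen_id = NULL) {
  mode <- match.arg(mode)
  outline <- as_xy_matrix(outline, "outline vertices")
  n <- nrow(outline)
  ci <- as.integer(corner_indices)
  if (length(ci) != 2L || any(ci < 1L | ci > n) || ci[1L] == ci[2L])
    stop("corner indices must be two distinct outline vertex indices",
         call. = FALSE)
  if (signed_area(outline) < 0) {  # normalize to counterclockwise
    outline <- outline[rev(seq_len(n)), , drop = FALSE]
    ci <- n + 1L - ci
  }
  # rotate so the lower medial corner is vertex 1
  ord <- c(ci[1L]:n, seq_len(ci[1L] - 1L))[seq_len(n)]
  if (ci[1L] == 1L) ord <- seq_len(n)
  outline <- outline[ord, , drop = FALSE]
  upper <- match(ci[2L], ord)
  if (mode == "random" && n < n_between + 2L)
    stop("outline has fewer vertices than requested landmarks", call. = FALSE)
  if (mode == "arc_length") {
    chain1 <- outline[1:upper, , drop = FALSE]                 # lower -> upper
    chain2 <- rbind(outline[upper:n, , drop = FALSE], outline[1L, , drop = FALSE])
    L1 <- sum(sqrt(rowSums(diff(chain1)^2)))
    L2 <- sum(sqrt(rowSums(diff(chain2)^2)))
    n1 <- round(n_between * L1 / (L1 + L2))
    n1 <- min(max(n1, 0L), n_between)
    n2 <- n_between - n1
    s1 <- if (n1 > 0) seq_len(n1) * L1 / (n1 + 1L) else numeric(0)
    s2 <- if (n2 > 0) seq_len(n2) * L2 / (n2 + 1L) else numeric(0)
    lm <- rbind(outline[1L, , drop = FALSE],
                interp_chain(chain1, s1),
                outline[upper, , drop = FALSE],
                interp_chain(chain2, s2))
    k_star <- n1 + 2L
  } else {
    pool <- setdiff(seq_len(n), c(1L, upper))
    keep <- with_seed(seed, sort(sample(pool, n_between)))
    idx <- sort(c(1L, upper, keep))
    lm <- outline[idx, , drop = FALSE]
    k_star <- match(upper, idx)
    lm <- rbind(lm[match(1L, idx):nrow(lm), , drop = FALSE],
                lm[seq_len(match(1L, idx) - 1L), , drop = FALSE])
    k_star <- ((k_star - match(1L, idx)) %% nrow(lm)) + 1L
  }
  structure(lm, corners = c(1L, k_star), specimen_id = specimen_id,
            class = c("landmark_set", class(lm)))
}

# Optimal rotation (no reflection) aligning X onto Y; both centered.
optimal_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  sv <- svd(M)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)  # X %*% R best approximates Y
}

center_scale <- function(X) {
  X <- sweep(X, 2L, colMeans(X))
  X / centroid_size(X)
}

#' Procrustes distance between two configurations
#'
#' Root summed squared difference after centering, unit-size scaling, and
#' optimal rotation (reflections excluded).
#'
#' @param A,B landmark matrices with corresponding rows.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(A, B) {
  A <- center_scale(as_xy_matrix(A)); B <- center_scale(as_xy_matrix(B))
  sqrt(sum((A %*% optimal_rotation(A, B) - B)^2))
}

#' Generalized Procrustes alignment and consensus shape
#'
#' Iterative GPA: each configuration is centered and scaled to unit centroid
#' size, rotated to the running consensus by the optimal orthogonal rotation
#' (reflections disallowed), and the consensus is recomputed, until the
#' consensus moves less than \code{tol} (RMS) or \code{max_iter} iterations.
#' Optionally one tangent-sliding pass of the semilandmarks per iteration.
#'
#' @param shapes list of landmark matrices with equal row counts and
#'   corresponding indices (>= 2 shapes).
#' @param tol consensus convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @param slide slide semilandmarks toward the consensus along local tangents
#'   (default FALSE).
#' @param fixed indices of landmarks that never slide; defaults to the
#'   \code{corners} attribute of the first shape, if present.
#' @param slide_passes number of initial iterations that include a sliding
#'   pass (default 3). Minimum-distance sliding leaves the position of a
#'   semilandmark along the outline unconstrained, so unbounded repeated
#'   sliding lets points drift along the curve; a small fixed number of
#'   passes removes most tangential digitization noise while keeping the
#'   superimposition convergent.
#' @return List with \code{aligned} (list of aligned configurations),
#'   \code{mean} (consensus: centered, unit centroid size), \code{iterations},
#'   \code{converged}.
#' @export
gpa_align <- function(shapes, tol = 1e-10, max_iter = 100L, slide = FALSE,
                      fixed = NULL, slide_passes = 3L) {
  stopifnot(length(shapes) >= 2L)
  mats <- lapply(shapes, as_xy_matrix)
  k <- unique(vapply(mats, nrow, 0L))
  if (length(k) != 1L)
    stop("all shapes must have the same number of landmarks", call. = FALSE)
  if (any(vapply(mats, centroid_size, 0) == 0))
    stop("degenerate shape with zero centroid size", call. = FALSE)
  if (is.null(fixed)) fixed <- attr(shapes[[1L]], "corners")
  mats <- lapply(mats, center_scale)
  consensus <- mats[[1L]]
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    mats <- lapply(mats, function(X) X %*% optimal_rotation(X, consensus))
    if (slide && length(fixed) && it <= slide_passes)
      mats <- slide_semilandmarks(mats, consensus, fixed)
    new_consensus <- center_scale(Reduce(`+`, mats) / length(mats))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  mats <- lapply(mats, function(X) X %*% optimal_rotation(X, consensus))
  list(aligned = mats, mean = consensus, iterations = iterations,
       converged = converged)
}

#' Slide semilandmarks along local outline tangents
#'
#' One Gauss-Seidel pass: every non-fixed landmark moves along the tangent
#' direction estimated from its cyclic neighbors, by the projection of its
#' offset from the consensus onto that tangent — the position on the tangent
#' line closest to the consensus landmark. Fixed landmarks (the plate
#' corners) never move; the pass never increases the summed squared distance
#' to the consensus.
#'
#' @param aligned list of GPA-aligned landmark matrices.
#' @param consensus consensus configuration.
#' @param fixed indices of fixed landmarks.
#' @return List of adjusted landmark matrices.
#' @export
slide_semilandmarks <- function(aligned, consensus, fixed) {
  k <- nrow(consensus)
  sliders <- setdiff(seq_len(k), fixed)
  lapply(aligned, function(X) {
    for (j in sliders) {
      prv <- if (j == 1L) k else j - 1L
      nxt <- if (j == k) 1L else j + 1L
      tangent <- X[nxt, ] - X[prv, ]
      len <- sqrt(sum(tangent^2))
      if (len == 0) next
      tangent <- tangent / len
      X[j, ] <- X[j, ] + tangent * sum((consensus[j, ] - X[j, ]) * tangent)
    }
    X
  })
}

#' Population mean plate shapes
#'
#' GPA consensus shape for every population with at least \code{min_n}
#' landmark sets (the same eligibility rule as the KDE comparisons).
#' Populations of a single female are returned as that female's standardized
#' configuration.
#'
#' @param landmarks_by_population named list: population_id -> list of
#'   landmark matrices (one per female).
#' @param min_n eligibility threshold (default 4).
#' @param ... passed to \code{\link{gpa_align}}.
#' @return Named list of consensus matrices (centered, unit centroid size)
#'   with attribute \code{n_shapes} on each.
#' @export
population_mean_shapes <- function(landmarks_by_population, min_n = 4L, ...) {
  eligible <- names(landmarks_by_population)[
    vapply(landmarks_by_population, length, 0L) >= min_n]
  out <- lapply(landmarks_by_population[eligible], function(sets) {
    m <- if (length(sets) == 1L) center_scale(as_xy_matrix(sets[[1L]]))
         else gpa_align(sets, ...)$mean
    attr(m, "n_shapes") <- length(sets)
    m
  })
  out
}
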