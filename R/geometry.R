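#' Planar geometry primitives for plate morphometrics
#'
#' Polygons are plain two-column numeric matrices of vertices in traversal
#' order; the closing edge (last vertex back to first) is implicit. Sensilla
#' point sets are two-column matrices as well. All functions work in the input
#' units (micrometres for raw digitized plates, dimensionless after
#' standardization).
#'
#' @name geometry
#' @keywords internal
NULL

as_xy_matrix <- function(x, what = "points") {
  m <- as.matrix(x)
  if (is.null(dim(m)) || ncol(m) < 2L)
    stop(what, " must have two numeric columns (x, y)", call. = FALSE)
  m <- m[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m)))
    stop(what, " contain non-finite coordinates", call. = FALSE)
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

# Signed shoelace area (positive for counterclockwise traversal).
signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace formula)
#'
#' Absolute area of a simple polygon, independent of winding direction.
#'
#' @param p polygon: two-column matrix of ordered vertices (implicitly closed).
#' @return Positive area in squared input units.
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # 1
#' @export
polygon_area <- function(p) {
  p <- as_xy_matrix(p, "polygon vertices")
  if (nrow(p) < 3L) stop("polygon needs >= 3 vertices", call. = FALSE)
  a <- abs(signed_area(p))
  scale2 <- max(abs(p))^2
  if (a <= 1e-12 * max(scale2, 1))
    stop("degenerate (collinear) polygon: area is zero", call. = FALSE)
  a
}

#' Polygon centroid (area centroid)
#'
#' Area-weighted centroid of a simple polygon (first moments divided by the
#' signed area), which is invariant to how densely the outline was digitized —
#' unlike the vertex mean.
#'
#' @inheritParams polygon_area
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(p) {
  p <- as_xy_matrix(p, "polygon vertices")
  if (nrow(p) < 3L) stop("polygon needs >= 3 vertices", call. = FALSE)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) <= 1e-12 * max(max(abs(p))^2, 1))
    stop("degenerate (collinear) polygon: centroid undefined", call. = FALSE)
  c(x = sum((x + xn) * cross) / (6 * a),
    y = sum((y + yn) * cross) / (6 * a))
}

#' Convex hull of a point set
#'
#' Minimal convex polygon containing all points. Vertices are returned in
#' counterclockwise order starting from the lexicographically smallest vertex;
#' points lying on (but not spanning) a hull edge are excluded from the vertex
#' list, so the output is byte-stable under boundary densification.
#'
#' @param points two-column matrix of point coordinates.
#' @return Polygon matrix of hull vertices.
#' @export
convex_hull <- function(points) {
  points <- as_xy_matrix(points)
  if (nrow(points) < 3L) stop("convex hull needs >= 3 points", call. = FALSE)
  idx <- grDevices::chull(points[, 1L], points[, 2L])  # clockwise order
  hull <- points[rev(idx), , drop = FALSE]             # -> counterclockwise
  if (nrow(hull) >= 3L) {
    # prune collinear triples left on hull edges
    keep <- rep(TRUE, nrow(hull))
    n <- nrow(hull)
    for (i in seq_len(n)) {
      a <- hull[if (i == 1L) n else i - 1L, ]
      b <- hull[i, ]
      c_ <- hull[if (i == n) 1L else i + 1L, ]
      cr <- (b[1L] - a[1L]) * (c_[2L] - a[2L]) - (b[2L] - a[2L]) * (c_[1L] - a[1L])
      if (abs(cr) <= 1e-12 * max(max(abs(hull))^2, 1)) keep[i] <- FALSE
    }
    hull <- hull[keep, , drop = FALSE]
  }
  if (nrow(hull) < 3L)
    stop("all points are collinear: hull area undefined", call. = FALSE)
  start <- order(hull[, 1L], hull[, 2L])[1L]
  if (start > 1L) hull <- hull[c(start:nrow(hull), 1:(start - 1L)), , drop = FALSE]
  hull
}

#' Nearest-neighbor distances within a point set
#'
#' For each point, the Euclidean distance to its closest other point, in input
#' order. Duplicate points produce zero distances (with a warning) rather than
#' an error: coincident sensilla can arise from digitization double-clicks and
#' are a QC matter, not a geometry one.
#'
#' @param points two-column matrix with at least two rows.
#' @return Numeric vector of length \code{nrow(points)}.
#' @export
nearest_neighbor_distances <- function(points) {
  points <- as_xy_matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("nearest-neighbor distances need >= 2 points", call. = FALSE)
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  nnd <- apply(d, 1L, min)
  if (any(nnd == 0)) warning("duplicate points: zero nearest-neighbor distance")
  unname(nnd)
}

#' Standardize a plate to unit area and centroid origin
#'
#' Scales the outline and its sensilla jointly by \code{1/sqrt(area)} so the
#' outline has area exactly 1, then translates both so the outline's area
#' centroid sits at the origin. Relative positions of sensilla within the
#' plate (all distance ratios) are preserved, making clouds comparable across
#' females of different sizes.
#'
#' @param outline polygon matrix (the plate boundary).
#' @param points two-column matrix of sensilla coordinates in the same frame.
#' @param specimen_id optional identifier carried through to pooling.
#' @return An object of class \code{standardized_cloud}: a list with
#'   \code{outline}, \code{points}, and \code{specimen_id}.
#' @export
standardize_cloud <- function(outline, points, specimen_id = NULL) {
  outline <- as_xy_matrix(outline, "polygon vertices")
  points <- as_xy_matrix(points)
  s <- 1 / sqrt(polygon_area(outline))
  outline <- outline * s
  points <- points * s
  ctr <- polygon_centroid(outline)
  outline <- sweep(outline, 2L, ctr)
  points <- sweep(points, 2L, ctr)
  structure(list(outline = outline, points = points, specimen_id = specimen_id),
            class = "standardized_cloud")
}

#' @export
print.standardized_cloud <- function(x, ...) {
  cat("<standardized_cloud>",
      if (!is.null(x$specimen_id)) paste0(" specimen ", x$specimen_id), "\n",
      "  outline: ", nrow(x$outline), " vertices (area 1); sensilla: ",
      nrow(x$points), " points\n", sep = "")
  invisible(x)
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Exhaustive O(n^2) check of all non-adjacent edge pairs for proper or
#' improper intersection. Intended for validation and generator-contract
#' tests; not run on every record construction because digitized outlines
#' carry many hundreds of vertices.
#'
#' @inheritParams polygon_area
#' @return Logical scalar.
#' @export
is_simple_polygon <- function(p) {
  p <- as_xy_matrix(p, "polygon vertices")
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  a1 <- p; a2 <- p[nxt, , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip edges adjacent to edge i (share a vertex)
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_intersect(a1[i, ], a2[i, ],
                               a1[js, , drop = FALSE], a2[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# vectorized proper/improper segment intersection: segment (p1,p2) vs rows of (q1,q2)
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- (q2[, 1L] - q1[, 1L]) * (p1[2L] - q1[, 2L]) -
        (q2[, 2L] - q1[, 2L]) * (p1[1L] - q1[, 1L])
  d2 <- (q2[, 1L] - q1[, 1L]) * (p2[2L] - q1[, 2L]) -
        (q2[, 2L] - q1[, 2L]) * (p2[1L] - q1[, 1L])
  d3 <- (p2[1L] - p1[1L]) * (q1[, 2L] - p1[2L]) -
        (p2[2L] - p1[2L]) * (q1[, 1L] - p1[1L])
  d4 <- (p2[1L] - p1[1L]) * (q2[, 2L] - p1[2L]) -
        (p2[2L] - p1[2L]) * (q2[, 1L] - p1[1L])
  (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorized ray-casting test; points exactly on the boundary count as
#' inside, matching the convention that boundary sensilla belong to the plate.
#'
#' @param points two-column matrix of query points.
#' @param poly polygon matrix.
#' @param tol boundary tolerance in input units.
#' @return Logical vector, one entry per query point.
#' @export
points_in_polygon <- function(points, poly, tol = 1e-9) {
  points <- as_xy_matrix(points)
  poly <- as_xy_matrix(poly, "polygon vertices")
  inside <- .pip_crossing(points, poly)
  if (tol > 0 && any(!inside)) {
    check <- which(!inside)
    inside[check] <- .near_boundary(points[check, , drop = FALSE], poly, tol)
  }
  inside
}

# even-odd crossing test, boundary not handled specially (vectorized over
# the points x edges matrix)
.pip_crossing <- function(points, poly) {
  n <- nrow(poly); m <- nrow(points)
  px <- points[, 1L]; py <- points[, 2L]
  xi <- poly[, 1L]; yi <- poly[, 2L]
  jj <- c(n, seq_len(n - 1L))
  xj <- xi[jj]; yj <- yi[jj]
  PY <- matrix(py, m, n)
  YI <- matrix(yi, m, n, byrow = TRUE)
  straddles <- (YI > PY) != (matrix(yj, m, n, byrow = TRUE) > PY)
  slope <- (xj - xi) / (yj - yi)  # Inf/NaN rows are masked by `straddles`
  xint <- matrix(xi, m, n, byrow = TRUE) +
    (PY - YI) * matrix(slope, m, n, byrow = TRUE)
  crosses <- straddles & (matrix(px, m, n) < xint)
  rowSums(crosses) %% 2L == 1L
}

.near_boundary <- function(points, poly, tol) {
  n <- nrow(poly)
  px <- points[, 1L]; py <- points[, 2L]
  near <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    ex <- poly[i, 1L] - poly[j, 1L]; ey <- poly[i, 2L] - poly[j, 2L]
    len2 <- ex * ex + ey * ey
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((px - poly[j, 1L]) * ex +
                              (py - poly[j, 2L]) * ey) / len2))
      d2 <- (poly[j, 1L] + t * ex - px)^2 + (poly[j, 2L] + t * ey - py)^2
      near <- near | d2 <= tol^2
    }
    j <- i
  }
  near
}
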