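## Polygon primitives shared by every analysis stage.
##
## A polygon is an open ring: a numeric matrix with >= 3 rows and columns
## (x, y) in metres (projected CRS); the closing edge back to row 1 is
## implicit. Interiors overlapping with positive area counts as "overlap";
## mere boundary contact does not.

#' Validate a polygon ring
#'
#' Checks that `p` is a numeric two-column matrix with at least three
#' distinct vertices, finite coordinates, strictly positive area and a
#' simple (non-self-intersecting) ring.
#'
#' @param p Numeric matrix, one vertex per row, columns x and y (metres).
#' @param what Label used in error messages.
#' @return `p`, invisibly, with any repeated closing vertex dropped.
#' @export
validate_polygon <- function(p, what = "polygon") {
  if (!is.matrix(p) || !is.numeric(p) || ncol(p) != 2)
    stop(what, " must be a numeric matrix with columns (x, y)", call. = FALSE)
  if (!all(is.finite(p)))
    stop(what, " has non-finite coordinates", call. = FALSE)
  n <- nrow(p)
  if (n >= 4 && all(p[1, ] == p[n, ])) {
    p <- p[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (nrow(unique(p)) < 3)
    stop(what, " needs at least 3 distinct vertices", call. = FALSE)
  if (!ring_is_simple(p))
    stop(what, " ring is self-intersecting", call. = FALSE)
  if (abs(polygon_area(p)) <= 0)
    stop(what, " has zero area", call. = FALSE)
  invisible(p)
}

ring_is_simple <- function(p) {
  n <- nrow(p)
  idx <- seq_len(n)
  nxt <- c(idx[-1], 1L)
  for (i in idx) {
    for (j in idx) {
      if (j <= i) next
      # skip adjacent edges (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a, b, c, d) {
  o <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- o(c, d, a); d2 <- o(c, d, b); d3 <- o(a, b, c); d4 <- o(a, b, d)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Signed shoelace area of a ring
#' @param p Polygon matrix.
#' @return Signed area in square metres (positive for counter-clockwise).
#' @export
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Perimeter of a ring
#' @param p Polygon matrix.
#' @return Perimeter in metres.
#' @export
polygon_perimeter <- function(p) {
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((q - p)^2)))
}

#' Area centroid of a polygon
#'
#' The "centre point" used throughout: the area (shoelace) centroid, which
#' is rotation-invariant and serves as the pivot for rigid rotations.
#'
#' @param p Polygon matrix.
#' @return Numeric length-2 vector (x, y).
#' @export
centre_point <- function(p) {
  a <- polygon_area(p)
  if (abs(a) <= 0) stop("zero-area polygon has no centroid", call. = FALSE)
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Edge-to-edge distance between two polygons
#'
#' Minimum Euclidean distance between the boundaries/interiors of two
#' polygons: exactly 0 when they touch, cross or one contains the other.
#'
#' @param a,b Polygon matrices.
#' @return Distance in metres (>= 0).
#' @export
edge_distance <- function(a, b) {
  a <- validate_polygon(a, "a"); b <- validate_polygon(b, "b")
  cpp_edge_distance(a, b)
}

#' Do two polygon interiors overlap with positive area?
#'
#' Boundary contact alone (shared edge or vertex) is not overlap.
#' Intersection area at or below `tol` square metres counts as
#' non-overlapping, so grazing floating-point contacts are tolerated.
#'
#' @param a,b Polygon matrices.
#' @param tol Area tolerance in m^2.
#' @return Logical.
#' @export
overlaps <- function(a, b, tol = 1e-9) {
  if (!bbox_overlap(bbox(a), bbox(b))) return(FALSE)
  # compiled classifier settles disjoint / crossing / containment pairs;
  # only boundary contact without a proper crossing needs the clipped area
  state <- cpp_overlap_state(a, b)
  if (state == 0L) return(FALSE)
  if (state != 3L) return(TRUE)
  intersection_area(a, b) > tol
}

#' Intersection area of two polygons
#' @param a,b Polygon matrices.
#' @return Area of the interior intersection in m^2.
#' @export
intersection_area <- function(a, b) {
  inter <- polyclip::polyclip(ring_list(a), ring_list(b), op = "intersection")
  if (length(inter) == 0) return(0)
  sum(vapply(inter, function(r) abs(polygon_area(cbind(r$x, r$y))), 0))
}

ring_list <- function(p) list(list(x = p[, 1], y = p[, 2]))

bbox <- function(p) c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))

bbox_overlap <- function(ba, bb, gap = 0) {
  !(bb[1] > ba[2] + gap || ba[1] > bb[2] + gap ||
      bb[3] > ba[4] + gap || ba[3] > bb[4] + gap)
}

#' Construct a rigid motion
#'
#' @param rotation_deg Rotation in degrees about the polygon's centroid
#'   (counter-clockwise).
#' @param translation Numeric length-2 vector (dx, dy) in metres.
#' @return An object of class `rigid_motion`.
#' @export
rigid_motion <- function(rotation_deg = 0, translation = c(0, 0)) {
  stopifnot(is.numeric(rotation_deg), length(rotation_deg) == 1,
            is.numeric(translation), length(translation) == 2)
  structure(list(rotation_deg = rotation_deg, translation = translation),
            class = "rigid_motion")
}

#' Apply a rigid motion to a polygon
#'
#' Rotates by `m$rotation_deg` about the polygon's area centroid, then
#' translates by `m$translation`. Area and perimeter are preserved.
#'
#' @param a Polygon matrix.
#' @param m A [rigid_motion()].
#' @return The moved polygon matrix.
#' @export
apply_motion <- function(a, m) {
  stopifnot(inherits(m, "rigid_motion"))
  out <- rotate_about(a, m$rotation_deg, centre_point(a))
  out[, 1] <- out[, 1] + m$translation[1]
  out[, 2] <- out[, 2] + m$translation[2]
  out
}

rotate_about <- function(p, deg, centre) {
  if (deg == 0) return(p)
  th <- deg * pi / 180
  co <- cos(th); si <- sin(th)
  dx <- p[, 1] - centre[1]; dy <- p[, 2] - centre[2]
  cbind(centre[1] + co * dx - si * dy,
        centre[2] + si * dx + co * dy)
}

translate_poly <- function(p, dx, dy) {
  p[, 1] <- p[, 1] + dx; p[, 2] <- p[, 2] + dy
  p
}

#' Convex hull of a set of points, optionally buffered
#'
#' Used for the default analysis window: the convex hull of all annotation
#' vertices dilated outward by `buffer` metres (round joins).
#'
#' @param xy Two-column matrix of points.
#' @param buffer Outward offset in metres (0 for the bare hull).
#' @return Polygon matrix.
#' @export
convex_hull_window <- function(xy, buffer = 0) {
  h <- xy[chull(xy), , drop = FALSE]
  if (buffer > 0) {
    off <- polyclip::polyoffset(ring_list(h)[[1]], buffer, jointype = "round")
    h <- cbind(off[[1]]$x, off[[1]]$y)
  }
  h
}

point_in_polygon <- function(x, y, p) {
  cpp_points_in_poly(as.numeric(x), as.numeric(y), p)
}
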