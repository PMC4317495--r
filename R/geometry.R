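# 2-D vector-geometry primitives used by the cortical-dynamics module and
# the track simulator. Polygons are n x 2 numeric matrices of vertices in
# micrometres, implicitly closed (last vertex joins the first). All
# predicates are boundary-inclusive: a point lying exactly on an edge is
# "inside", a segment touching a box border intersects it. Inclusive
# predicates make counts deterministic at shared borders.

#' Signed area of a polygon
#'
#' Positive for counter-clockwise vertex order (shoelace formula).
#'
#' @param poly n x 2 matrix of vertices.
#' @return signed area in squared input units.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon perimeter
#'
#' @param poly n x 2 matrix of vertices.
#' @return total edge length.
#' @export
polygon_perimeter <- function(poly) {
  d <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

# orient counter-clockwise; error on degenerate (zero-area) input
ensure_ccw <- function(poly) {
  a <- polygon_area(poly)
  if (abs(a) < .Machine$double.eps * 100)
    .fail("degenerate polygon (zero area)")
  if (a < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# check that no two non-adjacent edges intersect
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # edges sharing the closing vertex
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Distance from points to a line segment
#'
#' Vectorised over the points.
#'
#' @param px,py point coordinates.
#' @param ax,ay,bx,by segment endpoints.
#' @return numeric vector of Euclidean distances.
#' @export
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  degenerate <- len2 == 0
  t <- ((px - ax) * dx + (py - ay) * dy) / (len2 + degenerate)
  t <- pmin(1, pmax(0, t))
  t[rep_len(degenerate, length(t))] <- 0  # point-like segment
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Distance from a point to a polygon boundary
#'
#' Minimum over all edges of the point-to-segment distance; zero on the
#' boundary.
#'
#' @param p length-2 numeric (x, y).
#' @param poly n x 2 matrix of vertices.
#' @return non-negative distance.
#' @export
polygon_edge_distance <- function(p, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  min(dist_point_segment(p[1], p[2],
                         poly[, 1], poly[, 2],
                         poly[nxt, 1], poly[nxt, 2]))
}

# cross product of (b - a) and (c - a)
.cross3 <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

#' Do two segments intersect?
#'
#' Inclusive: shared endpoints and collinear overlap count as intersection.
#'
#' @param p1,p2 endpoints of the first segment (length-2 numerics).
#' @param q1,q2 endpoints of the second segment.
#' @return logical.
#' @export
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- .cross3(q1, q2, p1); d2 <- .cross3(q1, q2, p2)
  d3 <- .cross3(p1, p2, q1); d4 <- .cross3(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {  # c collinear with a-b: does c lie on a-b?
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (abs(d1) < 1e-12 && on_seg(q1, q2, p1)) ||
  (abs(d2) < 1e-12 && on_seg(q1, q2, p2)) ||
  (abs(d3) < 1e-12 && on_seg(p1, p2, q1)) ||
  (abs(d4) < 1e-12 && on_seg(p1, p2, q2))
}

#' Is a point inside (or on) a polygon?
#'
#' Even-odd ray casting with an explicit boundary check, so points on an
#' edge or vertex return `TRUE`.
#'
#' @param p length-2 numeric (x, y).
#' @param poly n x 2 matrix of vertices.
#' @param tol boundary tolerance in input units.
#' @return logical.
#' @export
point_in_polygon <- function(p, poly, tol = 1e-9) {
  if (polygon_edge_distance(p, poly) <= tol) return(TRUE)
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > p[2]) != (yj > p[2])) {
      xint <- poly[i, 1] + (p[2] - yi) / (yj - yi) * (poly[j, 1] - poly[i, 1])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# first crossing of directed segment p -> q with the polygon boundary:
# returns the parameter t in (0, 1] or Inf when the segment stays inside
segment_boundary_hit <- function(p, q, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  tmin <- Inf
  r <- q - p
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[nxt[i], ]
    s <- b - a
    denom <- r[1] * s[2] - r[2] * s[1]
    if (abs(denom) < 1e-15) next
    t <- ((a[1] - p[1]) * s[2] - (a[2] - p[2]) * s[1]) / denom
    u <- ((a[1] - p[1]) * r[2] - (a[2] - p[2]) * r[1]) / denom
    if (t > 1e-12 && t <= 1 && u >= -1e-12 && u <= 1 + 1e-12) tmin <- min(tmin, t)
  }
  tmin
}

#' Does a polyline intersect a polygon?
#'
#' True when any vertex lies inside/on the polygon or any polyline segment
#' crosses a polygon edge.
#'
#' @param line m x 2 matrix of polyline vertices.
#' @param poly n x 2 matrix of polygon vertices.
#' @return logical.
#' @export
polyline_intersects_polygon <- function(line, poly) {
  for (i in seq_len(nrow(line)))
    if (point_in_polygon(line[i, ], poly)) return(TRUE)
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  for (i in seq_len(nrow(line) - 1)) {
    for (j in seq_len(n)) {
      if (segments_intersect(line[i, ], line[i + 1, ],
                             poly[j, ], poly[nxt[j], ])) return(TRUE)
    }
  }
  FALSE
}

# uniform random point strictly inside a polygon (rejection sampling)
random_interior_point <- function(poly, margin = 0) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  for (i in 1:10000) {
    p <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
    if (point_in_polygon(p, poly) && polygon_edge_distance(p, poly) > margin)
      return(p)
  }
  .fail("could not sample an interior point; is the polygon degenerate?")
}
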