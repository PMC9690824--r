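## Planar geometry primitives for projected (meter) coordinates.
## Polygons are two-column matrices of vertices (x, y), not closed (the last
## vertex is joined back to the first implicitly). All operations assume a
## projected CRS; nothing here understands degrees.

#' Polygon area by the shoelace formula
#'
#' @param xy two-column numeric matrix of vertices in order (either winding).
#' @return area in squared input units (always nonnegative).
#' @examples
#' polygonArea(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))  # 2
#' @export
polygonArea <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) stop("polygon needs at least 3 vertices")
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:nrow(xy), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon centroid (area-weighted geometric centre)
#'
#' @param xy two-column vertex matrix.
#' @return length-2 numeric (x, y).
#' @export
polygonCentroid <- function(xy) {
  xy <- as.matrix(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:nrow(xy), 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(abs(xy))^2) {
    return(colMeans(xy))  # degenerate: fall back to vertex mean
  }
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Point-in-polygon test (ray casting)
#'
#' Vectorised even-odd crossing test. Points exactly on an edge may land on
#' either side; callers that care position grids so cell centres avoid edges.
#'
#' @param pts two-column matrix of query points.
#' @param poly two-column vertex matrix.
#' @return logical vector, TRUE for points inside.
#' @export
pointInPolygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- as.matrix(poly)
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Distance from points to a polygon
#'
#' Euclidean distance from each query point to the polygon: 0 for points
#' inside or on the boundary, otherwise the minimum distance to any edge.
#'
#' @param pts two-column matrix of query points.
#' @param poly two-column vertex matrix.
#' @return numeric vector of distances (meters for meter coordinates).
#' @export
distanceToPolygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- as.matrix(poly)
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  d2 <- rep(Inf, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  d <- sqrt(d2)
  d[pointInPolygon(pts, poly)] <- 0
  d
}

#' Axis-aligned rectangle as a polygon
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return 4 x 2 vertex matrix (counter-clockwise).
#' @export
rectPolygon <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Regular polygon approximating a circle
#'
#' @param center length-2 numeric (x, y).
#' @param radius circle radius.
#' @param n number of vertices (default 256).
#' @return n x 2 vertex matrix.
#' @export
circlePolygon <- function(center, radius, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

## Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman).
## Used to keep generated patches inside the study frame.
clipPolygonToRect <- function(poly, xmin, ymin, xmax, ymax) {
  clipEdge <- function(pts, inside, intersect) {
    if (nrow(pts) == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1L) n else i - 1L, ]
      curIn <- inside(cur); prevIn <- inside(prev)
      if (curIn) {
        if (!prevIn) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prevIn) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  p <- as.matrix(poly)
  p <- clipEdge(p, function(v) v[1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  p <- clipEdge(p, function(v) v[1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  p <- clipEdge(p, function(v) v[2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  p <- clipEdge(p, function(v) v[2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  p
}
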