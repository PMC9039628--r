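# Planar geometry in metres (UTM-like frame: x = easting, y = northing).
# Polygons are n x 2 matrices of vertices, open rings (first vertex not
# repeated); multipolygons are lists of such matrices with disjoint parts.

as_xy <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2)
    return(p)
  }
  if (is.data.frame(p)) return(cbind(p[[1]], p[[2]]))
  stopifnot(is.numeric(p), length(p) == 2)
  matrix(p, ncol = 2)
}

#' Compass azimuth from one point to another
#'
#' Bearing in degrees clockwise from north (grid north = +y), the convention
#' used by hand-held compasses and VHF receivers.
#'
#' @param from,to Points as length-2 numeric vectors `c(x, y)` or n x 2
#'   matrices (vectorised row-wise).
#' @return Azimuth(s) in degrees in `[0, 360)`.
#' @export
#' @examples
#' azimuth(c(0, 0), c(0, 100))  # due north: 0
#' azimuth(c(0, 0), c(100, 0))  # due east: 90
azimuth <- function(from, to) {
  from <- as_xy(from)
  to <- as_xy(to)
  dx <- to[, 1] - from[, 1]
  dy <- to[, 2] - from[, 2]
  if (any(dx == 0 & dy == 0)) {
    stop("azimuth is undefined between coincident points")
  }
  (atan2(dx, dy) * 180 / pi) %% 360
}

#' Forward intersection of two bearings (biangulation)
#'
#' Locates a transmitter at the intersection of the forward rays defined by
#' two bearings taken from distinct observer positions.
#'
#' @param origin1,origin2 Observer positions, length-2 numeric `c(x, y)`.
#' @param azimuth1,azimuth2 Bearings in degrees clockwise from north.
#' @return A list with `point` (the intersection) and `angle_deg`, the
#'   inter-bearing angle folded to `[0, 180]`.
#' @export
ray_intersection <- function(origin1, azimuth1, origin2, azimuth2) {
  o1 <- as.numeric(origin1)
  o2 <- as.numeric(origin2)
  if (all(o1 == o2)) stop("bearings must come from distinct observers")
  a1 <- azimuth1 * pi / 180
  a2 <- azimuth2 * pi / 180
  d1 <- c(sin(a1), cos(a1))
  d2 <- c(sin(a2), cos(a2))
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-12) stop("parallel bearings do not intersect")
  w <- o2 - o1
  t1 <- (w[1] * d2[2] - w[2] * d2[1]) / denom
  t2 <- (w[1] * d1[2] - w[2] * d1[1]) / denom
  if (t1 <= 1e-9 || t2 <= 1e-9) {
    stop("bearings diverge: no forward intersection")
  }
  list(point = o1 + t1 * d1, angle_deg = fold_angle(azimuth1 - azimuth2))
}

# fold an azimuth difference to the inter-bearing angle in [0, 180]
fold_angle <- function(delta_deg) {
  d <- abs(delta_deg) %% 360
  ifelse(d > 180, 360 - d, d)
}

signed_area <- function(poly) {
  poly <- drop_closing_vertex(poly)
  x <- poly[, 1]
  y <- poly[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

drop_closing_vertex <- function(poly) {
  n <- nrow(poly)
  if (n > 1 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly
}

#' Area of a simple polygon (surveyor's formula)
#'
#' @param poly An n x 2 vertex matrix (open or closed ring), or a list of
#'   such matrices whose areas are summed.
#' @return Area in squared input units.
#' @export
polygon_area <- function(poly) {
  if (is.list(poly) && !is.matrix(poly)) {
    return(sum(vapply(poly, polygon_area, numeric(1))))
  }
  abs(signed_area(poly))
}

ensure_ccw <- function(poly) {
  poly <- drop_closing_vertex(poly)
  if (signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}

is_convex <- function(poly) {
  poly <- drop_closing_vertex(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  e <- poly[nxt, , drop = FALSE] - poly
  cr <- e[, 1] * e[nxt, 2] - e[, 2] * e[nxt, 1]
  all(cr >= -1e-9 * max(abs(cr), 1)) || all(cr <= 1e-9 * max(abs(cr), 1))
}

# Sutherland-Hodgman clipping of a simple polygon against a convex window.
# Returns NULL when the intersection is empty or degenerate.
clip_convex <- function(subject, clip) {
  out <- drop_closing_vertex(subject)
  clip <- ensure_ccw(clip)
  if (!is_convex(clip)) stop("clip window must be convex")
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[i, ]
    b <- clip[i %% nc + 1, ]
    ex <- b[1] - a[1]
    ey <- b[2] - a[2]
    s <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    tol <- 1e-9 * max(abs(ex), abs(ey), 1)
    inside <- s >= -tol
    n <- nrow(out)
    keep <- vector("list", 2L * n)
    m <- 0L
    for (j in seq_len(n)) {
      k <- j %% n + 1
      if (inside[j]) {
        m <- m + 1L
        keep[[m]] <- out[j, ]
      }
      if (inside[j] != inside[k]) {
        t <- s[j] / (s[j] - s[k])
        m <- m + 1L
        keep[[m]] <- out[j, ] + t * (out[k, ] - out[j, ])
      }
    }
    out <- if (m >= 3L) do.call(rbind, keep[seq_len(m)]) else NULL
  }
  if (is.null(out) || nrow(out) < 3 || polygon_area(out) < 1e-9) return(NULL)
  out
}

# Exact intersection area of two multipolygons whose parts are disjoint and
# at least one side convex part-wise.
intersection_area <- function(a, b) {
  a <- as_multipolygon(a)
  b <- as_multipolygon(b)
  total <- 0
  for (pa in a) {
    for (pb in b) {
      if (!bbox_overlap(pa, pb)) next
      piece <- if (is_convex(pb)) {
        clip_convex(pa, pb)
      } else if (is_convex(pa)) {
        clip_convex(pb, pa)
      } else {
        stop("intersection of two non-convex parts is not supported")
      }
      if (!is.null(piece)) total <- total + polygon_area(piece)
    }
  }
  total
}

bbox_overlap <- function(a, b) {
  !(max(a[, 1]) < min(b[, 1]) || max(b[, 1]) < min(a[, 1]) ||
      max(a[, 2]) < min(b[, 2]) || max(b[, 2]) < min(a[, 2]))
}

as_multipolygon <- function(p) {
  if (is.matrix(p)) list(p) else p
}

rect_poly <- function(xmin, xmax, ymin, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# Boundary-inclusive point-in-polygon test, vectorised over points.
points_in_polygon <- function(x, y, poly) {
  poly <- drop_closing_vertex(poly)
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

points_in_multipolygon <- function(x, y, mp) {
  mp <- as_multipolygon(mp)
  inside <- rep(FALSE, length(x))
  for (part in mp) {
    idx <- !inside
    if (!any(idx)) break
    inside[idx] <- points_in_polygon(x[idx], y[idx], part)
  }
  inside
}

euclid <- function(p, q) {
  p <- as_xy(p)
  q <- as_xy(q)
  sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2)
}
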