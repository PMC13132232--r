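# Minimal planar geometry for survey polygons and transect lines.
# All coordinates are kilometres in a planar equal-area projection; no
# curved-earth corrections are attempted anywhere in the package.

#' Polygon area by the shoelace formula
#'
#' @param v two-column matrix of vertices (closed or open ring).
#' @return area in squared coordinate units (km^2).
#' @keywords internal
poly_area <- function(v) {
  v <- close_ring(v)
  n <- nrow(v)
  if (n < 4) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Polygon centroid (area-weighted)
#' @keywords internal
poly_centroid <- function(v) {
  v <- close_ring(v)
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v[-n, , drop = FALSE]))
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  c(cx, cy)
}

close_ring <- function(v) {
  v <- as.matrix(v)
  if (nrow(v) < 1) return(v)
  if (any(v[1, ] != v[nrow(v), ])) v <- rbind(v, v[1, ])
  v
}

open_ring <- function(v) {
  v <- as.matrix(v)
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  v
}

#' Validate a polygon ring: >= 3 vertices, finite, non-self-intersecting
#' @keywords internal
poly_validate <- function(v, label = "polygon") {
  v <- open_ring(v)
  if (nrow(v) < 3) stop(sprintf("%s has fewer than 3 vertices", label))
  if (!all(is.finite(v))) stop(sprintf("%s has non-finite coordinates", label))
  if (poly_area(v) <= 0) stop(sprintf("%s is degenerate (zero area)", label))
  n <- nrow(v)
  vc <- close_ring(v)
  # brute-force edge pair intersection test; fine for survey-area rings
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (segments_cross(vc[i, ], vc[i + 1, ], vc[j, ], vc[j + 1, ]))
        stop(sprintf("%s is self-intersecting", label))
    }
  }
  invisible(v)
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Even-odd point-in-polygon test
#' @keywords internal
point_in_poly <- function(px, py, v) {
  v <- open_ring(v)
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  xj <- x[c(n, seq_len(n - 1))]; yj <- y[c(n, seq_len(n - 1))]
  vapply(seq_along(px), function(i) {
    cross <- (y > py[i]) != (yj > py[i])
    xin <- px[i] < (xj - x) * (py[i] - y) / (yj - y) + x
    sum(cross & xin) %% 2 == 1
  }, logical(1))
}

#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' Exact for convex subject polygons; used to intersect prediction-grid cells
#' with study-area rings.
#' @keywords internal
clip_poly_rect <- function(v, xmin, xmax, ymin, ymax) {
  v <- open_ring(v)
  clip_halfplane <- function(poly, inside, intersect) {
    n <- nrow(poly)
    if (n == 0) return(poly)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- poly[i, ]; prv <- poly[if (i == 1) n else i - 1, ]
      ci <- inside(cur); pi <- inside(prv)
      if (ci) {
        if (!pi) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pi) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  v <- clip_halfplane(v, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  v <- clip_halfplane(v, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  v <- clip_halfplane(v, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  v <- clip_halfplane(v, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  v
}

#' Distance from a point to a line segment
#' @keywords internal
dist_point_seg <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
  qx <- ax + t * dx; qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

#' Distance from a point to a polyline (vertex matrix)
#' @keywords internal
dist_point_polyline <- function(px, py, v) {
  v <- as.matrix(v)
  n <- nrow(v)
  if (n == 1) return(sqrt((px - v[1, 1])^2 + (py - v[1, 2])^2))
  min(vapply(seq_len(n - 1), function(i) {
    dist_point_seg(px, py, v[i, 1], v[i, 2], v[i + 1, 1], v[i + 1, 2])
  }, numeric(1)))
}

#' Length of a polyline
#' @keywords internal
polyline_length <- function(v) {
  v <- as.matrix(v)
  if (nrow(v) < 2) return(0)
  sum(sqrt(rowSums(diff(v)^2)))
}

#' Split a polyline at given arc-length break points
#'
#' @param v vertex matrix; @param breaks increasing arc lengths strictly
#'   inside (0, length).
#' @return list of vertex matrices whose lengths sum to the original.
#' @keywords internal
split_polyline <- function(v, breaks) {
  v <- as.matrix(v)
  total <- polyline_length(v)
  breaks <- breaks[breaks > 1e-12 & breaks < total - 1e-12]
  cuts <- c(0, breaks, total)
  seg_len <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg_len))
  point_at <- function(s) {
    i <- max(which(cum <= s + 1e-12))
    if (i >= nrow(v)) return(v[nrow(v), ])
    t <- (s - cum[i]) / seg_len[i]
    v[i, ] + t * (v[i + 1, ] - v[i, ])
  }
  out <- vector("list", length(cuts) - 1)
  for (k in seq_len(length(cuts) - 1)) {
    s0 <- cuts[k]; s1 <- cuts[k + 1]
    keep <- which(cum > s0 + 1e-12 & cum < s1 - 1e-12)
    pts <- rbind(point_at(s0), v[keep, , drop = FALSE], point_at(s1))
    out[[k]] <- pts
  }
  out
}

#' Point at a given arc length along a polyline
#' @keywords internal
polyline_point_at <- function(v, s) {
  v <- as.matrix(v)
  seg_len <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg_len))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(which(cum <= s + 1e-12))
  if (i >= nrow(v)) return(v[nrow(v), ])
  t <- if (seg_len[i] == 0) 0 else (s - cum[i]) / seg_len[i]
  v[i, ] + t * (v[i + 1, ] - v[i, ])
}
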