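# Planar contour utilities. A contour is an ordered (n x 2) matrix of
# vertices in a frame's normal/binormal plane, implicitly closed,
# counterclockwise. OCT lumen and stent contours are star-shaped about the
# catheter center (the frame origin), which the azimuthal parameterization
# below relies on.

#' Signed area of a closed polygon (shoelace; positive = counterclockwise)
#' @param xy (n x 2) vertex matrix.
#' @return signed area in mm^2.
#' @export
contour_area <- function(xy) {
  xy <- as_xy_matrix(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(2:nrow(xy), 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Perimeter of a closed polygon
#' @param xy (n x 2) vertex matrix.
#' @return perimeter in mm.
#' @export
contour_perimeter <- function(xy) {
  xy <- as_xy_matrix(xy)
  sum(row_norms(diff(rbind(xy, xy[1L, ]))))
}

# ensure counterclockwise orientation
ensure_ccw <- function(xy) {
  xy <- as_xy_matrix(xy)
  if (contour_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# area centroid of a closed polygon
contour_centroid <- function(xy) {
  xy <- as_xy_matrix(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(2:nrow(xy), 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#' @param xy (n x 2) vertex matrix.
#' @return logical.
#' @export
is_simple_polygon <- function(xy) {
  xy <- as_xy_matrix(xy)
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  a <- xy
  b <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) j > i + 1L &
                         !(i == 1L & j == n)), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  d1 <- b[i, , drop = FALSE] - a[i, , drop = FALSE]
  d2 <- b[j, , drop = FALSE] - a[j, , drop = FALSE]
  w <- a[j, , drop = FALSE] - a[i, , drop = FALSE]
  cr <- function(p, q) p[, 1L] * q[, 2L] - p[, 2L] * q[, 1L]
  den <- cr(d1, d2)
  t1 <- cr(w, d2)
  t2 <- cr(w, d1)
  eps <- 1e-12
  hit <- abs(den) > eps &
    (t1 / den) > eps & (t1 / den) < 1 - eps &
    (t2 / den) > eps & (t2 / den) < 1 - eps
  !any(hit)
}

#' Canonical azimuthal resampling of a closed contour
#'
#' Re-orients the contour counterclockwise, anchors its parameterization at
#' the crossing of the positive-u axis (azimuth 0 about the origin), and
#' resamples it to `n` points equally spaced in arc length. This canonical
#' form is used consistently by the unrolling and roll-back steps so the two
#' are exact inverses of each other. Requires the contour to wind once around
#' the origin (star-shaped OCT contours about the catheter center).
#'
#' @param xy (n x 2) closed contour vertices.
#' @param n number of resampled vertices (default 256).
#' @return object of class `canonical_contour`: list with `vertices` (n x 2),
#'   `theta` (vertex azimuths, increasing from ~0), `cumlen` (arc length at
#'   each vertex), `perimeter`.
#' @export
canonical_contour <- function(xy, n = 256L) {
  xy <- ensure_ccw(as_xy_matrix(xy))
  if (nrow(xy) < 3L) stopf("invalid-contour: fewer than 3 vertices")
  th <- atan2(xy[, 2L], xy[, 1L])
  thu <- unwrap_angles(th)
  total_wind <- thu[length(thu)] - thu[1L] +
    angle_diff(th[1L], th[length(th)])
  if (abs(total_wind - 2 * pi) > 0.5) {
    stopf("invalid-contour: contour does not wind once around the origin")
  }
  # locate the crossing of azimuth 0 (mod 2*pi) on the closed polyline
  thc <- c(thu, thu[length(thu)] + angle_diff(th[1L], th[length(th)]))
  target <- 2 * pi * ceiling(thc[1L] / (2 * pi))
  if (target > max(thc)) target <- target - 2 * pi
  seg <- which(thc[-length(thc)] <= target & thc[-1L] >= target)[1L]
  if (is.na(seg)) seg <- 1L
  dth <- thc[seg + 1L] - thc[seg]
  frac <- if (abs(dth) < 1e-12) 0 else (target - thc[seg]) / dth
  closed <- rbind(xy, xy[1L, ])
  anchor <- closed[seg, ] * (1 - frac) + closed[seg + 1L, ] * frac
  # rotate vertex order to start at the anchor
  m <- nrow(xy)
  idx <- if (seg < m) c((seg + 1L):m, 1L:seg) else 1L:m
  verts <- rbind(anchor, xy[idx, , drop = FALSE], anchor)
  dimnames(verts) <- NULL
  keep <- c(TRUE, row_norms(diff(verts)) > 1e-12)
  verts <- verts[keep, , drop = FALSE]
  cum <- unname(c(0, cumsum(row_norms(diff(verts)))))
  per <- cum[length(cum)]
  s_out <- seq(0, per, length.out = n + 1L)[seq_len(n)]
  vx <- stats::approx(cum, verts[, 1L], xout = s_out)$y
  vy <- stats::approx(cum, verts[, 2L], xout = s_out)$y
  v <- cbind(vx, vy)
  th_out <- unwrap_angles(atan2(v[, 2L], v[, 1L]))
  th_out <- th_out - 2 * pi * round(th_out[1L] / (2 * pi))
  structure(list(vertices = v, theta = th_out,
                 cumlen = s_out, perimeter = per),
            class = "canonical_contour")
}

# radius of a canonical contour at azimuth theta (linear interpolation in
# azimuth between adjacent canonical vertices; exact self-inverse partner of
# contour_azimuth_lookup below)
contour_radius_at <- function(canon, theta) {
  th <- wrap_angle(theta - canon$theta[1L]) + canon$theta[1L]
  i0 <- findInterval(th, canon$theta, rightmost.closed = FALSE)
  i0 <- pmin(pmax(i0, 1L), length(canon$theta))
  r <- row_norms(canon$vertices)
  n <- length(r)
  th_ext <- c(canon$theta, canon$theta[1L] + 2 * pi)
  r_ext <- c(r, r[1L])
  dth <- th_ext[i0 + 1L] - th_ext[i0]
  frac <- ifelse(dth > 1e-12, (th - th_ext[i0]) / dth, 0)
  r_ext[i0] * (1 - frac) + r_ext[i0 + 1L] * frac
}

# arc length along a canonical contour from its anchor to azimuth theta
contour_arclength_at <- function(canon, theta) {
  th <- wrap_angle(theta - canon$theta[1L]) + canon$theta[1L]
  i0 <- findInterval(th, canon$theta, rightmost.closed = FALSE)
  i0 <- pmin(pmax(i0, 1L), length(canon$theta))
  n <- length(canon$theta)
  th_ext <- c(canon$theta, canon$theta[1L] + 2 * pi)
  s_ext <- c(canon$cumlen, canon$perimeter)
  dth <- th_ext[i0 + 1L] - th_ext[i0]
  frac <- ifelse(dth > 1e-12, (th - th_ext[i0]) / dth, 0)
  s_ext[i0] * (1 - frac) + s_ext[i0 + 1L] * frac
}

# azimuth on a canonical contour at arc length y from the anchor
contour_azimuth_at <- function(canon, y) {
  y <- y %% canon$perimeter
  s_ext <- c(canon$cumlen, canon$perimeter)
  th_ext <- c(canon$theta, canon$theta[1L] + 2 * pi)
  i0 <- pmin(pmax(findInterval(y, s_ext, rightmost.closed = FALSE), 1L),
             length(canon$theta))
  ds <- s_ext[i0 + 1L] - s_ext[i0]
  frac <- ifelse(ds > 1e-12, (y - s_ext[i0]) / ds, 0)
  wrap_angle(th_ext[i0] * (1 - frac) + th_ext[i0 + 1L] * frac)
}

# minimum distance from points (k x 2) to a closed polygon outline
dist_to_polygon <- function(p, xy) {
  xy <- as_xy_matrix(xy)
  a <- xy
  b <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  ab <- b - a
  len2 <- pmax(rowSums(ab * ab), 1e-24)
  p <- as_xy_matrix(p)
  vapply(seq_len(nrow(p)), function(i) {
    ap <- sweep(a, 2L, p[i, ], "-")
    t <- pmin(pmax(-(ap[, 1L] * ab[, 1L] + ap[, 2L] * ab[, 2L]) / len2, 0), 1)
    dx <- a[, 1L] + t * ab[, 1L] - p[i, 1L]
    dy <- a[, 2L] + t * ab[, 2L] - p[i, 2L]
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1L))
}

#' Fit a stent contour through a frame's strut points
#'
#' Used when a frame carries segmented strut points but no segmented stent
#' contour: the convex closed curve through the struts (convex hull, densely
#' resampled) stands in for the scaffold contour that unrolling is defined
#' along.
#' @param struts (m x 2) strut point coordinates, m >= 3.
#' @param n resampled vertex count.
#' @return (n x 2) contour matrix.
#' @export
fit_stent_contour <- function(struts, n = 128L) {
  struts <- as_xy_matrix(struts)
  if (nrow(struts) < 3L) {
    stopf("invalid-input: need at least 3 strut points to fit a stent contour")
  }
  h <- grDevices::chull(struts[, 1L], struts[, 2L])
  hull <- struts[rev(h), , drop = FALSE]  # chull returns clockwise
  canonical_contour(hull, n = n)$vertices
}

#' Sample an ellipse contour
#' @param a,b semi-axes in mm.
#' @param n vertex count.
#' @param phase rotation of the major axis, radians.
#' @param center length-2 center.
#' @return (n x 2) vertex matrix.
#' @export
ellipse_contour <- function(a, b = a, n = 96L, phase = 0, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  xy <- cbind(a * cos(t), b * sin(t))
  sweep(rotate2(xy, phase), 2L, center, "+")
}
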