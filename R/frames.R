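#' Rotation-minimizing frames along a centerline
#'
#' Computes one orthonormal local frame (tangent, normal, binormal) per
#' centerline point using the double-reflection method, which transports the
#' initial normal along the curve with zero twist and is stable at inflection
#' points where Frenet frames flip. OCT cross-sections are embedded in the
#' normal/binormal plane of these frames.
#'
#' @param cl a `centerline`.
#' @param initial_normal optional unit 3-vector for the first frame's normal;
#'   must not be parallel to the first tangent. By default the coordinate axis
#'   least aligned with the first tangent is used (deterministic).
#' @return an object of class `frame_set`: list with `origin`, `tangent`,
#'   `normal`, `binormal` (each n x 3) and `arclength` (length n).
#' @references Wang, W., Juettler, B., Zheng, D., Liu, Y. (2008) Computation
#'   of rotation minimizing frames. ACM TOG 27(1).
#' @export
rotation_minimizing_frames <- function(cl, initial_normal = NULL) {
  pts <- cl$points
  n <- nrow(pts)
  tg <- polyline_tangents(pts)
  if (is.null(initial_normal)) {
    ax <- diag(3)
    initial_normal <- ax[which.min(abs(ax %*% tg[1L, ])), ]
  }
  initial_normal <- as.numeric(initial_normal)
  t1 <- tg[1L, ]
  r1 <- initial_normal - sum(initial_normal * t1) * t1
  if (vec_norm(r1) < 1e-8) {
    stopf("invalid-parameter: initial_normal is parallel to the first tangent")
  }
  nm <- matrix(0, n, 3L)
  nm[1L, ] <- r1 / vec_norm(r1)
  for (i in seq_len(n - 1L)) {
    v1 <- pts[i + 1L, ] - pts[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-24) { nm[i + 1L, ] <- nm[i, ]; next }
    rL <- nm[i, ] - (2 / c1) * sum(v1 * nm[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    r2 <- if (c2 < 1e-24) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalize against the tangent to keep drift at machine precision
    r2 <- r2 - sum(r2 * tg[i + 1L, ]) * tg[i + 1L, ]
    nm[i + 1L, ] <- r2 / vec_norm(r2)
  }
  bn <- cbind(tg[, 2L] * nm[, 3L] - tg[, 3L] * nm[, 2L],
              tg[, 3L] * nm[, 1L] - tg[, 1L] * nm[, 3L],
              tg[, 1L] * nm[, 2L] - tg[, 2L] * nm[, 1L])
  structure(list(origin = pts, tangent = tg, normal = nm, binormal = bn,
                 arclength = cl$arclength),
            class = "frame_set")
}

# unit tangents of a 3D polyline: central differences inside, second-order
# one-sided differences at the ends
polyline_tangents <- function(pts) {
  n <- nrow(pts)
  d <- diff(pts)
  tg <- matrix(0, n, 3L)
  if (n > 2L) {
    tg[1L, ] <- -3 * pts[1L, ] + 4 * pts[2L, ] - pts[3L, ]
    tg[n, ] <- 3 * pts[n, ] - 4 * pts[n - 1L, ] + pts[n - 2L, ]
    tg[2:(n - 1L), ] <- pts[3:n, , drop = FALSE] - pts[1:(n - 2L), , drop = FALSE]
  } else {
    tg[1L, ] <- d[1L, ]
    tg[n, ] <- d[n - 1L, ]
  }
  normalize_rows(tg)
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames over %.3f mm\n",
              nrow(x$origin), x$arclength[length(x$arclength)]))
  invisible(x)
}

#' Resample a centerline and compute rotation-minimizing frames
#'
#' Convenience wrapper used throughout the pipeline so that every consumer of
#' the same centerline file derives an identical frame field.
#' @param cl a `centerline`.
#' @param spacing resample spacing in mm (default 0.05).
#' @param initial_normal see [rotation_minimizing_frames()].
#' @return a `frame_set`.
#' @export
centerline_frames <- function(cl, spacing = 0.05, initial_normal = NULL) {
  rotation_minimizing_frames(resample_by_arclength(cl, spacing), initial_normal)
}

#' Interpolate frames at arbitrary stations
#'
#' Linear interpolation of origins and axes between the two bracketing frames,
#' followed by re-orthonormalization. Stations are clamped to the frame-set
#' range.
#' @param frames a `frame_set`.
#' @param s numeric vector of arc-length stations in mm.
#' @return a `frame_set` with one frame per requested station.
#' @export
frame_at <- function(frames, s) {
  al <- frames$arclength
  s <- pmin(pmax(s, al[1L]), al[length(al)])
  i0 <- pmin(findInterval(s, al, rightmost.closed = TRUE), length(al) - 1L)
  ds <- al[i0 + 1L] - al[i0]
  frac <- ifelse(ds > 0, (s - al[i0]) / ds, 0)
  o <- lerp_rows(frames$origin, i0, frac)
  tg <- normalize_rows(lerp_rows(frames$tangent, i0, frac))
  nm <- lerp_rows(frames$normal, i0, frac)
  nm <- nm - rowSums(nm * tg) * tg
  nm <- normalize_rows(nm)
  bn <- cbind(tg[, 2L] * nm[, 3L] - tg[, 3L] * nm[, 2L],
              tg[, 3L] * nm[, 1L] - tg[, 1L] * nm[, 3L],
              tg[, 1L] * nm[, 2L] - tg[, 2L] * nm[, 1L])
  structure(list(origin = o, tangent = tg, normal = nm, binormal = bn,
                 arclength = s),
            class = "frame_set")
}

# extract frame i as a list of plain vectors
get_frame <- function(frames, i) {
  list(origin = frames$origin[i, ], tangent = frames$tangent[i, ],
       normal = frames$normal[i, ], binormal = frames$binormal[i, ])
}

#' In-plane coordinates of 3D points relative to a local frame
#'
#' Projects points onto the frame's normal/binormal plane. The inverse map
#' [frame_point3d()] reconstructs the original point exactly when the
#' out-of-plane offset is re-added.
#'
#' @param frame a single frame: list with `origin`, `tangent`, `normal`,
#'   `binormal` (as returned by `get_frame` or a one-row `frame_set`).
#' @param p matrix (k x 3) or length-3 vector of 3D points.
#' @return matrix (k x 3) with columns `u`, `v` (in-plane, along normal and
#'   binormal) and `offset` (along the tangent).
#' @export
frame_plane_coordinates <- function(frame, p) {
  frame <- as_single_frame(frame)
  p <- if (is.null(dim(p))) matrix(p, 1L, 3L) else as_xyz_matrix(p)
  rel <- sweep(p, 2L, frame$origin)
  cbind(u = rel %*% frame$normal, v = rel %*% frame$binormal,
        offset = rel %*% frame$tangent)
}

#' Map in-plane coordinates back to 3D
#' @param frame a single frame (see [frame_plane_coordinates()]).
#' @param uv matrix (k x 2) of in-plane coordinates or length-2 vector.
#' @param offset out-of-plane offsets (recycled).
#' @return matrix (k x 3) of 3D points.
#' @export
frame_point3d <- function(frame, uv, offset = 0) {
  frame <- as_single_frame(frame)
  uv <- if (is.null(dim(uv))) matrix(uv, 1L, 2L) else as_xy_matrix(uv)
  offset <- rep_len(offset, nrow(uv))
  outer(rep(1, nrow(uv)), frame$origin) +
    outer(uv[, 1L], frame$normal) + outer(uv[, 2L], frame$binormal) +
    outer(offset, frame$tangent)
}

as_single_frame <- function(frame) {
  if (inherits(frame, "frame_set")) {
    if (nrow(frame$origin) != 1L) {
      stopf("expected a single frame; got a frame_set of %d", nrow(frame$origin))
    }
    return(get_frame(frame, 1L))
  }
  frame
}

# accumulated twist of a frame set: rotation of the normal about the tangent
# not explained by tangent change; ~0 for a rotation-minimizing field
frame_total_twist <- function(frames) {
  n <- nrow(frames$origin)
  tw <- 0
  for (i in seq_len(n - 1L)) {
    # transport normal i onto tangent i+1 by projection, compare with normal i+1
    t2 <- frames$tangent[i + 1L, ]
    v <- frames$normal[i, ] - sum(frames$normal[i, ] * t2) * t2
    v <- v / vec_norm(v)
    s <- sum(cross3(v, frames$normal[i + 1L, ]) * t2)
    c <- sum(v * frames$normal[i + 1L, ])
    tw <- tw + atan2(s, c)
  }
  tw
}
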