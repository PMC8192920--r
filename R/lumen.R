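# Lumen reconstruction: package segmented OCT lumen contours along the
# centerline, orient them with the marker, and loft the oriented rings into
# the 3D lumen surface that anchors the whole stent reconstruction.

#' Package OCT contours onto centerline frames
#'
#' Assigns every frame's lumen contour the rotation-minimizing frame at its
#' pullback station, so each contour plane is perpendicular to the local
#' centerline tangent.
#'
#' @param pb an [oct_pullback()].
#' @param cl a [centerline()].
#' @param frames optional precomputed `frame_set` (from
#'   [centerline_frames()]); computed from `cl` if omitted.
#' @param rmf_spacing frame-field resolution in mm when `frames` is computed
#'   here.
#' @return list with `frames` (a `frame_set`, one frame per OCT frame),
#'   `contours` (list of lumen contours), `stations`, `frame_field` (the full
#'   resolution `frame_set` along the centerline).
#' @export
package_contours <- function(pb, cl, frames = NULL, rmf_spacing = 0.05) {
  stations <- pullback_stations(pb)
  total <- total_arclength(cl)
  if (any(stations > total + 1e-9)) {
    stopf("out-of-range: frame station %.3f mm beyond centerline length %.3f mm",
          max(stations), total)
  }
  field <- frames %||% centerline_frames(cl, spacing = rmf_spacing)
  placed <- frame_at(field, stations)
  list(frames = placed,
       contours = lapply(pb$frames, `[[`, "lumen"),
       stations = stations,
       frame_field = field)
}

#' Orient packaged contours using the marker direction
#'
#' Rotates each contour in its plane so the imaged marker direction maps onto
#' a common reference direction transported along the centerline by the
#' rotation-minimizing frames (azimuth 0, the frame normal). The applied
#' per-frame rotation is minus the imaged marker angle; frames without a
#' marker inherit a rotation interpolated linearly (on unwrapped angles)
#' between the nearest marked frames, with boundary values held at the ends.
#'
#' @param placed result of [package_contours()].
#' @param marker_angles per-frame marker angle in radians (NA where absent).
#' @return `placed` with rotated `contours` and an added `rotations` vector
#'   (radians, counterclockwise, as applied).
#' @export
orient_contours <- function(placed, marker_angles) {
  n <- length(placed$contours)
  marker_angles <- rep_len(as.numeric(marker_angles), n)
  if (all(is.na(marker_angles))) {
    stopf("missing-reference: no frame carries a marker angle")
  }
  rot <- interpolate_rotations(-unwrap_angles(marker_angles))
  placed$contours <- lapply(seq_len(n), function(i) {
    rotate2(placed$contours[[i]], rot[i])
  })
  placed$rotations <- rot
  placed
}

# fill NA rotations by linear interpolation over frame index, holding the
# boundary value beyond the first/last marked frame
interpolate_rotations <- function(rot) {
  if (!anyNA(rot)) return(rot)
  idx <- which(!is.na(rot))
  stats::approx(idx, rot[idx], xout = seq_along(rot), rule = 2)$y
}

#' Loft oriented contours into the 3D lumen surface
#'
#' Each contour is resampled to `samples_per_contour` points equally spaced
#' in arc length starting at the transported reference direction, embedded in
#' its frame plane, and consecutive rings are stitched with triangles. The
#' equal-arclength correspondence anchored at the shared reference direction
#' avoids twisting artifacts in the loft.
#'
#' @param oriented result of [orient_contours()] (or [package_contours()] if
#'   the contours are already aligned).
#' @param samples_per_contour ring resolution (>= 8, default 64).
#' @return object of class `lumen_surface`: list with `mesh` (a
#'   [tri_mesh()]), `rings` (list of aligned 3D ring matrices), `canonical`
#'   (per-frame [canonical_contour()]s in plane coordinates), `stations`,
#'   `frames`.
#' @export
loft_surface <- function(oriented, samples_per_contour = 64L) {
  contours <- oriented$contours
  if (length(contours) < 2L) {
    stopf("insufficient-input: lofting needs at least 2 contours")
  }
  if (samples_per_contour < 8L) {
    stopf("invalid-parameter: samples_per_contour must be >= 8")
  }
  for (i in seq_along(contours)) {
    if (!is_simple_polygon(contours[[i]])) {
      stopf("invalid-contour: contour %d self-intersects", i)
    }
  }
  canon <- lapply(contours, canonical_contour, n = samples_per_contour)
  rings <- lapply(seq_along(canon), function(i) {
    frame_point3d(get_frame(oriented$frames, i), canon[[i]]$vertices)
  })
  nr <- length(rings)
  m <- samples_per_contour
  verts <- do.call(rbind, rings)
  faces <- vector("list", nr - 1L)
  jnext <- c(2:m, 1L)
  for (i in seq_len(nr - 1L)) {
    a <- (i - 1L) * m + seq_len(m)
    b <- i * m + seq_len(m)
    faces[[i]] <- rbind(cbind(a, a[jnext], b[jnext]), cbind(a, b[jnext], b))
  }
  mesh <- tri_mesh(verts, do.call(rbind, faces))
  structure(list(mesh = mesh, rings = rings, canonical = canon,
                 stations = oriented$stations, frames = oriented$frames),
            class = "lumen_surface")
}

#' @export
print.lumen_surface <- function(x, ...) {
  cat(sprintf("<lumen_surface> %d rings x %d samples, %.2f mm long\n",
              length(x$rings), nrow(x$rings[[1L]]),
              max(x$stations) - min(x$stations)))
  invisible(x)
}

# lumen wall radius at (station, azimuth): linear blend between the two
# bracketing aligned contours
lumen_radius_at <- function(lumen, s, theta) {
  st <- lumen$stations
  i0 <- pmin(pmax(findInterval(s, st, rightmost.closed = TRUE), 1L),
             length(st) - 1L)
  ds <- st[i0 + 1L] - st[i0]
  lam <- ifelse(ds > 0, pmin(pmax((s - st[i0]) / ds, 0), 1), 0)
  r0 <- vapply(seq_along(s), function(k) {
    contour_radius_at(lumen$canonical[[i0[k]]], theta[k])
  }, numeric(1L))
  r1 <- vapply(seq_along(s), function(k) {
    contour_radius_at(lumen$canonical[[i0[k] + 1L]], theta[k])
  }, numeric(1L))
  r0 * (1 - lam) + r1 * lam
}
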