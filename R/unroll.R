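# Stent unrolling: package and rotate stent contours and strut points with
# the lumen rotations, straighten the stack on a common axis anchored at the
# distal stent contour centroid, and unroll everything onto a plane
# (axial position x, circumferential arc length y).

#' Package, rotate and straighten stent contours and strut points
#'
#' Applies to every frame's stent contour and strut points exactly the
#' in-plane rotation applied to the same frame's lumen contour, stacks the
#' frames on a straight axis at their pullback stations, and translates the
#' whole stack so the centroid of the distal stent contour is the axis
#' origin. Frames that carry strut points but no segmented stent contour get
#' one fitted through their struts (convex closed curve, see
#' [fit_stent_contour()]).
#'
#' @param pb an [oct_pullback()].
#' @param rotations per-frame rotations in radians (as returned by
#'   [orient_contours()]); length must equal the number of frames.
#' @param canonical_points resolution of the canonical per-frame stent
#'   contour parameterization (default 256).
#' @return object of class `straightened_stack`: list with `stations`,
#'   `frame_index`, `contours` (canonical stent contours, after
#'   straightening), `struts` (list of m x 2 matrices), `rotations`,
#'   `distal_centroid`, `distal_station`, `perimeters`.
#' @export
package_and_rotate <- function(pb, rotations, canonical_points = 256L) {
  nfr <- length(pb$frames)
  if (length(rotations) != nfr) {
    stopf("invalid-input: got %d rotations for %d frames", length(rotations), nfr)
  }
  has_stent <- vapply(pb$frames, function(f) {
    !is.null(f$stent) || nrow(f$struts) >= 3L
  }, logical(1L))
  if (!any(has_stent)) stopf("invalid-input: no frame carries stent data")
  keep <- which(has_stent)
  rot_k <- rotations[keep]
  contours_rot <- vector("list", length(keep))
  struts_rot <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    f <- pb$frames[[keep[j]]]
    stent <- f$stent %||% fit_stent_contour(f$struts)
    contours_rot[[j]] <- rotate2(stent, rot_k[j])
    struts_rot[[j]] <- if (nrow(f$struts) > 0L) {
      rotate2(f$struts, rot_k[j])
    } else matrix(0, 0L, 2L)
  }
  c0 <- contour_centroid(contours_rot[[1L]])
  contours <- lapply(contours_rot, function(m) sweep(m, 2L, c0))
  struts <- lapply(struts_rot, function(m) {
    if (nrow(m) > 0L) sweep(m, 2L, c0) else m
  })
  canon <- lapply(contours, canonical_contour, n = canonical_points)
  stations <- pullback_stations(pb)[keep]
  structure(list(stations = stations,
                 frame_index = vapply(pb$frames[keep], `[[`, integer(1L), "index"),
                 contours = canon,
                 struts = struts,
                 rotations = rotations,
                 distal_centroid = c0,
                 distal_station = stations[1L],
                 perimeters = vapply(canon, `[[`, numeric(1L), "perimeter")),
            class = "straightened_stack")
}

#' @export
print.straightened_stack <- function(x, ...) {
  cat(sprintf("<straightened_stack> %d stent frames, stations %.2f..%.2f mm\n",
              length(x$stations), min(x$stations), max(x$stations)))
  invisible(x)
}

#' Unroll a straightened stack onto a plane
#'
#' Each strut point maps to `x` = station minus the distal stent station and
#' `y` = arc length along that frame's stent contour, from the transported
#' reference direction to the contour point at the strut's azimuth. The
#' radial gap between the strut and the contour (`malapposition_mm`,
#' positive when the strut sits inside the contour) is stored and re-applied
#' at roll-back, so the unroll/roll-back pair is exactly invertible and
#' malapposition magnitude survives the round trip. Struts farther than
#' `malapposition_limit` from the contour are flagged malapposed and
#' unrolled by the arc length at their own radius (azimuth preserved), not
#' dropped. Contour rows record each frame's unrolled perimeter line, and a
#' duplicate wrap band of width `wrap_band` is appended beyond y = perimeter
#' to expose cross-seam continuity.
#'
#' @param stack a [package_and_rotate()] result.
#' @param wrap_band wrap-band width in mm (default 2).
#' @param malapposition_limit distance (mm) beyond which a strut is flagged
#'   malapposed (default 1).
#' @param contour_samples unrolled contour-row samples per frame (0 to omit).
#' @return a `planar_point_set`: data.frame with columns `x`, `y`, `azimuth`,
#'   `radius`, `malapposition_mm`, `malapposed`, `role`, `frame_index`,
#'   `wrap_period`, `wrapped`; attributes `distal_station`, `wrap_band`.
#' @export
unroll_to_plane <- function(stack, wrap_band = 2, malapposition_limit = 1,
                            contour_samples = 0L) {
  if (length(stack$stations) == 0L) stopf("invalid-input: empty stack")
  rows <- vector("list", length(stack$stations))
  for (j in seq_along(stack$stations)) {
    canon <- stack$contours[[j]]
    st <- stack$struts[[j]]
    x <- stack$stations[j] - stack$distal_station
    out <- NULL
    if (nrow(st) > 0L) {
      th <- wrap_angle(atan2(st[, 2L], st[, 1L]))
      r <- row_norms(st)
      rc <- contour_radius_at(canon, th)
      dr <- rc - r
      dist <- dist_to_polygon(st, canon$vertices)
      mal <- dist > malapposition_limit
      y <- ifelse(mal, th * r, contour_arclength_at(canon, th))
      out <- data.frame(x = x, y = as.numeric(y), azimuth = as.numeric(th),
                        radius = as.numeric(r),
                        malapposition_mm = as.numeric(dr),
                        malapposed = as.logical(mal),
                        role = "strut", frame_index = stack$frame_index[j],
                        wrap_period = canon$perimeter, wrapped = FALSE,
                        row.names = NULL)
    }
    if (contour_samples > 0L) {
      ys <- seq(0, canon$perimeter, length.out = contour_samples + 1L)[seq_len(contour_samples)]
      out <- rbind(out, data.frame(x = x, y = ys,
                                   azimuth = contour_azimuth_at(canon, ys),
                                   radius = NA_real_, malapposition_mm = 0,
                                   malapposed = FALSE, role = "contour-sample",
                                   frame_index = stack$frame_index[j],
                                   wrap_period = canon$perimeter, wrapped = FALSE))
    }
    rows[[j]] <- out
  }
  planar <- do.call(rbind, rows)
  if (wrap_band > 0 && !is.null(planar) && nrow(planar) > 0L) {
    band <- planar[planar$y < wrap_band, , drop = FALSE]
    if (nrow(band) > 0L) {
      band$y <- band$y + band$wrap_period
      band$wrapped <- TRUE
      planar <- rbind(planar, band)
    }
  }
  rownames(planar) <- NULL
  structure(planar, class = c("planar_point_set", "data.frame"),
            distal_station = stack$distal_station, wrap_band = wrap_band)
}

#' Write a planar point set to CSV
#' @param planar a `planar_point_set`.
#' @param path file path.
#' @export
write_planar_csv <- function(planar, path) {
  df <- as.data.frame(planar)
  df <- df[, c("x", "y", "role", "frame_index", "malapposition_mm",
               "azimuth", "wrap_period", "wrapped")]
  names(df)[1:2] <- c("x_mm", "y_mm")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
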