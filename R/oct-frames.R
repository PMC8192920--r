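#' OCT pullback container
#'
#' One segmented OCT pullback: per-frame lumen contour, optional stent
#' contour, strut points and optional marker angle, plus the frame distance
#' (longitudinal spacing set by pullback speed and frame rate). Coordinates
#' are mm in the OCT image plane with the catheter center at (0, 0); the
#' station of frame `i` is `i * frame_distance` (no longitudinal motion
#' compensation).
#'
#' @param frame_distance frame spacing in mm (e.g. 0.1 or 0.2).
#' @param frames list of frames; each a list with `index` (integer, 0-based),
#'   `lumen` (n x 2 matrix), optional `stent` (n x 2), `struts` (m x 2,
#'   possibly 0-row), optional `marker_angle` (radians, NA if absent).
#' @return object of class `oct_pullback`.
#' @export
oct_pullback <- function(frame_distance, frames) {
  if (!is.numeric(frame_distance) || frame_distance <= 0) {
    stopf("invalid-parameter: frame_distance must be positive")
  }
  idx <- vapply(frames, function(f) as.integer(f$index), integer(1L))
  if (is.unsorted(idx, strictly = TRUE)) {
    stopf("invalid-input: frame indices must be strictly increasing")
  }
  frames <- lapply(frames, function(f) {
    f$index <- as.integer(f$index)
    f$station <- f$index * frame_distance
    f$lumen <- as_xy_matrix(f$lumen)
    if (nrow(f$lumen) < 3L) {
      stopf("frame %d: lumen contour needs at least 3 points", f$index)
    }
    if (!is.null(f$stent)) f$stent <- as_xy_matrix(f$stent)
    f$struts <- if (is.null(f$struts) || length(f$struts) == 0L) {
      matrix(0, 0L, 2L)
    } else as_xy_matrix(f$struts)
    f$marker_angle <- if (is.null(f$marker_angle)) NA_real_ else as.numeric(f$marker_angle)
    if (!is.null(f$stent) && nrow(f$struts) > 0L) {
      d <- dist_to_polygon(f$struts, f$stent)
      if (any(d > 2)) {
        warnf("frame %d: %d strut point(s) farther than 2 mm from the stent contour",
              f$index, sum(d > 2))
      }
    }
    f
  })
  structure(list(frame_distance = frame_distance, frames = frames),
            class = "oct_pullback")
}

#' @export
print.oct_pullback <- function(x, ...) {
  ns <- sum(vapply(x$frames, function(f) nrow(f$struts), integer(1L)))
  cat(sprintf("<oct_pullback> %d frames every %.3g mm, %d strut points\n",
              length(x$frames), x$frame_distance, ns))
  invisible(x)
}

pullback_stations <- function(pb) {
  vapply(pb$frames, `[[`, numeric(1L), "station")
}

#' Read a segmented pullback from its JSON interchange format
#'
#' Schema: `{frame_distance_mm, frames: [{index, marker_angle_deg?,
#' lumen: [[u,v],...], stent: [[u,v],...]?, struts: [[u,v],...]}]}`.
#' Malformed frames abort with an error naming the offending frame index.
#' @param path file path.
#' @return an `oct_pullback`.
#' @export
read_frames_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$frame_distance_mm)) stopf("frames JSON: missing frame_distance_mm")
  frames <- lapply(seq_along(obj$frames), function(k) {
    f <- obj$frames[[k]]
    if (is.null(f$index)) stopf("frame entry %d: missing index", k)
    if (is.null(f$lumen) || length(f$lumen) < 6L) {
      stopf("frame %s: missing or degenerate lumen contour", f$index)
    }
    list(index = f$index,
         lumen = matrix(unlist(f$lumen), ncol = 2L, byrow = !is.matrix(f$lumen)),
         stent = if (!is.null(f$stent))
           matrix(unlist(f$stent), ncol = 2L, byrow = !is.matrix(f$stent)),
         struts = if (!is.null(f$struts) && length(f$struts) > 0L)
           matrix(unlist(f$struts), ncol = 2L, byrow = !is.matrix(f$struts)),
         marker_angle = if (!is.null(f$marker_angle_deg))
           f$marker_angle_deg * pi / 180 else NA_real_)
  })
  oct_pullback(obj$frame_distance_mm, frames)
}

#' Write a pullback to the JSON interchange format
#' @param pb an `oct_pullback`.
#' @param path file path.
#' @export
write_frames_json <- function(pb, path) {
  frames <- lapply(pb$frames, function(f) {
    out <- list(index = f$index)
    if (!is.na(f$marker_angle)) out$marker_angle_deg <- f$marker_angle * 180 / pi
    out$lumen <- unname(f$lumen)
    if (!is.null(f$stent)) out$stent <- unname(f$stent)
    out$struts <- if (nrow(f$struts) > 0L) unname(f$struts) else list()
    out
  })
  jsonlite::write_json(list(frame_distance_mm = pb$frame_distance, frames = frames),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
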