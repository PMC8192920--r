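#' Vessel centerline
#'
#' A centerline is the arc-length-parameterized 3D polyline along which all
#' OCT cross-sections are placed: the backbone of lumen and stent
#' reconstruction. Coordinates are in mm. Consecutive duplicate points are
#' dropped; at least two distinct points are required.
#'
#' @param points numeric matrix (n x 3) of ordered 3D coordinates in mm.
#' @return an object of class `centerline` with elements `points` (n x 3
#'   matrix) and `arclength` (cumulative arc length, `arclength[1] == 0`,
#'   strictly increasing).
#' @examples
#' cl <- centerline(cbind(0, 0, seq(0, 10, by = 0.5)))
#' total_arclength(cl)
#' @export
centerline <- function(points) {
  points <- as_xyz_matrix(points)
  if (nrow(points) >= 2L) {
    keep <- c(TRUE, row_norms(diff(points)) > 1e-12)
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 2L) {
    stopf("invalid-input: a centerline needs at least 2 distinct points")
  }
  arclength <- c(0, cumsum(row_norms(diff(points))))
  structure(list(points = points, arclength = arclength), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.3f mm\n",
              nrow(x$points), total_arclength(x)))
  invisible(x)
}

#' Total arc length of a centerline
#' @param cl a `centerline`.
#' @return total length in mm.
#' @export
total_arclength <- function(cl) {
  cl$arclength[length(cl$arclength)]
}

#' Point on a centerline at given arc-length stations
#' @param cl a `centerline`.
#' @param s numeric vector of stations in mm (clamped to the valid range).
#' @return matrix (length(s) x 3) of interpolated points.
#' @export
centerline_point <- function(cl, s) {
  s <- pmin(pmax(s, 0), total_arclength(cl))
  i0 <- pmin(findInterval(s, cl$arclength, rightmost.closed = TRUE),
             nrow(cl$points) - 1L)
  ds <- cl$arclength[i0 + 1L] - cl$arclength[i0]
  frac <- ifelse(ds > 0, (s - cl$arclength[i0]) / ds, 0)
  lerp_rows(cl$points, i0, frac)
}

#' Resample a centerline at uniform arc-length spacing
#'
#' Points are placed equally spaced in arc length with both endpoints
#' preserved; the realized spacing is the largest value not exceeding
#' `spacing` that divides the total length evenly. Sparse polylines
#' (input spacing > 1 mm) are first smoothed with a natural cubic spline per
#' coordinate, parameterized by arc length, before resampling.
#'
#' @param cl a `centerline`.
#' @param spacing requested spacing in mm; must be positive and smaller than
#'   the total length.
#' @return a resampled `centerline`.
#' @export
resample_by_arclength <- function(cl, spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stopf("invalid-parameter: spacing must be a positive number")
  }
  total <- total_arclength(cl)
  if (spacing >= total) {
    stopf("invalid-parameter: spacing (%g mm) must be smaller than the total length (%g mm)",
          spacing, total)
  }
  n <- max(2L, as.integer(ceiling(total / spacing - 1e-9)) + 1L)
  stations <- seq(0, total, length.out = n)
  if (max(diff(cl$arclength)) > 1 && nrow(cl$points) >= 4L) {
    pts <- vapply(1:3, function(k) {
      stats::spline(cl$arclength, cl$points[, k], xout = stations,
                    method = "natural")$y
    }, numeric(n))
    return(centerline(pts))
  }
  centerline(centerline_point(cl, stations))
}

#' Read a centerline from CSV
#'
#' Expects a header line and columns `x`, `y`, `z` in mm, one row per point.
#' @param path file path.
#' @return a `centerline`.
#' @export
read_centerline_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) {
    stopf("centerline CSV must have header columns x,y,z (got: %s)",
          paste(names(df), collapse = ","))
  }
  centerline(as.matrix(df[, need]))
}

#' Write a centerline to CSV
#' @param cl a `centerline`.
#' @param path file path.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(x = cl$points[, 1L], y = cl$points[, 2L], z = cl$points[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a centerline polyline from a legacy-format VTK file
#'
#' Parses an ASCII legacy VTK POLYDATA file containing a `POINTS` block and a
#' `LINES` block; the first polyline is used.
#' @param path file path.
#' @return a `centerline`.
#' @export
read_centerline_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)
  if (length(ip) == 0L) stopf("no POINTS block in VTK file '%s'", path)
  npts <- as.integer(strsplit(trimws(lines[ip[1L]]), "\\s+")[[1L]][2L])
  il <- grep("^(LINES|POLYGONS|CELLS|VERTICES)", lines)
  il <- il[il > ip[1L]]
  end <- if (length(il)) il[1L] - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(ip[1L] + 1L):end]), "\\s+")))
  vals <- vals[is.finite(vals)]
  if (length(vals) < 3L * npts) stopf("truncated POINTS block in '%s'", path)
  pts <- matrix(vals[seq_len(3L * npts)], ncol = 3L, byrow = TRUE)
  iln <- grep("^LINES", lines)
  if (length(iln)) {
    conn <- as.numeric(unlist(strsplit(trimws(lines[(iln[1L] + 1L):length(lines)]),
                                       "\\s+")))
    conn <- conn[is.finite(conn)]
    if (length(conn) >= 2L) {
      m <- as.integer(conn[1L])
      idx <- as.integer(conn[2L:(1L + m)]) + 1L
      pts <- pts[idx, , drop = FALSE]
    }
  }
  centerline(pts)
}
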