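# Morphometric validation metrics: stent length, mean stent diameter from
# serial cross-sections, ellipse ratio, malapposition, Bland-Altman
# agreement, and the time-averaged wall shear stress post-processing step.

#' Serial cross-sections of a 3D stent wireframe
#'
#' Cuts planes perpendicular to the centerline every `spacing` mm along the
#' stent extent and collects the intersection points of the wireframe strut
#' polylines with each plane, expressed in the cutting frame's in-plane
#' coordinates.
#'
#' @param wire3d a `wireframe3d` (or [sweep_volume()] result, whose
#'   wireframe is used).
#' @param frames the centerline `frame_set`.
#' @param spacing section spacing in mm (default 0.1).
#' @param stations optional explicit station vector (mm, along the
#'   centerline); overrides `spacing`.
#' @return object of class `cross_section_series`: list with `stations`,
#'   `slices` (list of k x 2 in-plane point matrices), `points3d`.
#' @export
cross_section_series <- function(wire3d, frames, spacing = 0.1, stations = NULL) {
  if (inherits(wire3d, "stent_mesh")) wire3d <- wire3d$wireframe3d
  st_all <- unlist(lapply(wire3d$edges, `[[`, "station"))
  rng <- range(st_all)
  if (is.null(stations)) {
    start <- ceiling(rng[1L] / spacing) * spacing
    stations <- seq(start, rng[2L], by = spacing)
  }
  hits3d <- vector("list", length(stations))
  for (e in wire3d$edges) {
    s <- e$station
    if (anyNA(s)) s <- seq(s[1L], s[length(s)], length.out = nrow(e$pts))
    lo <- min(s); hi <- max(s)
    inside <- which(stations >= lo & stations <= hi)
    if (length(inside) == 0L) next
    increasing <- s[length(s)] >= s[1L]
    ss <- if (increasing) s else rev(s)
    pp <- if (increasing) e$pts else e$pts[rev(seq_along(s)), , drop = FALSE]
    ss <- cummax(ss)  # guard against tiny non-monotone jitter in station
    for (k in inside) {
      i0 <- min(max(findInterval(stations[k], ss, rightmost.closed = TRUE), 1L),
                length(ss) - 1L)
      dsr <- ss[i0 + 1L] - ss[i0]
      frac <- if (dsr > 0) (stations[k] - ss[i0]) / dsr else 0
      p <- pp[i0, ] * (1 - frac) + pp[i0 + 1L, ] * frac
      hits3d[[k]] <- rbind(hits3d[[k]], p)
    }
  }
  keep <- !vapply(hits3d, is.null, logical(1L))
  stations <- stations[keep]
  hits3d <- hits3d[keep]
  fr <- frame_at(frames, stations)
  slices <- lapply(seq_along(stations), function(k) {
    uvo <- frame_plane_coordinates(get_frame(fr, k), hits3d[[k]])
    uvo[, 1:2, drop = FALSE]
  })
  structure(list(stations = stations, slices = slices, points3d = hits3d),
            class = "cross_section_series")
}

#' @export
print.cross_section_series <- function(x, ...) {
  cat(sprintf("<cross_section_series> %d sections, stations %.2f..%.2f mm\n",
              length(x$stations), min(x$stations), max(x$stations)))
  invisible(x)
}

#' Stent length along the centerline
#'
#' Arc-length distance along the centerline between the most distal and most
#' proximal strut material (not the 3D chord), so curved stents report their
#' deployed length.
#' @param wire3d a `wireframe3d` or `stent_mesh`.
#' @return length in mm.
#' @export
stent_length <- function(wire3d) {
  if (inherits(wire3d, "stent_mesh")) wire3d <- wire3d$wireframe3d
  st <- unlist(lapply(wire3d$edges, `[[`, "station"))
  if (length(st) == 0L) stopf("invalid-input: empty stent wireframe")
  diff(range(st))
}

#' Mean stent diameter from serial cross-sections
#'
#' Per-station stent diameter is the area-equivalent diameter
#' `2 * sqrt(A / pi)` of the polygon through the slice's strut intersection
#' points ordered by azimuth; the mean stent diameter (MSD) is the
#' unweighted mean over stations. Feret alternatives (`"feret-max"`,
#' `"feret-min"`, mean caliper via the furthest/closest support pairs) are
#' exposed behind `method`. Slices with fewer than 3 strut intersections are
#' skipped with a warning.
#'
#' @param series a [cross_section_series()].
#' @param method diameter definition (default `"equivalent-area"`).
#' @return list with `stations`, `diameters` (NA where skipped) and `msd`.
#' @export
mean_stent_diameter <- function(series, method = c("equivalent-area",
                                                   "feret-max", "feret-min")) {
  method <- match.arg(method)
  d <- vapply(series$slices, function(sl) {
    if (nrow(sl) < 3L) return(NA_real_)
    slice_diameter(sl, method)
  }, numeric(1L))
  if (anyNA(d)) {
    warnf("%d cross-section(s) with fewer than 3 strut intersections skipped",
          sum(is.na(d)))
  }
  list(stations = series$stations, diameters = d, msd = mean(d, na.rm = TRUE))
}

slice_diameter <- function(sl, method = "equivalent-area") {
  if (method == "equivalent-area") {
    ctr <- colMeans(sl)
    ord <- order(atan2(sl[, 2L] - ctr[2L], sl[, 1L] - ctr[1L]))
    2 * sqrt(abs(contour_area(sl[ord, , drop = FALSE])) / pi)
  } else {
    dm <- as.matrix(stats::dist(sl))
    if (method == "feret-max") max(dm) else {
      # min caliper width over hull edge directions
      h <- grDevices::chull(sl)
      hull <- sl[h, , drop = FALSE]
      nh <- nrow(hull)
      widths <- vapply(seq_len(nh), function(i) {
        e <- hull[(i %% nh) + 1L, ] - hull[i, ]
        en <- c(-e[2L], e[1L]) / max(vec_norm(e), 1e-24)
        pr <- as.numeric(hull %*% en)
        max(pr) - min(pr)
      }, numeric(1L))
      min(widths)
    }
  }
}

#' Ellipse ratio of a stent cross-section
#'
#' The ratio of the maximum distance between the two furthest points of the
#' cross-section (distance X) and the maximum point-pair distance measured
#' perpendicular to X's direction (distance Y). 1 for a circular section,
#' > 1 for elliptic deformation; scale- and rotation-invariant, and >= 1 by
#' construction.
#'
#' @param pts (k x 2) planar point set, k >= 3 and not collinear.
#' @return X / Y (dimensionless).
#' @export
ellipse_ratio <- function(pts) {
  pts <- as_xy_matrix(pts)
  if (nrow(pts) < 3L) stopf("invalid-input: need at least 3 points")
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  dm <- as.matrix(stats::dist(hull))
  X <- max(dm)
  if (X < 1e-12) stopf("undefined-ratio: degenerate point set")
  ij <- which(dm == X, arr.ind = TRUE)[1L, ]
  e <- hull[ij[2L], ] - hull[ij[1L], ]
  e <- e / vec_norm(e)
  ep <- c(-e[2L], e[1L])
  pr <- as.numeric(hull %*% ep)
  Y <- max(pr) - min(pr)
  if (Y < 1e-9 * X) stopf("undefined-ratio: collinear point set")
  X / Y
}

#' Strut-to-lumen malapposition map
#'
#' Signed radial distance from every wireframe sample to the lumen wall,
#' positive toward the lumen center (strut standing off the wall). Exact for
#' concentric circular fixtures.
#'
#' @param wire3d a `wireframe3d` or `stent_mesh`.
#' @param lumen a [loft_surface()] result.
#' @param frames the centerline `frame_set`.
#' @return list with `samples` (data.frame: station, azimuth, gap_mm) and
#'   `max` (maximum gap, mm).
#' @export
malapposition <- function(wire3d, lumen, frames) {
  if (inherits(wire3d, "stent_mesh")) wire3d <- wire3d$wireframe3d
  smp <- wireframe_samples(wire3d)
  fr <- frame_at(frames, smp$station)
  n <- nrow(smp$pts)
  gap <- numeric(n)
  theta <- numeric(n)
  for (k in seq_len(n)) {
    uvo <- frame_plane_coordinates(get_frame(fr, k), smp$pts[k, ])
    th <- atan2(uvo[2L], uvo[1L])
    r <- sqrt(uvo[1L]^2 + uvo[2L]^2)
    gap[k] <- lumen_radius_at(lumen, smp$station[k], th) - r
    theta[k] <- wrap_angle(th)
  }
  list(samples = data.frame(station = smp$station, azimuth = theta,
                            gap_mm = gap),
       max = max(gap))
}

#' Bland-Altman agreement between two paired series
#'
#' Differences `d = a - b`; reports the mean difference (bias) and the
#' limits of agreement `mean(d) +/- 1.96 * sd(d)` (sample SD, n - 1).
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return object of class `agreement_result`: list with `mean_difference`,
#'   `loa_low`, `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stopf("invalid-input: series lengths differ")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stopf("invalid-input: need at least 2 paired values")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_difference = m, loa_low = m - 1.96 * s,
                 loa_high = m + 1.96 * s, sd = s, n = length(d)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4g (LoA %.4g to %.4g, n = %d)\n",
              x$mean_difference, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Time-averaged wall shear stress
#'
#' `TAWSS = (1/T) * integral_0^T |tau_w| dt` per surface element, with the
#' integral evaluated by the trapezoidal rule over one cardiac cycle.
#'
#' @param history data.frame with columns `element`, `time` (s) and `tau`
#'   (wall shear stress magnitude, Pa), or a matrix (elements x times) plus
#'   `times`.
#' @param times time vector when `history` is a matrix.
#' @return named numeric vector of TAWSS per element (Pa).
#' @export
tawss <- function(history, times = NULL) {
  if (is.matrix(history)) {
    if (is.null(times)) stopf("invalid-input: matrix history needs a times vector")
    if (length(times) < 3L) stopf("invalid-input: need at least 3 time points over the cycle")
    TT <- max(times) - min(times)
    return(apply(history, 1L, function(v) pracma::trapz(times, abs(v)) / TT))
  }
  need <- c("element", "time", "tau")
  if (!all(need %in% names(history))) {
    stopf("invalid-input: history needs columns element, time, tau")
  }
  out <- vapply(split(history, history$element), function(g) {
    g <- g[order(g$time), ]
    if (nrow(g) < 3L) stopf("invalid-input: need at least 3 time points over the cycle")
    TT <- max(g$time) - min(g$time)
    if (TT <= 0) stopf("invalid-input: degenerate time span")
    pracma::trapz(g$time, abs(g$tau)) / TT
  }, numeric(1L))
  out
}

#' Read a wall-shear-stress history from CSV
#'
#' Columns: `element_id`, `time`, `tau_w`.
#' @param path file path.
#' @return data.frame with columns `element`, `time`, `tau`.
#' @export
read_wss_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("element_id", "time", "tau_w")
  if (!all(need %in% names(df))) {
    stopf("WSS CSV must have columns element_id,time,tau_w")
  }
  data.frame(element = df$element_id, time = df$time, tau = df$tau_w)
}

#' Write a per-station metrics report (JSON + CSV)
#'
#' @param msd a [mean_stent_diameter()] result.
#' @param length_mm stent length.
#' @param ellipse per-station ellipse ratios (same stations as `msd`).
#' @param malappo optional [malapposition()] result.
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_metrics_report <- function(msd, length_mm, ellipse = NULL,
                                 malappo = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(station_mm = msd$stations, diameter_mm = msd$diameters)
  if (!is.null(ellipse)) tab$ellipse_ratio <- ellipse
  csv <- file.path(dir, "metrics_per_station.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  summary <- list(stent_length_mm = length_mm, msd_mm = msd$msd,
                  n_sections = length(msd$stations))
  if (!is.null(ellipse)) summary$mean_ellipse_ratio <- mean(ellipse, na.rm = TRUE)
  if (!is.null(malappo)) summary$max_malapposition_mm <- malappo$max
  js <- file.path(dir, "metrics.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA)
  invisible(c(js, csv))
}
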