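# Synthetic stented-vessel phantoms with known ground truth. Deployment is
# purely geometric: the planar template wireframe is wrapped onto the vessel
# wall at its azimuthal phase, with optional malapposition zones offset
# radially inward. The pullback simulator then emulates OCT sampling: frames
# at fixed spacing, strut points from wireframe/plane crossings, catheter
# rotation drift reported through the marker, a guidewire shadow sector, and
# Gaussian segmentation jitter.

#' Phantom specification
#'
#' @param template a [stent_template()].
#' @param centerline list: `family` ("straight", "arc" or "helix"),
#'   `radius` (arc/helix, mm), `pitch` (helix, mm per turn), `margin`
#'   (unstented vessel beyond each stent end, mm, default 8).
#' @param lumen list: `profile` ("constant", "taper" or "elliptic"),
#'   `radius` (mm), `radius_proximal` (taper end radius), `ratio` (elliptic
#'   axis ratio), `phase` (elliptic axis orientation, radians).
#' @param deployment_diameter nominal deployed stent diameter, mm; must be
#'   within 0.8-1.2x the local lumen diameter.
#' @param malapposition_zones list of zones, each
#'   `list(x_range = c(a, b), azimuth_range = c(t1, t2), gap = g)` with
#'   `x_range` in mm from the distal stent end, azimuths in radians (the
#'   sector may wrap), `gap` the inward radial offset in mm.
#' @param frame_distance OCT frame spacing, mm (0.1 or 0.2 in practice).
#' @param jitter_sd Gaussian segmentation jitter SD per coordinate, mm
#'   (default 0.03, on the scale of the OCT axial resolution).
#' @param shadow list: `width_deg` (default 30, guidewire shadow),
#'   `azimuth_deg` (sector center in image coordinates),
#'   `drift_deg_per_frame`.
#' @param marker_drift_deg_per_frame catheter (marker) rotation drift per
#'   frame, degrees (default 1).
#' @param seed RNG seed for the pullback simulation.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(template = stent_template(),
                         centerline = list(family = "straight"),
                         lumen = list(profile = "constant", radius = 1.5),
                         deployment_diameter = 2 * (lumen$radius %||% 1.5),
                         malapposition_zones = list(),
                         frame_distance = 0.1,
                         jitter_sd = 0.03,
                         shadow = list(width_deg = 30, azimuth_deg = 90,
                                       drift_deg_per_frame = 0),
                         marker_drift_deg_per_frame = 1,
                         seed = 1L) {
  centerline$margin <- centerline$margin %||% 8
  shadow$width_deg <- shadow$width_deg %||% 30
  shadow$azimuth_deg <- shadow$azimuth_deg %||% 90
  shadow$drift_deg_per_frame <- shadow$drift_deg_per_frame %||% 0
  if (jitter_sd < 0) stopf("invalid-spec: jitter_sd must be >= 0")
  if (shadow$width_deg >= 180) stopf("invalid-spec: shadow width must be < 180 degrees")
  for (z in malapposition_zones) {
    if ((z$gap %||% -1) < 0) stopf("invalid-spec: malapposition gap must be >= 0")
  }
  spec <- structure(list(template = template, centerline = centerline,
                         lumen = lumen,
                         deployment_diameter = deployment_diameter,
                         malapposition_zones = malapposition_zones,
                         frame_distance = frame_distance,
                         jitter_sd = jitter_sd, shadow = shadow,
                         marker_drift_deg_per_frame = marker_drift_deg_per_frame,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  check_deployment_feasible(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s vessel, %s lumen r=%.2g mm, stent %.1f x %.0f mm, fd=%.2g mm, jitter %.3g mm, shadow %g deg, seed %d\n",
              x$centerline$family, x$lumen$profile, x$lumen$radius %||% NA,
              x$deployment_diameter, x$template$nominal_length,
              x$frame_distance, x$jitter_sd, x$shadow$width_deg, x$seed))
  invisible(x)
}

check_deployment_feasible <- function(spec) {
  # mean lumen diameter over the stent extent vs nominal deployment diameter
  xs <- seq(0, spec$template$nominal_length, length.out = 21L)
  dmean <- vapply(xs, function(x) 2 * mean_lumen_radius(spec, x), numeric(1L))
  ratio <- spec$deployment_diameter / dmean
  if (any(ratio < 0.8 - 1e-9) || any(ratio > 1.2 + 1e-9)) {
    stopf("invalid-spec: deployment diameter %.2f mm outside 0.8-1.2x the local lumen diameter (%.2f-%.2f mm)",
          spec$deployment_diameter, min(dmean), max(dmean))
  }
  invisible(TRUE)
}

mean_lumen_radius <- function(spec, x) {
  lum <- spec$lumen
  L <- spec$template$nominal_length
  base <- switch(lum$profile,
                 constant = lum$radius,
                 taper = lum$radius + (lum$radius_proximal - lum$radius) *
                   pmin(pmax(x / L, 0), 1),
                 elliptic = lum$radius,
                 stopf("invalid-spec: unknown lumen profile '%s'", lum$profile))
  base
}

# lumen wall radius at azimuth theta, x mm from the distal stent end
phantom_wall_radius <- function(spec, x, theta) {
  r <- mean_lumen_radius(spec, x)
  if (spec$lumen$profile == "elliptic") {
    ratio <- spec$lumen$ratio %||% 1
    a <- r * sqrt(ratio)
    b <- r / sqrt(ratio)
    ph <- spec$lumen$phase %||% 0
    a * b / sqrt((b * cos(theta - ph))^2 + (a * sin(theta - ph))^2)
  } else {
    rep_len(r, length(theta))
  }
}

# malapposition gap at planar position (x from distal stent end, azimuth)
phantom_gap_at <- function(spec, x, theta) {
  g <- numeric(length(x))
  for (z in spec$malapposition_zones) {
    inx <- x >= z$x_range[1L] & x <= z$x_range[2L]
    span <- wrap_angle(z$azimuth_range[2L] - z$azimuth_range[1L])
    inth <- wrap_angle(theta - z$azimuth_range[1L]) <= span
    g[inx & inth] <- pmax(g[inx & inth], z$gap)
  }
  g
}

phantom_centerline <- function(spec) {
  L <- spec$template$nominal_length + 2 * spec$centerline$margin
  s <- seq(0, L, by = 0.05)
  fam <- spec$centerline$family
  pts <- switch(fam,
                straight = cbind(0, 0, s),
                arc = {
                  R <- spec$centerline$radius %||% 30
                  phi <- s / R
                  cbind(R * (1 - cos(phi)), 0, R * sin(phi))
                },
                helix = {
                  a <- spec$centerline$radius %||% 10
                  p <- spec$centerline$pitch %||% 30
                  c2 <- p / (2 * pi)
                  t <- s / sqrt(a^2 + c2^2)
                  cbind(a * cos(t) - a, a * sin(t), c2 * t)
                },
                stopf("invalid-spec: unknown centerline family '%s'", fam))
  centerline(pts)
}

#' Deploy a stent template onto a phantom vessel
#'
#' Wraps the template's planar wireframe onto the vessel wall: planar x maps
#' to the centerline station `margin + x`, planar azimuth to the
#' rotation-minimizing frame azimuth, and each point sits at the wall radius
#' minus the malapposition gap of any zone covering it.
#'
#' @param spec a [phantom_spec()].
#' @param densify edge sampling step in planar mm (default 0.05).
#' @return object of class `ground_truth`: list with `spec`, `centerline`,
#'   `frames` (RMF field), `planar` (template graph with per-node gap),
#'   `wire3d` (truth `wireframe3d`), `lumen` (analytic [loft_surface()]),
#'   `s0` (distal stent station).
#' @export
deploy_stent <- function(spec, densify = 0.05) {
  cl <- phantom_centerline(spec)
  frames <- centerline_frames(cl, spacing = 0.05)
  s0 <- spec$centerline$margin
  g <- template_planar_graph(spec$template)
  rbar <- spec$deployment_diameter / 2
  nodes <- g$nodes
  nodes$dr <- phantom_gap_at(spec, nodes$x, nodes$azimuth)
  node_xyz <- phantom_embed(spec, frames, s0, nodes$x, nodes$azimuth, nodes$dr)
  nodes$X <- node_xyz[, 1L]; nodes$Y <- node_xyz[, 2L]; nodes$Z <- node_xyz[, 3L]
  edges3d <- vector("list", nrow(g$edges))
  for (e in seq_len(nrow(g$edges))) {
    a <- nodes[g$edges$from[e], ]
    b <- nodes[g$edges$to[e], ]
    dth <- angle_diff(b$azimuth, a$azimuth)
    plen <- sqrt((b$x - a$x)^2 + (dth * rbar)^2)
    k <- max(2L, as.integer(ceiling(plen / densify)) + 1L)
    t <- seq(0, 1, length.out = k)
    xx <- a$x + t * (b$x - a$x)
    th <- a$azimuth + t * dth
    dr <- phantom_gap_at(spec, xx, wrap_angle(th))
    pts <- phantom_embed(spec, frames, s0, xx, th, dr)
    edges3d[[e]] <- list(from = g$edges$from[e], to = g$edges$to[e],
                         kind = g$edges$kind[e], provenance = "truth",
                         pts = pts, station = s0 + xx,
                         azimuth = wrap_angle(th), dr = dr,
                         planar_x = xx, planar_theta = th)
  }
  wire3d <- structure(list(nodes = nodes, edges = edges3d, graph = g,
                           stations_range = s0 + range(nodes$x)),
                      class = "wireframe3d")
  lumen <- phantom_lumen_surface(spec, cl, frames, s0)
  structure(list(spec = spec, centerline = cl, frames = frames, planar = g,
                 wire3d = wire3d, lumen = lumen, s0 = s0),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s phantom, stent stations %.2f..%.2f mm\n",
              x$spec$centerline$family, x$wire3d$stations_range[1L],
              x$wire3d$stations_range[2L]))
  invisible(x)
}

# embed planar (x, azimuth, gap) on the wall, in world coordinates
phantom_embed <- function(spec, frames, s0, x, theta, dr) {
  s <- s0 + x
  r <- phantom_wall_radius(spec, x, wrap_angle(theta)) - dr
  fr <- frame_at(frames, s)
  fr$origin + r * cos(theta) * fr$normal + r * sin(theta) * fr$binormal
}

# analytic lumen surface for the whole phantom vessel (reference for
# malapposition and STL export)
phantom_lumen_surface <- function(spec, cl, frames, s0, spacing = 0.25,
                                  samples = 96L) {
  stations <- seq(0, total_arclength(cl), by = spacing)
  th <- seq(0, 2 * pi, length.out = samples + 1L)[seq_len(samples)]
  contours <- lapply(stations, function(s) {
    r <- phantom_wall_radius(spec, s - s0, th)
    cbind(r * cos(th), r * sin(th))
  })
  placed <- list(frames = frame_at(frames, stations), contours = contours,
                 stations = stations)
  loft_surface(placed, samples_per_contour = samples)
}

#' Simulate an OCT pullback over a deployed phantom
#'
#' Cutting planes every `frame_distance` along the centerline; strut points
#' are the wireframe/plane crossings expressed in image coordinates (the
#' frame plane rotated by the accumulated catheter drift), jittered with
#' Gaussian noise and deleted inside the guidewire shadow sector; lumen and
#' stent contours are sampled analytically; each frame reports the imaged
#' marker angle. Deterministic for a fixed spec seed.
#'
#' @param truth a [deploy_stent()] result.
#' @param spec the same [phantom_spec()].
#' @param contour_samples vertices per emitted contour (default 96).
#' @return an [oct_pullback()]; each frame carries a `strut_meta` attribute
#'   (data.frame: kind, ring of the source wireframe edge) for validation.
#' @export
simulate_pullback <- function(truth, spec = truth$spec, contour_samples = 96L) {
  withr::with_seed(spec$seed, {
    L <- total_arclength(truth$centerline)
    nfr <- floor(L / spec$frame_distance + 1e-9)
    th_c <- seq(0, 2 * pi, length.out = contour_samples + 1L)[seq_len(contour_samples)]
    stent_rng <- truth$wire3d$stations_range
    ring_of_edge <- truth$planar$nodes$ring[truth$planar$edges$from]
    frames <- vector("list", nfr + 1L)
    for (i in 0:nfr) {
      s <- i * spec$frame_distance
      x <- s - truth$s0
      phi <- spec$marker_drift_deg_per_frame * pi / 180 * i
      r_lum <- phantom_wall_radius(spec, x, th_c)
      lumen_img <- rotate2(cbind(r_lum * cos(th_c), r_lum * sin(th_c)), -phi)
      in_stent <- s >= stent_rng[1L] - 1e-9 & s <= stent_rng[2L] + 1e-9
      stent_img <- NULL
      struts_img <- matrix(0, 0L, 2L)
      meta <- NULL
      if (in_stent) {
        stent_img <- rotate2(cbind(r_lum * cos(th_c), r_lum * sin(th_c)), -phi)
        cr <- phantom_plane_crossings(truth, spec, x)
        if (nrow(cr) > 0L) {
          img_th <- wrap_angle(cr$theta - phi)
          shadow_c <- (spec$shadow$azimuth_deg +
                         spec$shadow$drift_deg_per_frame * i) * pi / 180
          keep <- angle_dist(img_th, shadow_c) > spec$shadow$width_deg * pi / 360
          cr <- cr[keep, , drop = FALSE]
          if (nrow(cr) > 0L) {
            uv <- cbind(cr$r * cos(cr$theta), cr$r * sin(cr$theta))
            uv <- rotate2(uv, -phi)
            if (spec$jitter_sd > 0) {
              uv <- uv + matrix(stats::rnorm(length(uv), 0, spec$jitter_sd),
                                ncol = 2L)
            }
            struts_img <- uv
            meta <- data.frame(kind = cr$kind, ring = cr$ring)
          }
        }
      }
      f <- list(index = i, lumen = lumen_img, stent = stent_img,
                struts = struts_img, marker_angle = -phi)
      attr(f, "strut_meta") <- meta
      frames[[i + 1L]] <- f
    }
    pb <- oct_pullback(spec$frame_distance, frames)
    # oct_pullback rebuilds the frame lists; re-attach the validation labels
    for (j in seq_along(pb$frames)) {
      attr(pb$frames[[j]], "strut_meta") <-
        attr(frames[[j]], "strut_meta")
    }
    pb
  })
}

# wireframe/plane crossings at x mm from the distal stent end, evaluated on
# the continuous deployed wireframe (exact, not polyline-interpolated)
phantom_plane_crossings <- function(truth, spec, x) {
  g <- truth$planar
  nodes <- g$nodes
  out <- NULL
  for (e in seq_len(nrow(g$edges))) {
    a <- nodes[g$edges$from[e], ]
    b <- nodes[g$edges$to[e], ]
    if ((a$x - x) * (b$x - x) > 0) next
    if (abs(b$x - a$x) < 1e-12) next
    t <- (x - a$x) / (b$x - a$x)
    if (t < -1e-12 || t > 1 + 1e-12) next
    th <- wrap_angle(a$azimuth + t * angle_diff(b$azimuth, a$azimuth))
    dr <- phantom_gap_at(spec, x, th)
    r <- phantom_wall_radius(spec, x, th) - dr
    out <- rbind(out, data.frame(theta = th, r = r, dr = dr,
                                 kind = g$edges$kind[e],
                                 ring = nodes$ring[g$edges$from[e]]))
  }
  if (is.null(out)) data.frame(theta = numeric(0), r = numeric(0),
                               dr = numeric(0), kind = character(0),
                               ring = integer(0)) else out
}
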