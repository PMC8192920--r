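# Roll-back: inverse of the planar unrolling. Planar coordinates
# (x = axial station from the distal stent frame, azimuth about the
# straightened axis) map back onto the stent contour interpolated between
# the two bracketing OCT frames, stored malapposition gaps are re-applied
# radially, and the in-plane point is embedded in the rotation-minimizing
# frame at its centerline station.

# blended canonical stent contour radius at (station index pair, azimuth)
stack_radius_at <- function(stack, i0, lam, theta) {
  r0 <- contour_radius_at(stack$contours[[i0]], theta)
  if (lam <= 0 || i0 >= length(stack$contours)) return(r0)
  r1 <- contour_radius_at(stack$contours[[i0 + 1L]], theta)
  r0 * (1 - lam) + r1 * lam
}

#' Roll planar points back into 3D
#'
#' @param pts data.frame with columns `x` (axial mm from the distal stent
#'   frame), `azimuth` (radians) and optionally `malapposition_mm` (radial
#'   gap re-applied inward; 0 if absent).
#' @param stack the [package_and_rotate()] stack (supplies the per-frame
#'   canonical stent contours and the straightening translation).
#' @param frames the centerline `frame_set` (full resolution field from
#'   [package_contours()]).
#' @return matrix (n x 3) of 3D points in mm.
#' @export
roll_back_points <- function(pts, stack, frames) {
  n <- nrow(pts)
  stations <- stack$distal_station + pts$x
  rng <- range(stack$stations)
  # fitted (bridged) apexes may land marginally beyond the end frames;
  # clamp within one frame spacing, error beyond that
  tol <- max(diff(stack$stations), 1e-6)
  if (any(stations < rng[1L] - tol | stations > rng[2L] + tol)) {
    stopf("out-of-range: planar x maps outside the stent frame stations")
  }
  stations <- pmin(pmax(stations, rng[1L]), rng[2L])
  dr <- if (is.null(pts$malapposition_mm)) rep(0, n) else pts$malapposition_mm
  i0 <- pmin(pmax(findInterval(stations, stack$stations, rightmost.closed = TRUE), 1L),
             max(length(stack$stations) - 1L, 1L))
  ds <- stack$stations[i0 + 1L] - stack$stations[i0]
  lam <- ifelse(is.finite(ds) & ds > 0,
                pmin(pmax((stations - stack$stations[i0]) / ds, 0), 1), 0)
  # snap to an exact frame when the station falls on one (keeps the
  # unroll/roll-back pair exactly inverse on frame-sampled struts)
  on0 <- abs(stations - stack$stations[i0]) < 1e-9
  on1 <- abs(stations - stack$stations[pmin(i0 + 1L, length(stack$stations))]) < 1e-9
  lam[on0] <- 0
  i0[on1] <- pmin(i0[on1] + 1L, length(stack$stations))
  lam[on1] <- 0
  th <- wrap_angle(pts$azimuth)
  out <- matrix(0, n, 3L)
  fr <- frame_at(frames, stations)
  for (k in seq_len(n)) {
    r <- stack_radius_at(stack, i0[k], lam[k], th[k]) - dr[k]
    uv <- c(r * cos(th[k]), r * sin(th[k])) + stack$distal_centroid
    out[k, ] <- frame_point3d(get_frame(fr, k), uv)
  }
  out
}

#' Roll the planar wireframe back onto the 3D lumen
#'
#' Edge polylines are densified in the planar metric (default 0.05 mm) so
#' the rolled-back struts follow the lumen curvature, then every sample is
#' mapped with [roll_back_points()]; malapposition offsets are interpolated
#' linearly along each edge between its end nodes. A node on the wrap seam
#' (y = 0 vs y = perimeter) maps to the same 3D point by construction.
#'
#' @param graph a `wireframe_graph`.
#' @param stack the [package_and_rotate()] stack.
#' @param frames the centerline `frame_set`.
#' @param densify planar sampling step in mm (default 0.05).
#' @return object of class `wireframe3d`: list with `nodes` (graph nodes +
#'   3D coordinates), `edges` (list: from, to, kind, provenance, `pts`
#'   (k x 3), `station`, `azimuth`, `dr`), `graph`, `stations_range`.
#' @export
roll_back_wireframe <- function(graph, stack, frames, densify = 0.05) {
  rng <- range(stack$stations) - stack$distal_station
  tol <- max(diff(stack$stations), 1e-6)
  if (min(graph$nodes$x) < rng[1L] - tol || max(graph$nodes$x) > rng[2L] + tol) {
    stopf("out-of-range: wireframe x extent [%.3f, %.3f] outside stack range [%.3f, %.3f]",
          min(graph$nodes$x), max(graph$nodes$x), rng[1L], rng[2L])
  }
  rbar <- graph$wrap_period / (2 * pi)
  node_xyz <- roll_back_points(graph$nodes, stack, frames)
  edges3d <- vector("list", nrow(graph$edges))
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$nodes[graph$edges$from[e], ]
    b <- graph$nodes[graph$edges$to[e], ]
    dth <- angle_diff(b$azimuth, a$azimuth)
    plen <- sqrt((b$x - a$x)^2 + (dth * rbar)^2)
    k <- max(2L, as.integer(ceiling(plen / densify)) + 1L)
    t <- seq(0, 1, length.out = k)
    seg <- data.frame(x = a$x + t * (b$x - a$x),
                      azimuth = a$azimuth + t * dth,
                      malapposition_mm = a$dr + t * (b$dr - a$dr))
    pts3 <- roll_back_points(seg, stack, frames)
    edges3d[[e]] <- list(from = graph$edges$from[e], to = graph$edges$to[e],
                         kind = graph$edges$kind[e],
                         provenance = graph$edges$provenance[e] %||% "observed",
                         pts = pts3,
                         station = stack$distal_station + seg$x,
                         azimuth = wrap_angle(seg$azimuth),
                         dr = seg$malapposition_mm)
  }
  nodes <- graph$nodes
  nodes$X <- node_xyz[, 1L]; nodes$Y <- node_xyz[, 2L]; nodes$Z <- node_xyz[, 3L]
  structure(list(nodes = nodes, edges = edges3d, graph = graph,
                 stations_range = range(stack$stations)),
            class = "wireframe3d")
}

#' @export
print.wireframe3d <- function(x, ...) {
  npts <- sum(vapply(x$edges, function(e) nrow(e$pts), integer(1L)))
  cat(sprintf("<wireframe3d> %d edges, %d sampled points, stations %.2f..%.2f mm\n",
              length(x$edges), npts, x$stations_range[1L], x$stations_range[2L]))
  invisible(x)
}

# all sampled points of a 3D wireframe with their stations
wireframe_samples <- function(wire3d) {
  list(pts = do.call(rbind, lapply(wire3d$edges, `[[`, "pts")),
       station = unlist(lapply(wire3d$edges, `[[`, "station")),
       azimuth = unlist(lapply(wire3d$edges, `[[`, "azimuth")),
       dr = unlist(lapply(wire3d$edges, `[[`, "dr")))
}

#' Round the stent crowns with circular fillets
#'
#' Each degree-2 crown apex (peaks and valleys that carry no link) is
#' replaced by a circular arc of the given radius tangent to both adjacent
#' strut segments; link junctions and free endpoints are untouched. When the
#' requested radius does not fit the adjacent segment lengths the maximum
#' feasible radius is used for that apex, with a warning.
#'
#' @param wire3d a `wireframe3d`.
#' @param fillet_radius fillet radius in mm; 0 returns the wireframe
#'   unchanged.
#' @param arc_points samples per fillet arc (default 8).
#' @return the filleted `wireframe3d`.
#' @export
round_crowns <- function(wire3d, fillet_radius, arc_points = 8L) {
  if (fillet_radius <= 0) return(wire3d)
  nodes <- wire3d$nodes
  apexes <- nodes$id[!nodes$junction]
  infeasible <- 0L
  for (nid in apexes) {
    inc <- which(vapply(wire3d$edges, function(e) e$from == nid || e$to == nid,
                        logical(1L)))
    if (length(inc) != 2L) next
    # orient both polylines to start at the apex
    polys <- lapply(wire3d$edges[inc], function(e) {
      if (e$from == nid) e$pts else e$pts[rev(seq_len(nrow(e$pts))), , drop = FALSE]
    })
    P <- polys[[1L]][1L, ]
    u1 <- polys[[1L]][2L, ] - P
    u2 <- polys[[2L]][2L, ] - P
    l1 <- polyline_length(polys[[1L]])
    l2 <- polyline_length(polys[[2L]])
    u1 <- u1 / vec_norm(u1)
    u2 <- u2 / vec_norm(u2)
    cosg <- max(min(sum(u1 * u2), 1), -1)
    gam <- acos(cosg)   # angle between the two segments at the apex
    if (gam > pi - 1e-6) next  # collinear: no corner to round
    rf <- fillet_radius
    tmax <- 0.45 * min(l1, l2)
    t <- rf / tan(gam / 2)
    if (t > tmax) {
      rf <- tmax * tan(gam / 2)
      t <- tmax
      infeasible <- infeasible + 1L
    }
    bis <- u1 + u2
    bis <- bis / vec_norm(bis)
    center <- P + bis * (rf / sin(gam / 2))
    p1 <- P + u1 * t
    p2 <- P + u2 * t
    v1 <- (p1 - center) / vec_norm(p1 - center)
    v2 <- (p2 - center) / vec_norm(p2 - center)
    ang <- acos(max(min(sum(v1 * v2), 1), -1))
    axis <- cross3(v1, v2)
    if (vec_norm(axis) < 1e-12) next
    axis <- axis / vec_norm(axis)
    ts <- seq(0, 1, length.out = max(arc_points, 3L))
    arc <- t(vapply(ts, function(s) {
      center + rf * rotate_about_axis(v1, axis, s * ang)
    }, numeric(3L)))
    half <- ceiling(nrow(arc) / 2)
    new1 <- rbind(arc[half:1, , drop = FALSE],
                  trim_polyline(polys[[1L]], t))
    new2 <- rbind(arc[half:nrow(arc), , drop = FALSE],
                  trim_polyline(polys[[2L]], t))
    wire3d$edges[[inc[1L]]] <- replace_polyline(wire3d$edges[[inc[1L]]], nid, new1)
    wire3d$edges[[inc[2L]]] <- replace_polyline(wire3d$edges[[inc[2L]]], nid, new2)
  }
  if (infeasible > 0L) {
    warnf("fillet radius infeasible at %d apex(es); reduced to the maximum feasible radius",
          infeasible)
  }
  wire3d
}

rotate_about_axis <- function(v, axis, angle) {
  v * cos(angle) + cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(row_norms(diff(pts)))
}

# drop the part of a polyline within arc-length t of its first point and
# start it at exactly that distance
trim_polyline <- function(pts, t) {
  cum <- c(0, cumsum(row_norms(diff(pts))))
  i0 <- findInterval(t, cum, rightmost.closed = TRUE)
  i0 <- min(max(i0, 1L), nrow(pts) - 1L)
  frac <- (t - cum[i0]) / max(cum[i0 + 1L] - cum[i0], 1e-24)
  start <- pts[i0, ] * (1 - frac) + pts[i0 + 1L, ] * frac
  rbind(start, pts[(i0 + 1L):nrow(pts), , drop = FALSE])
}

# put a re-shaped polyline back into an edge, restoring stored orientation
replace_polyline <- function(edge, apex_id, new_pts) {
  if (edge$from == apex_id) {
    edge$pts <- new_pts
  } else {
    edge$pts <- new_pts[rev(seq_len(nrow(new_pts))), , drop = FALSE]
  }
  n <- nrow(edge$pts)
  edge$station <- seq(edge$station[1L], edge$station[length(edge$station)],
                      length.out = n)
  edge$azimuth <- rep(NA_real_, n)
  edge$dr <- seq(edge$dr[1L], edge$dr[length(edge$dr)], length.out = n)
  edge
}

#' Sweep the strut profile along the 3D wireframe into a volume mesh
#'
#' Every edge polyline is swept with the template's strut cross-section:
#' circular profiles are oriented by a rotation-minimizing frame along the
#' edge; rectangular profiles keep their wide face tangent to the local
#' vessel wall (width axis perpendicular to the radial direction). Each
#' swept segment is closed with end caps, giving a watertight mesh per strut
#' segment; segments are exported together as one mesh.
#'
#' @param wire3d a `wireframe3d`.
#' @param profile strut profile list from the [stent_template()] (`shape`
#'   plus `diameter` or `width`/`thickness`, mm).
#' @param frames optional centerline `frame_set`, needed for the radial
#'   reference of rectangular profiles; falls back to the sweep's own
#'   rotation-minimizing frame if absent.
#' @param sides polygon sides of the circular profile (default 12).
#' @return object of class `stent_mesh`: list with `mesh` (a [tri_mesh()]),
#'   `segments` (per-edge meshes), `wireframe3d`, `profile`.
#' @export
sweep_volume <- function(wire3d, profile, frames = NULL, sides = 12L) {
  if (profile$shape == "circular") {
    if (profile$diameter <= 0) stopf("invalid-parameter: profile diameter must be positive")
    a <- profile$diameter / 2
    section <- cbind(a * cos(seq(0, 2 * pi, length.out = sides + 1L)[-1L]),
                     a * sin(seq(0, 2 * pi, length.out = sides + 1L)[-1L]))
  } else {
    if (profile$width <= 0 || profile$thickness <= 0) {
      stopf("invalid-parameter: profile dimensions must be positive")
    }
    w <- profile$width / 2
    h <- profile$thickness / 2
    section <- rbind(c(w, -h), c(w, h), c(-w, h), c(-w, -h))
  }
  segs <- vector("list", length(wire3d$edges))
  skipped <- 0L
  for (e in seq_along(wire3d$edges)) {
    pts <- dedupe_polyline(wire3d$edges[[e]]$pts)
    if (nrow(pts) < 2L || polyline_length(pts) < 1e-9) {
      skipped <- skipped + 1L
      next
    }
    sfr <- sweep_frames(pts, wire3d$edges[[e]]$station, frames,
                        rectangular = profile$shape == "rectangular")
    segs[[e]] <- sweep_section(pts, sfr, section)
  }
  if (skipped > 0L) warnf("skipped %d zero-length edge(s) during sweep", skipped)
  segs <- segs[!vapply(segs, is.null, logical(1L))]
  structure(list(mesh = merge_meshes(segs), segments = segs,
                 wireframe3d = wire3d, profile = profile),
            class = "stent_mesh")
}

#' @export
print.stent_mesh <- function(x, ...) {
  cat(sprintf("<stent_mesh> %d swept segments, %d faces, volume %.4f mm^3\n",
              length(x$segments), nrow(x$mesh$faces), mesh_volume(x$mesh)))
  invisible(x)
}

dedupe_polyline <- function(pts) {
  if (nrow(pts) < 2L) return(pts)
  keep <- c(TRUE, row_norms(diff(pts)) > 1e-9)
  pts[keep, , drop = FALSE]
}

# orientation frames along a swept polyline: RMF by default; for rectangular
# profiles the second axis is aligned with the radial direction from the
# centerline so the wide face lies tangent to the wall
sweep_frames <- function(pts, station, frames, rectangular = FALSE) {
  sfr <- rotation_minimizing_frames(centerline(pts))
  if (rectangular && !is.null(frames) && !anyNA(station)) {
    st <- seq(station[1L], station[length(station)], length.out = nrow(pts))
    cfr <- frame_at(frames, st)
    radial <- pts - cfr$origin
    for (i in seq_len(nrow(pts))) {
      r <- radial[i, ] - sum(radial[i, ] * sfr$tangent[i, ]) * sfr$tangent[i, ]
      if (vec_norm(r) < 1e-9) next
      r <- r / vec_norm(r)
      w <- cross3(sfr$tangent[i, ], r)
      sfr$normal[i, ] <- w
      sfr$binormal[i, ] <- r
    }
  }
  sfr
}

# build the closed swept tube: rings of the section at every frame, side
# quads split into triangles, triangle-fan caps at both ends
sweep_section <- function(pts, sfr, section) {
  n <- nrow(pts)
  m <- nrow(section)
  verts <- matrix(0, n * m, 3L)
  for (i in seq_len(n)) {
    verts[(i - 1L) * m + seq_len(m), ] <-
      outer(rep(1, m), sfr$origin[i, ]) +
      outer(section[, 1L], sfr$normal[i, ]) +
      outer(section[, 2L], sfr$binormal[i, ])
  }
  jn <- c(2:m, 1L)
  faces <- vector("list", n + 1L)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * m + seq_len(m)
    b <- i * m + seq_len(m)
    faces[[i]] <- rbind(cbind(a, a[jn], b[jn]), cbind(a, b[jn], b))
  }
  # end caps (fans about the first ring vertex), wound outward
  first <- seq_len(m)
  last <- (n - 1L) * m + seq_len(m)
  cap1 <- do.call(rbind, lapply(2:(m - 1L), function(k) c(first[1L], first[k + 1L], first[k])))
  cap2 <- do.call(rbind, lapply(2:(m - 1L), function(k) c(last[1L], last[k], last[k + 1L])))
  faces[[n]] <- cap1
  faces[[n + 1L]] <- cap2
  tri_mesh(verts, do.call(rbind, faces))
}
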