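#' Planar stent design template
#'
#' Generic parameterized crown-and-link stent pattern: `rings` zig-zag rings
#' of `crowns_per_ring` crowns each, adjacent rings phase-shifted by half a
#' crown period so that every peak of one ring faces a valley of the next,
#' and `links_per_ring_pair` longitudinal links at the crown positions given
#' by `link_phase` (numbered ascending from one edge of the flattened
#' pattern). Manufacturer CAD patterns are proprietary; this generic family
#' reproduces their crown/link topology.
#'
#' @param name template name.
#' @param rings number of zig-zag rings (>= 1).
#' @param crowns_per_ring crowns (peak/valley pairs) per ring (>= 3).
#' @param links_per_ring_pair links between consecutive rings
#'   (1..crowns_per_ring).
#' @param link_phase strictly increasing integer vector of crown indices
#'   (1..crowns_per_ring) carrying links; default evenly spaced.
#' @param strut_profile list: `shape` ("circular" or "rectangular") plus
#'   `diameter` (circular) or `width`/`thickness` (rectangular), mm.
#' @param nominal_diameter,nominal_length nominal deployed diameter and
#'   stent length, mm.
#' @param crown_fraction fraction of the ring pitch occupied by the crown
#'   height (the rest is the inter-ring link gap); default 0.8.
#' @return object of class `stent_template` (with derived `crown_height`,
#'   `pitch`, `width` fields).
#' @export
stent_template <- function(name = "generic",
                           rings = 9L,
                           crowns_per_ring = 8L,
                           links_per_ring_pair = 3L,
                           link_phase = NULL,
                           strut_profile = list(shape = "circular", diameter = 0.081),
                           nominal_diameter = 3.0,
                           nominal_length = 16.0,
                           crown_fraction = 0.8) {
  rings <- as.integer(rings)
  crowns_per_ring <- as.integer(crowns_per_ring)
  links_per_ring_pair <- as.integer(links_per_ring_pair)
  if (crowns_per_ring < 3L) stopf("invalid-template: crowns_per_ring must be >= 3")
  if (links_per_ring_pair < 1L || links_per_ring_pair > crowns_per_ring) {
    stopf("invalid-template: links_per_ring_pair must be in 1..crowns_per_ring")
  }
  if (is.null(link_phase)) {
    link_phase <- unique(as.integer(
      floor(seq(0, crowns_per_ring - 1e-9,
                length.out = links_per_ring_pair + 1L)[seq_len(links_per_ring_pair)])) + 1L)
  }
  link_phase <- as.integer(link_phase)
  if (length(link_phase) != links_per_ring_pair ||
      is.unsorted(link_phase, strictly = TRUE) ||
      min(link_phase) < 1L || max(link_phase) > crowns_per_ring) {
    stopf("invalid-template: link_phase must be a strictly increasing sequence in 1..crowns_per_ring")
  }
  if (!strut_profile$shape %in% c("circular", "rectangular")) {
    stopf("invalid-template: strut profile shape must be circular or rectangular")
  }
  crown_height <- crown_fraction * nominal_length / rings
  pitch <- if (rings > 1L) (nominal_length - crown_height) / (rings - 1L) else nominal_length
  structure(list(name = name, rings = rings, crowns_per_ring = crowns_per_ring,
                 links_per_ring_pair = links_per_ring_pair,
                 link_phase = link_phase, strut_profile = strut_profile,
                 nominal_diameter = nominal_diameter,
                 nominal_length = nominal_length,
                 crown_height = crown_height, pitch = pitch,
                 width = pi * nominal_diameter),
            class = "stent_template")
}

#' @export
print.stent_template <- function(x, ...) {
  cat(sprintf("<stent_template> %s: %d rings x %d crowns, %d links/pair, %s strut, %.1f x %.0f mm\n",
              x$name, x$rings, x$crowns_per_ring, x$links_per_ring_pair,
              x$strut_profile$shape, x$nominal_diameter, x$nominal_length))
  invisible(x)
}

# half-width of the strut profile (used for fillet default and sweeps)
profile_half_width <- function(profile) {
  if (profile$shape == "circular") profile$diameter / 2 else profile$width / 2
}

#' Ground-truth planar graph of a template
#'
#' Expands the template into its planar wireframe: node table (crown apexes
#' and link junctions, with azimuth parameterization of the circumferential
#' coordinate) and edge table (zig-zag strut segments and inter-ring links).
#' The circumferential coordinate wraps with period `2*pi` in azimuth
#' (equivalently `width` mm at the nominal diameter).
#'
#' @param tpl a [stent_template()].
#' @return list with `nodes` (data.frame: id, ring, role, junction, x,
#'   azimuth, y) and `edges` (data.frame: id, from, to, kind), plus `width`,
#'   `period = 2*pi`.
#' @export
template_planar_graph <- function(tpl) {
  C <- tpl$crowns_per_ring
  P <- 2 * pi / C
  nodes <- NULL
  for (r in seq_len(tpl$rings) - 1L) {
    phase <- 0.5 * (r %% 2L)
    th_v <- wrap_angle((seq_len(C) - 1L + phase) * P)          # valleys
    th_p <- wrap_angle(th_v + P / 2)                           # peaks
    x_v <- r * tpl$pitch
    x_p <- x_v + tpl$crown_height
    nodes <- rbind(nodes,
                   data.frame(ring = r, role = "valley", x = x_v, azimuth = th_v),
                   data.frame(ring = r, role = "peak", x = x_p, azimuth = th_p))
  }
  nodes$id <- seq_len(nrow(nodes))
  nodes$y <- nodes$azimuth / (2 * pi) * tpl$width
  nodes$junction <- FALSE
  nodes$provenance <- "template"
  edges <- NULL
  for (r in seq_len(tpl$rings) - 1L) {
    ring_nodes <- nodes[nodes$ring == r, ]
    ord <- ring_nodes$id[order(ring_nodes$azimuth)]
    to <- c(ord[-1L], ord[1L])
    edges <- rbind(edges, data.frame(from = ord, to = to, kind = "strut"))
  }
  for (r in seq_len(max(tpl$rings - 1L, 0L))) {
    r0 <- r - 1L
    peaks <- nodes[nodes$ring == r0 & nodes$role == "peak", ]
    peaks <- peaks[order(peaks$azimuth), ]
    valleys <- nodes[nodes$ring == r0 + 1L & nodes$role == "valley", ]
    for (k in tpl$link_phase) {
      pk <- peaks[k, ]
      vk <- valleys[which.min(angle_dist(valleys$azimuth, pk$azimuth)), ]
      nodes$junction[nodes$id %in% c(pk$id, vk$id)] <- TRUE
      edges <- rbind(edges, data.frame(from = pk$id, to = vk$id, kind = "link"))
    }
  }
  edges$id <- seq_len(nrow(edges))
  list(nodes = nodes, edges = edges, width = tpl$width, period = 2 * pi)
}

#' Read a stent template from JSON
#' @param path file path.
#' @return a [stent_template()].
#' @export
read_template_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  stent_template(name = o$name %||% "unnamed",
                 rings = o$rings,
                 crowns_per_ring = o$crowns_per_ring,
                 links_per_ring_pair = o$links_per_ring_pair,
                 link_phase = o$link_phase,
                 strut_profile = as.list(o$strut_profile),
                 nominal_diameter = o$nominal_diameter_mm,
                 nominal_length = o$nominal_length_mm,
                 crown_fraction = o$crown_fraction %||% 0.8)
}

#' Write a stent template to JSON
#' @param tpl a [stent_template()].
#' @param path file path.
#' @export
write_template_json <- function(tpl, path) {
  jsonlite::write_json(list(name = tpl$name, rings = tpl$rings,
                            crowns_per_ring = tpl$crowns_per_ring,
                            links_per_ring_pair = tpl$links_per_ring_pair,
                            link_phase = tpl$link_phase,
                            strut_profile = tpl$strut_profile,
                            nominal_diameter_mm = tpl$nominal_diameter,
                            nominal_length_mm = tpl$nominal_length,
                            crown_fraction = tpl$crown_height * tpl$rings / tpl$nominal_length),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
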