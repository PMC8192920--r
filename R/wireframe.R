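# Planar stent wireframe reconstruction from unrolled strut points, guided
# by the stent design template. Connection rules: (1) consecutive peaks and
# valleys of each ring are joined into a closed zig-zag, (2) inter-ring links
# are placed consistently with the template's numbered link pattern, (3) in
# wire-shadow gaps apexes are synthesized at the template's expected phase
# ("bridged"), (4) the zig-zag closes across the wrap seam so the flattened
# pattern is periodic.

#' Partition unrolled strut points into rings
#'
#' 1-D clustering on the axial coordinate with the ring pitch expected from
#' the template; each ring's points are sorted by circumferential position.
#'
#' @param planar a `planar_point_set` from [unroll_to_plane()].
#' @param template a [stent_template()].
#' @return list of data.frames (one per detected ring, ordered by azimuth),
#'   with attribute `x0` (axial position of the distal valley row).
#' @export
cluster_rows <- function(planar, template) {
  pts <- planar[planar$role == "strut" & !planar$wrapped, , drop = FALSE]
  if (nrow(pts) == 0L) stopf("insufficient-input: no strut points to cluster")
  if (nrow(pts) < 2L * template$crowns_per_ring) {
    stopf("insufficient-input: %d strut points for %d crowns per ring",
          nrow(pts), template$crowns_per_ring)
  }
  x0 <- min(pts$x)
  ring <- round((pts$x - x0 - template$crown_height / 2) / template$pitch)
  ring <- pmin(pmax(ring, 0), template$rings - 1L)
  detected <- length(unique(ring))
  if (abs(detected - template$rings) > 1L) {
    warnf("template-mismatch: detected %d rings, template has %d",
          detected, template$rings)
  }
  out <- lapply(sort(unique(ring)), function(r) {
    g <- pts[ring == r, , drop = FALSE]
    g <- g[order(g$azimuth), , drop = FALSE]
    g$ring <- r
    g
  })
  attr(out, "x0") <- x0
  out
}

# triangle wave with period 'period', valleys (-1) at delta + k*period,
# peaks (+1) at delta + period/2 + k*period
crown_wave <- function(u, period) {
  1 - 4 * abs(((u / period) %% 1) - 0.5)
}

# fit x ~ mid + amp * crown_wave(azimuth - delta) by grid search over the
# phase delta plus closed-form least squares for mid/amp, with robust
# residual trimming (points on the inter-ring links do not belong to the
# ring's crown wave and would inflate the amplitude)
fit_crown_wave <- function(azimuth, x, crowns, n_grid = 144L) {
  period <- 2 * pi / crowns
  deltas <- seq(0, period, length.out = n_grid + 1L)[seq_len(n_grid)]
  fit_once <- function(az, xx) {
    eval_delta <- function(d) {
      s <- crown_wave(az - d, period)
      vs <- stats::var(s)
      if (!is.finite(vs) || vs < 1e-12) return(NULL)
      b <- stats::cov(xx, s) / vs
      a <- mean(xx) - b * mean(s)
      list(mid = a, amp = b, delta = d, rss = sum((xx - a - b * s)^2),
           period = period)
    }
    best <- NULL
    for (d in deltas) {
      cand <- eval_delta(d)
      if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) best <- cand
    }
    if (!is.null(best)) {
      step <- period / n_grid
      opt <- stats::optimize(function(d) {
        r <- eval_delta(d)
        if (is.null(r)) Inf else r$rss
      }, c(best$delta - step, best$delta + step), tol = 1e-10)
      ref <- eval_delta(opt$minimum)
      if (!is.null(ref) && ref$rss <= best$rss) best <- ref
    }
    if (is.null(best) || abs(best$amp) < 1e-9) {
      stopf("ring fit failed: strut points do not form a crown pattern")
    }
    # a negative amplitude is the same model shifted by half a crown period
    if (best$amp < 0) {
      best$amp <- -best$amp
      best$delta <- (best$delta + period / 2) %% period
    }
    best
  }
  best <- fit_once(azimuth, x)
  for (iter in 1:2) {
    resid <- x - best$mid - best$amp * crown_wave(azimuth - best$delta, period)
    thr <- max(3.5 * stats::mad(resid, center = 0), 0.005)
    keep <- abs(resid) <= thr
    if (sum(keep) < max(8L, length(x) %/% 2) || all(keep)) break
    best <- fit_once(azimuth[keep], x[keep])
  }
  best
}

#' Reconstruct the planar stent wireframe
#'
#' Applies the four connection rules (see the module header) to the unrolled
#' strut points. Within each ring the crown pattern is located by fitting a
#' triangle wave in (azimuth, x); each expected apex is matched to the
#' extremal observed strut point in its angular window, or synthesized at
#' the fitted position and marked `bridged` when the window is empty (wire
#' shadow). Inter-ring links are placed at the template's link crowns, with
#' the cyclic registration chosen to maximize support from observed strut
#' points inside the inter-ring gaps.
#'
#' @param planar a `planar_point_set`.
#' @param template a [stent_template()]; `NULL` aborts with a cannot-bridge
#'   error since rules 2 and 3 need the design pattern.
#' @param prominence minimum fitted crown amplitude, as a fraction of the
#'   template crown height (default 0.25); smaller fits trigger a warning.
#' @param cluster_radius nominal point-to-edge tolerance in mm used by
#'   coverage diagnostics (default 0.15).
#' @return object of class `wireframe_graph`: list with `nodes` (data.frame:
#'   id, ring, role, junction, provenance, x, azimuth, y, dr), `edges`
#'   (data.frame: id, from, to, kind, provenance), `wrap_period` (mean stent
#'   perimeter, mm), `crowns_per_ring`, `cluster_radius`.
#' @export
build_wireframe <- function(planar, template, prominence = 0.25,
                            cluster_radius = 0.15) {
  if (is.null(template)) {
    stopf("cannot-bridge: no stent template available to complete the pattern")
  }
  clusters <- cluster_rows(planar, template)
  C <- template$crowns_per_ring
  period <- 2 * pi / C
  slack <- 0.75 * min_axial_spacing(planar)
  nodes <- NULL
  fits <- list()
  for (g in clusters) {
    r <- g$ring[1L]
    fit <- fit_crown_wave(g$azimuth, g$x, C)
    if (fit$amp < prominence * template$crown_height) {
      warnf("ring %d: fitted crown amplitude %.3f mm below prominence threshold",
            r, fit$amp)
    }
    fits[[as.character(r)]] <- fit
    for (k in seq_len(C) - 1L) {
      for (role in c("valley", "peak")) {
        th_exp <- wrap_angle(fit$delta + k * period +
                               if (role == "peak") period / 2 else 0)
        x_exp <- fit$mid + if (role == "peak") fit$amp else -fit$amp
        win <- angle_dist(g$azimuth, th_exp) < period / 4
        cand <- if (role == "peak") {
          win & g$x >= fit$mid & g$x <= fit$mid + fit$amp + slack
        } else {
          win & g$x <= fit$mid & g$x >= fit$mid - fit$amp - slack
        }
        if (any(cand)) {
          # the apex position comes from the fitted crown wave (the frame
          # grid samples the zig-zag short of its true turning point); the
          # extremal observed point supplies the radial gap and provenance
          gx <- g[cand, , drop = FALSE]
          nodes <- rbind(nodes, data.frame(
            ring = r, role = role, junction = FALSE, provenance = "observed",
            x = x_exp, azimuth = th_exp,
            y = th_exp / (2 * pi) * mean(planar$wrap_period),
            dr = stats::median(gx$malapposition_mm)))
        } else {
          nodes <- rbind(nodes, data.frame(
            ring = r, role = role, junction = FALSE, provenance = "bridged",
            x = x_exp, azimuth = th_exp,
            y = th_exp / (2 * pi) * mean(planar$wrap_period), dr = 0))
        }
      }
    }
  }
  nodes$id <- seq_len(nrow(nodes))
  # rule 1 + rule 4: closed zig-zag per ring (wraps across the seam)
  edges <- NULL
  for (r in unique(nodes$ring)) {
    rn <- nodes[nodes$ring == r, ]
    ord <- rn$id[order(rn$azimuth)]
    edges <- rbind(edges, data.frame(from = ord, to = c(ord[-1L], ord[1L]),
                                     kind = "strut"))
  }
  # rule 2 + rule 3: links at template crowns, registration from gap support
  rings_present <- sort(unique(nodes$ring))
  strut_pts <- planar[planar$role == "strut" & !planar$wrapped, , drop = FALSE]
  for (r in rings_present[-length(rings_present)]) {
    if (!((r + 1L) %in% rings_present)) next
    f0 <- fits[[as.character(r)]]
    f1 <- fits[[as.character(r + 1L)]]
    peaks <- nodes[nodes$ring == r & nodes$role == "peak", ]
    peaks <- peaks[order(peaks$azimuth), ]
    valleys <- nodes[nodes$ring == r + 1L & nodes$role == "valley", ]
    gap <- strut_pts[strut_pts$x > f0$mid + f0$amp + slack &
                       strut_pts$x < f1$mid - f1$amp - slack, , drop = FALSE]
    score <- vapply(seq_len(C) - 1L, function(o) {
      th_links <- peaks$azimuth[(template$link_phase - 1L + o) %% C + 1L]
      if (nrow(gap) == 0L) return(0)
      sum(vapply(gap$azimuth, function(a) min(angle_dist(a, th_links)),
                 numeric(1L)) < period / 4)
    }, numeric(1L))
    o_best <- which.max(score) - 1L
    for (k in (template$link_phase - 1L + o_best) %% C + 1L) {
      pk <- peaks[k, ]
      vk <- valleys[which.min(angle_dist(valleys$azimuth, pk$azimuth)), ]
      nodes$junction[nodes$id %in% c(pk$id, vk$id)] <- TRUE
      edges <- rbind(edges, data.frame(from = pk$id, to = vk$id, kind = "link"))
    }
  }
  edges$provenance <- ifelse(nodes$provenance[edges$from] == "bridged" |
                               nodes$provenance[edges$to] == "bridged",
                             "bridged", "observed")
  edges$id <- seq_len(nrow(edges))
  structure(list(nodes = nodes, edges = edges,
                 wrap_period = mean(planar$wrap_period),
                 crowns_per_ring = C, cluster_radius = cluster_radius),
            class = "wireframe_graph")
}

min_axial_spacing <- function(planar) {
  xs <- sort(unique(round(planar$x[planar$role == "strut"], 9)))
  if (length(xs) < 2L) return(0.1)
  min(diff(xs))
}

#' @export
print.wireframe_graph <- function(x, ...) {
  cat(sprintf("<wireframe_graph> %d nodes (%d bridged), %d edges (%d links), %d rings\n",
              nrow(x$nodes), sum(x$nodes$provenance == "bridged"),
              nrow(x$edges), sum(x$edges$kind == "link"),
              length(unique(x$nodes$ring))))
  invisible(x)
}

node_degrees <- function(graph) {
  tabulate(c(graph$edges$from, graph$edges$to), nbins = max(graph$nodes$id))
}

#' Validate wireframe graph invariants
#'
#' Checks that crown apexes have degree 2, link junctions degree 3 (two
#' zig-zag segments plus one link), the graph is connected, and (when a
#' template is given) that every ring has `crowns_per_ring` peaks and
#' valleys and every consecutive ring pair `links_per_ring_pair` link edges.
#'
#' @param graph a `wireframe_graph`.
#' @param template optional [stent_template()] for count checks.
#' @param strict abort on problems instead of returning them.
#' @return character vector of problems (empty when valid), invisibly when
#'   `strict`.
#' @export
validate_wireframe <- function(graph, template = NULL, strict = FALSE) {
  problems <- character(0)
  deg <- node_degrees(graph)[graph$nodes$id]
  bad_apex <- !graph$nodes$junction & deg != 2L
  if (any(bad_apex)) {
    problems <- c(problems, sprintf("%d crown apex(es) without degree 2",
                                    sum(bad_apex)))
  }
  bad_junc <- graph$nodes$junction & deg != 3L
  if (any(bad_junc)) {
    problems <- c(problems, sprintf("%d link junction(s) without degree 3",
                                    sum(bad_junc)))
  }
  if (!graph_connected(graph)) problems <- c(problems, "graph is not connected")
  if (!is.null(template)) {
    C <- template$crowns_per_ring
    for (r in sort(unique(graph$nodes$ring))) {
      np <- sum(graph$nodes$ring == r & graph$nodes$role == "peak")
      nv <- sum(graph$nodes$ring == r & graph$nodes$role == "valley")
      if (np != C || nv != C) {
        problems <- c(problems,
                      sprintf("ring %d: %d peaks / %d valleys, expected %d", r, np, nv, C))
      }
    }
    nl <- link_counts_per_pair(graph)
    if (any(nl != template$links_per_ring_pair)) {
      problems <- c(problems, "link edge count per ring pair differs from template")
    }
  }
  if (strict && length(problems)) {
    stopf("wireframe validation failed: %s", paste(problems, collapse = "; "))
  }
  if (strict) invisible(problems) else problems
}

graph_connected <- function(graph) {
  ids <- graph$nodes$id
  if (length(ids) == 0L) return(TRUE)
  adj <- split(c(graph$edges$to, graph$edges$from),
               c(graph$edges$from, graph$edges$to))
  seen <- logical(max(ids))
  queue <- ids[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[as.character(v)]]
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen[ids])
}

# link edges per consecutive ring pair
link_counts_per_pair <- function(graph) {
  le <- graph$edges[graph$edges$kind == "link", , drop = FALSE]
  rings <- sort(unique(graph$nodes$ring))
  if (length(rings) < 2L) return(integer(0))
  vapply(rings[-length(rings)], function(r) {
    sum(graph$nodes$ring[le$from] == r)
  }, integer(1L))
}

#' Per-ring node and link counts of a wireframe graph
#' @param graph a `wireframe_graph`.
#' @return list with `peaks`, `valleys` (named per ring), `links` (per ring
#'   pair) and `n_edges`.
#' @export
wireframe_counts <- function(graph) {
  rings <- sort(unique(graph$nodes$ring))
  list(peaks = vapply(rings, function(r)
         sum(graph$nodes$ring == r & graph$nodes$role == "peak"), integer(1L)),
       valleys = vapply(rings, function(r)
         sum(graph$nodes$ring == r & graph$nodes$role == "valley"), integer(1L)),
       links = link_counts_per_pair(graph),
       n_edges = nrow(graph$edges))
}

#' Fraction of strut points close to a wireframe edge
#'
#' Distance is measured in the unrolled metric (axial mm, circumferential
#' azimuth scaled by the mean stent radius), honoring the wrap seam.
#' @param graph a `wireframe_graph`.
#' @param planar the `planar_point_set` it was built from.
#' @param radius tolerance in mm (default the graph's `cluster_radius`).
#' @return fraction of strut points within `radius` of some edge.
#' @export
planar_edge_coverage <- function(graph, planar, radius = NULL) {
  radius <- radius %||% graph$cluster_radius
  pts <- planar[planar$role == "strut" & !planar$wrapped, , drop = FALSE]
  rbar <- graph$wrap_period / (2 * pi)
  px <- pts$x
  py <- pts$azimuth * rbar
  wrapw <- 2 * pi * rbar
  dmin <- rep(Inf, nrow(pts))
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$nodes[graph$edges$from[e], ]
    b <- graph$nodes[graph$edges$to[e], ]
    day <- angle_diff(b$azimuth, a$azimuth) * rbar
    for (shift in c(-wrapw, 0, wrapw)) {
      ax <- a$x; ay <- a$azimuth * rbar + shift
      bx <- b$x; by <- ay + day
      vx <- bx - ax; vy <- by - ay
      len2 <- max(vx * vx + vy * vy, 1e-24)
      t <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1)
      d2 <- (ax + t * vx - px)^2 + (ay + t * vy - py)^2
      dmin <- pmin(dmin, d2)
    }
  }
  mean(sqrt(dmin) <= radius)
}

#' Apply a declarative edit list to a wireframe graph
#'
#' The planar wireframe step is operator-in-the-loop in practice; this is
#' the scripted counterpart of manual correction. Supported ops:
#' `add_node` (x + azimuth or y, role, ring), `move_node` (id, new x and/or
#' azimuth/y), `delete_node` (id; incident edges removed), `add_edge`
#' (from, to, kind), `delete_edge` (id or from/to pair). The edited graph is
#' re-validated; edits that break degree invariants are rejected with a
#' diagnostic.
#'
#' @param graph a `wireframe_graph`.
#' @param edits list of edit lists (or a JSON file path).
#' @return the edited `wireframe_graph`.
#' @export
apply_manual_edits <- function(graph, edits) {
  if (is.character(edits)) {
    edits <- jsonlite::fromJSON(edits, simplifyDataFrame = FALSE)
  }
  if (length(edits) == 0L) return(graph)
  nodes <- graph$nodes
  edges <- graph$edges
  to_azimuth <- function(ed) {
    if (!is.null(ed$azimuth)) as.numeric(ed$azimuth)
    else if (!is.null(ed$y)) as.numeric(ed$y) / graph$wrap_period * 2 * pi
    else NULL
  }
  for (ed in edits) {
    op <- ed$op %||% stopf("edit without an 'op' field")
    if (op == "add_node") {
      nid <- max(nodes$id, 0L) + 1L
      nodes <- rbind(nodes, data.frame(
        ring = as.integer(ed$ring %||% 0L), role = ed$role %||% "peak",
        junction = isTRUE(ed$junction), provenance = "manual",
        x = as.numeric(ed$x), azimuth = wrap_angle(to_azimuth(ed) %||% 0),
        y = (to_azimuth(ed) %||% 0) / (2 * pi) * graph$wrap_period,
        dr = as.numeric(ed$dr %||% 0), id = nid))
    } else if (op == "move_node") {
      i <- match(as.integer(ed$id), nodes$id)
      if (is.na(i)) stopf("edit references unknown node id %s", ed$id)
      if (!is.null(ed$x)) nodes$x[i] <- as.numeric(ed$x)
      az <- to_azimuth(ed)
      if (!is.null(az)) {
        nodes$azimuth[i] <- wrap_angle(az)
        nodes$y[i] <- wrap_angle(az) / (2 * pi) * graph$wrap_period
      }
      if (!is.null(ed$dr)) nodes$dr[i] <- as.numeric(ed$dr)
    } else if (op == "delete_node") {
      i <- match(as.integer(ed$id), nodes$id)
      if (is.na(i)) stopf("edit references unknown node id %s", ed$id)
      nodes <- nodes[-i, , drop = FALSE]
      edges <- edges[edges$from != as.integer(ed$id) &
                       edges$to != as.integer(ed$id), , drop = FALSE]
    } else if (op == "add_edge") {
      if (!all(c(ed$from, ed$to) %in% nodes$id)) {
        stopf("edit references unknown node ids %s-%s", ed$from, ed$to)
      }
      edges <- rbind(edges, data.frame(from = as.integer(ed$from),
                                       to = as.integer(ed$to),
                                       kind = ed$kind %||% "strut",
                                       provenance = "manual",
                                       id = max(edges$id, 0L) + 1L))
    } else if (op == "delete_edge") {
      if (!is.null(ed$id)) {
        edges <- edges[edges$id != as.integer(ed$id), , drop = FALSE]
      } else {
        drop <- (edges$from == as.integer(ed$from) & edges$to == as.integer(ed$to)) |
          (edges$from == as.integer(ed$to) & edges$to == as.integer(ed$from))
        edges <- edges[!drop, , drop = FALSE]
      }
    } else {
      stopf("unknown edit op '%s'", op)
    }
  }
  out <- graph
  out$nodes <- nodes
  out$edges <- edges
  problems <- validate_wireframe(reindex_graph(out))
  problems <- problems[grepl("degree", problems)]
  if (length(problems)) {
    stopf("edits rejected: %s", paste(problems, collapse = "; "))
  }
  reindex_graph(out)
}

# renumber node ids to 1..n and remap edges (keeps data frames tidy after
# deletions)
reindex_graph <- function(graph) {
  old <- graph$nodes$id
  graph$nodes$id <- seq_along(old)
  graph$edges$from <- match(graph$edges$from, old)
  graph$edges$to <- match(graph$edges$to, old)
  graph$edges$id <- seq_len(nrow(graph$edges))
  rownames(graph$nodes) <- NULL
  rownames(graph$edges) <- NULL
  graph
}

#' Write a wireframe graph to JSON
#' @param graph a `wireframe_graph`.
#' @param path file path.
#' @export
write_wireframe_json <- function(graph, path) {
  jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges,
                            wrap_period_mm = graph$wrap_period,
                            crowns_per_ring = graph$crowns_per_ring),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a wireframe graph from JSON
#' @param path file path.
#' @return a `wireframe_graph`.
#' @export
read_wireframe_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  structure(list(nodes = o$nodes, edges = o$edges,
                 wrap_period = o$wrap_period_mm,
                 crowns_per_ring = o$crowns_per_ring,
                 cluster_radius = 0.15),
            class = "wireframe_graph")
}
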