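test_that("strut points cluster into the template's rings", {
  fx <- small_jittered()
  clusters <- cluster_rows(fx$recon$planar, fx$spec$template)
  expect_length(clusters, fx$spec$template$rings)
  # phantom labels: points from a ring's own zig-zag edges must land in
  # that cluster (link points may go to either adjacent ring)
  planar <- fx$recon$planar
  struts <- planar[planar$role == "strut" & !planar$wrapped, ]
  labels <- do.call(rbind, lapply(fx$pb$frames, function(f) attr(f, "strut_meta")))
  shadow_kept <- nrow(struts) == nrow(labels)
  expect_true(shadow_kept)
  assigned <- integer(nrow(struts))
  for (k in seq_along(clusters)) {
    assigned[match(rownames(clusters[[k]]), rownames(struts))] <- k - 1L
  }
  zig <- labels$kind == "strut"
  expect_true(all(assigned[zig] == labels$ring[zig]))
})

test_that("clustering rejects empty and undersized inputs", {
  tpl <- stent_template()
  empty <- structure(data.frame(x = numeric(0), y = numeric(0),
                                azimuth = numeric(0), role = character(0),
                                wrapped = logical(0)),
                     class = c("planar_point_set", "data.frame"))
  expect_error(cluster_rows(empty, tpl), "insufficient-input")
})

test_that("a complete noiseless phantom yields the template graph exactly", {
  fx <- small_noiseless()
  g <- fx$recon$graph
  tpl <- fx$spec$template
  expect_length(validate_wireframe(g, tpl), 0L)
  wc <- wireframe_counts(g)
  expect_true(all(wc$peaks == tpl$crowns_per_ring))
  expect_true(all(wc$valleys == tpl$crowns_per_ring))
  expect_true(all(wc$links == tpl$links_per_ring_pair))
  expect_equal(wc$n_edges, nrow(template_planar_graph(tpl)$edges))
  expect_true(all(g$nodes$provenance == "observed"))
  # node positions match the deployed truth
  tn <- fx$truth$planar$nodes
  for (i in seq_len(nrow(g$nodes))) {
    cand <- tn[tn$ring == g$nodes$ring[i] & tn$role == g$nodes$role[i], ]
    j <- which.min(angle_dist(cand$azimuth, g$nodes$azimuth[i]))
    expect_lt(abs(cand$x[j] - g$nodes$x[i]), 1e-6)
    expect_lt(angle_dist(cand$azimuth[j], g$nodes$azimuth[i]), 1e-6)
  }
})

test_that("a wire-shadow sector is bridged from the template pattern", {
  spec <- small_spec(shadow = list(width_deg = 60, azimuth_deg = 200,
                                   drift_deg_per_frame = 0.3))
  truth <- deploy_stent(spec)
  pb <- simulate_pullback(truth, spec)
  recon <- suppressWarnings(reconstruct_stent(pb, truth$centerline,
                                              spec$template,
                                              pipeline_config(sweep = FALSE)))
  g <- recon$graph
  expect_gt(sum(g$nodes$provenance == "bridged"), 0L)
  expect_length(validate_wireframe(g, spec$template), 0L)
  # bridged apexes sit within half a crown pitch of the truth
  tn <- truth$planar$nodes
  pitch_mm <- g$wrap_period / spec$template$crowns_per_ring
  for (i in which(g$nodes$provenance == "bridged")) {
    cand <- tn[tn$ring == g$nodes$ring[i] & tn$role == g$nodes$role[i], ]
    j <- which.min(angle_dist(cand$azimuth, g$nodes$azimuth[i]))
    d <- sqrt((cand$x[j] - g$nodes$x[i])^2 +
                (angle_dist(cand$azimuth[j], g$nodes$azimuth[i]) *
                   g$wrap_period / (2 * pi))^2)
    expect_lt(d, 0.5 * pitch_mm)
  }
})

test_that("a single clean ring closes into a 2k zig-zag after wrap", {
  tpl <- stent_template(rings = 1L, crowns_per_ring = 6L,
                        links_per_ring_pair = 1L, nominal_diameter = 3,
                        nominal_length = 1.5)
  # synthesize unrolled points straight from the template wave
  th <- seq(0, 2 * pi, length.out = 241L)[-241L]
  x <- 0.6 + 0.6 * octstent:::crown_wave(th, 2 * pi / 6)
  planar <- structure(data.frame(x = x, y = th * 1.5, azimuth = th,
                                 radius = 1.5, malapposition_mm = 0,
                                 malapposed = FALSE, role = "strut",
                                 frame_index = 0L,
                                 wrap_period = 2 * pi * 1.5, wrapped = FALSE),
                      class = c("planar_point_set", "data.frame"))
  g <- build_wireframe(planar, tpl)
  expect_equal(nrow(g$nodes), 12L)
  expect_equal(nrow(g$edges), 12L)   # closed zig-zag: 2k edges for 2k nodes
  deg <- tabulate(c(g$edges$from, g$edges$to))
  expect_true(all(deg == 2L))
})

test_that("graph is periodic across the wrap seam", {
  fx <- small_noiseless()
  g <- fx$recon$graph
  # translating all nodes by one wrap period (2*pi in azimuth) maps the
  # node set onto itself
  for (r in unique(g$nodes$ring)) {
    th <- sort(g$nodes$azimuth[g$nodes$ring == r])
    th_shift <- sort(wrap_angle(th + 2 * pi))
    expect_equal(th_shift, th, tolerance = 1e-9)
  }
})

test_that("every observed strut point lies near a wireframe edge", {
  fx <- small_jittered()
  cov <- planar_edge_coverage(fx$recon$graph, fx$recon$planar, radius = 0.15)
  expect_gte(cov, 0.99)
})

test_that("missing template aborts with a cannot-bridge error", {
  fx <- small_jittered()
  expect_error(build_wireframe(fx$recon$planar, NULL), "cannot-bridge")
})

test_that("manual edits apply, conserve counts, and reject broken graphs", {
  fx0 <- small_noiseless()
  g <- fx0$recon$graph
  expect_identical(apply_manual_edits(g, list()), g)

  # delete one apex and its edges, re-add at a corrected position with its
  # edges: node count conserved and geometry matches the requested spot
  victim <- g$nodes$id[!g$nodes$junction][1L]
  inc <- g$edges[g$edges$from == victim | g$edges$to == victim, ]
  nbrs <- setdiff(unique(c(inc$from, inc$to)), victim)
  target <- g$nodes[g$nodes$id == victim, ]
  newid <- max(g$nodes$id) + 1L   # id assigned to the re-added node
  edits <- c(list(list(op = "delete_node", id = victim),
                  list(op = "add_node", x = target$x + 0.05,
                       azimuth = target$azimuth, role = target$role,
                       ring = target$ring)),
             lapply(nbrs, function(nb) list(op = "add_edge", from = newid,
                                            to = nb, kind = "strut")))
  g2 <- apply_manual_edits(g, edits)
  expect_equal(nrow(g2$nodes), nrow(g$nodes))
  expect_equal(nrow(g2$edges), nrow(g$edges))

  # an edit that strands an apex (degree != 2) is rejected
  bad <- list(list(op = "delete_edge", id = g$edges$id[1L]))
  expect_error(apply_manual_edits(g, bad), "rejected")
})

test_that("scripted corrections reproduce the ground-truth node positions", {
  spec <- small_spec(shadow = list(width_deg = 60, azimuth_deg = 200))
  truth <- deploy_stent(spec)
  pb <- simulate_pullback(truth, spec)
  recon <- suppressWarnings(reconstruct_stent(pb, truth$centerline,
                                              spec$template,
                                              pipeline_config(sweep = FALSE)))
  g <- recon$graph
  tn <- truth$planar$nodes
  edits <- lapply(which(g$nodes$provenance == "bridged"), function(i) {
    cand <- tn[tn$ring == g$nodes$ring[i] & tn$role == g$nodes$role[i], ]
    j <- which.min(angle_dist(cand$azimuth, g$nodes$azimuth[i]))
    list(op = "move_node", id = g$nodes$id[i], x = cand$x[j],
         azimuth = cand$azimuth[j])
  })
  g2 <- apply_manual_edits(g, edits)
  for (i in which(g$nodes$provenance == "bridged")) {
    cand <- tn[tn$ring == g2$nodes$ring[i] & tn$role == g2$nodes$role[i], ]
    j <- which.min(angle_dist(cand$azimuth, g2$nodes$azimuth[i]))
    expect_lt(abs(g2$nodes$x[i] - cand$x[j]), 1e-9)
  }
})

test_that("wireframe JSON export round-trips nodes and edges", {
  fx <- small_noiseless()
  path <- withr::local_tempfile(fileext = ".json")
  write_wireframe_json(fx$recon$graph, path)
  back <- read_wireframe_json(path)
  expect_equal(back$nodes$x, fx$recon$graph$nodes$x, tolerance = 1e-12)
  expect_equal(back$edges$from, fx$recon$graph$edges$from)
  expect_equal(back$wrap_period, fx$recon$graph$wrap_period, tolerance = 1e-12)
})
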