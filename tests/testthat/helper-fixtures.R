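# Shared fixtures, built in code. Heavy phantom reconstructions are
# memoized per session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# small, fast phantom: short 5-ring stent on a straight vessel
small_spec <- function(...) {
  phantom_spec(template = stent_template(rings = 5L, crowns_per_ring = 8L,
                                         links_per_ring_pair = 2L,
                                         nominal_diameter = 3, nominal_length = 8),
               lumen = list(profile = "constant", radius = 1.5),
               deployment_diameter = 3, seed = 99L, ...)
}

small_noiseless <- function() {
  cached("small_noiseless", {
    spec <- small_spec(jitter_sd = 0, shadow = list(width_deg = 0))
    truth <- deploy_stent(spec)
    pb <- simulate_pullback(truth, spec)
    recon <- reconstruct_stent(pb, truth$centerline, spec$template,
                               pipeline_config(sweep = FALSE, fillet_radius = 0))
    list(spec = spec, truth = truth, pb = pb, recon = recon)
  })
}

small_jittered <- function() {
  cached("small_jittered", {
    spec <- small_spec()
    truth <- deploy_stent(spec)
    pb <- simulate_pullback(truth, spec)
    recon <- suppressWarnings(
      reconstruct_stent(pb, truth$centerline, spec$template,
                        pipeline_config(sweep = FALSE)))
    list(spec = spec, truth = truth, pb = pb, recon = recon)
  })
}

# a straight single-edge 3D wireframe along z, for sweep/metrics fixtures
straight_edge_wireframe <- function(length = 10, n = 201L) {
  z <- seq(0, length, length.out = n)
  structure(list(
    nodes = NULL,
    edges = list(list(from = 1L, to = 2L, kind = "strut",
                      provenance = "observed",
                      pts = cbind(0, 0, z), station = z,
                      azimuth = rep(0, n), dr = rep(0, n))),
    graph = NULL, stations_range = c(0, length)), class = "wireframe3d")
}

# truth world-coordinate strut positions of a noiseless pullback, in frame
# order (matches the planar point order produced by unroll_to_plane)
true_strut_world <- function(truth, pb) {
  out <- NULL
  for (f in pb$frames) {
    if (nrow(f$struts) == 0L) next
    phi <- -f$marker_angle
    uv <- f$struts %*% t(matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2))
    fr <- frame_at(truth$frames, f$station)
    rel <- cbind(uv, 0)
    out <- rbind(out, fr$origin[rep(1, nrow(uv)), , drop = FALSE] +
                   uv[, 1L] %o% fr$normal[1L, ] + uv[, 2L] %o% fr$binormal[1L, ])
  }
  out
}

# symmetric Hausdorff distance between two 3D point sets (chunked)
hausdorff3 <- function(A, B, chunk = 500L) {
  one_sided <- function(P, Q) {
    worst <- 0
    q2 <- rowSums(Q^2)
    for (i in seq(1L, nrow(P), by = chunk)) {
      idx <- i:min(i + chunk - 1L, nrow(P))
      d2 <- outer(rowSums(P[idx, , drop = FALSE]^2), rep(1, nrow(Q))) -
        2 * P[idx, , drop = FALSE] %*% t(Q) +
        outer(rep(1, length(idx)), q2)
      worst <- max(worst, max(pmax(apply(d2, 1L, min), 0)))
    }
    sqrt(worst)
  }
  max(one_sided(A, B), one_sided(B, A))
}

wireframe_points <- function(w) {
  do.call(rbind, lapply(w$edges, `[[`, "pts"))
}

# small phantom serialized to files (shared by pipeline and acceptance tests)
phantom_files <- function() {
  cached("phantom_files", {
    dir <- file.path(tempdir(), "octstent-fixture")
    dir.create(dir, showWarnings = FALSE)
    spec <- small_spec()
    truth <- deploy_stent(spec)
    pb <- simulate_pullback(truth, spec)
    write_frames_json(pb, file.path(dir, "frames.json"))
    write_centerline_csv(truth$centerline, file.path(dir, "centerline.csv"))
    write_template_json(spec$template, file.path(dir, "template.json"))
    dir
  })
}
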