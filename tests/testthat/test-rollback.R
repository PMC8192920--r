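test_that("wrap-seam points roll back to identical 3D positions", {
  fx <- small_noiseless()
  stack <- fx$recon$stack
  frames <- fx$recon$frames
  p0 <- roll_back_points(data.frame(x = 2, azimuth = 0, malapposition_mm = 0),
                         stack, frames)
  p1 <- roll_back_points(data.frame(x = 2, azimuth = 2 * pi,
                                    malapposition_mm = 0),
                         stack, frames)
  expect_equal(p0, p1, tolerance = 1e-12)
})

test_that("nodes outside the station range are rejected", {
  fx <- small_noiseless()
  g <- fx$recon$graph
  g$nodes$x[1L] <- max(fx$recon$stack$stations) + 5
  expect_error(roll_back_wireframe(g, fx$recon$stack, fx$recon$frames),
               "out-of-range")
})

test_that("curved noiseless phantoms reconstruct within 0.05 mm Hausdorff", {
  spec <- phantom_spec(template = stent_template(rings = 5L,
                                                 nominal_diameter = 3,
                                                 nominal_length = 8),
                       centerline = list(family = "arc", radius = 20),
                       lumen = list(profile = "constant", radius = 1.5),
                       deployment_diameter = 3, jitter_sd = 0,
                       shadow = list(width_deg = 0), seed = 21L)
  truth <- deploy_stent(spec)
  pb <- simulate_pullback(truth, spec)
  recon <- reconstruct_stent(pb, truth$centerline, spec$template,
                             pipeline_config(sweep = FALSE, fillet_radius = 0,
                                             densify = 0.02))
  h <- hausdorff3(wireframe_points(recon$wire3d),
                  wireframe_points(truth$wire3d))
  expect_lt(h, 0.05)
})

test_that("crown fillets have the exact arc geometry", {
  z <- function(n, a, b) seq(a, b, length.out = n)
  mk_edge <- function(p0, p1, n = 41L) {
    list(from = 1L, to = 2L, kind = "strut", provenance = "observed",
         pts = cbind(z(n, p0[1L], p1[1L]), z(n, p0[2L], p1[2L]),
                     z(n, p0[3L], p1[3L])),
         station = z(n, p0[1L], p1[1L]), azimuth = rep(0, n), dr = rep(0, n))
  }
  apex_wire <- function() {
    e1 <- mk_edge(c(0, 0, 0), c(1, 1, 0)); e1$from <- 1L; e1$to <- 2L
    e2 <- mk_edge(c(1, 1, 0), c(2, 0, 0)); e2$from <- 2L; e2$to <- 3L
    structure(list(nodes = data.frame(ring = 0L,
                                      role = c("valley", "peak", "valley"),
                                      junction = FALSE, provenance = "observed",
                                      x = c(0, 1, 2), azimuth = 0, y = 0,
                                      dr = 0, id = 1:3),
                   edges = list(e1, e2), graph = NULL,
                   stations_range = c(0, 2)), class = "wireframe3d")
  }
  w <- apex_wire()
  wr <- round_crowns(w, 0.1, arc_points = 65L)
  # right-angle apex, radius 0.1: arc length 0.1 * pi / 2; measured as the
  # length removed relative to the sharp corner
  t <- 0.1 / tan(pi / 4)
  l0 <- sum(vapply(w$edges, function(e) octstent:::polyline_length(e$pts),
                   numeric(1L)))
  l1 <- sum(vapply(wr$edges, function(e) octstent:::polyline_length(e$pts),
                   numeric(1L)))
  expect_equal(l0 - l1, 2 * t - 0.1 * pi / 2, tolerance = 1e-4)
  # tangency: the arc ends exactly at the trim points on both segments
  trim1 <- c(1, 1, 0) + t * c(-1, -1, 0) / sqrt(2)
  d <- min(sqrt(rowSums(sweep(wr$edges[[1L]]$pts, 2L, trim1)^2)))
  expect_lt(d, 1e-9)

  # radius 0: unchanged
  expect_identical(round_crowns(w, 0), w)

  # collinear apex: no corner, unchanged geometry
  wc <- apex_wire()
  wc$edges[[2L]] <- mk_edge(c(1, 1, 0), c(2, 2, 0))
  wc$edges[[2L]]$from <- 2L; wc$edges[[2L]]$to <- 3L
  wcr <- round_crowns(wc, 0.1)
  expect_equal(wcr$edges[[1L]]$pts, wc$edges[[1L]]$pts)

  # infeasible radius falls back with a warning
  expect_warning(round_crowns(apex_wire(), 2), "infeasible")
})

test_that("profile sweeps reproduce closed-form volumes and are watertight", {
  w <- straight_edge_wireframe(10)
  sm <- sweep_volume(w, list(shape = "circular", diameter = 0.1), sides = 64L)
  expect_equal(mesh_volume(sm$mesh), pi * 0.05^2 * 10, tolerance = 0.005)
  expect_true(mesh_edge_info(sm$mesh)$closed)

  sm2 <- sweep_volume(w, list(shape = "rectangular", width = 0.090,
                              thickness = 0.074))
  expect_equal(mesh_volume(sm2$mesh), 0.090 * 0.074 * 10, tolerance = 0.005)
  expect_true(mesh_edge_info(sm2$mesh)$closed)

  # zero-length edge skipped with a warning
  wz <- w
  wz$edges[[2L]] <- wz$edges[[1L]]
  wz$edges[[2L]]$pts <- matrix(1, 4L, 3L)
  wz$edges[[2L]]$station <- rep(1, 4L)
  expect_warning(sweep_volume(wz, list(shape = "circular", diameter = 0.1)),
                 "zero-length")
})

test_that("swept phantom volume matches profile area times strut length", {
  fx <- small_noiseless()
  sm <- sweep_volume(fx$recon$wire3d,
                     list(shape = "circular", diameter = 0.081), sides = 24L)
  total_len <- sum(vapply(fx$recon$wire3d$edges, function(e)
    octstent:::polyline_length(e$pts), numeric(1L)))
  area <- pi * (0.081 / 2)^2
  expect_equal(mesh_volume(sm$mesh), area * total_len, tolerance = 0.02)
  # every segment is individually watertight
  expect_true(all(vapply(sm$segments, function(s) mesh_edge_info(s)$closed,
                         logical(1L))))
})

test_that("malapposition gaps survive the full round trip", {
  spec <- small_spec(jitter_sd = 0, shadow = list(width_deg = 0),
                     malapposition_zones = list(
                       list(x_range = c(2, 5), azimuth_range = c(pi, 1.5 * pi),
                            gap = 0.3)))
  truth <- deploy_stent(spec)
  pb <- simulate_pullback(truth, spec)
  recon <- suppressWarnings(
    reconstruct_stent(pb, truth$centerline, spec$template,
                      pipeline_config(sweep = FALSE, fillet_radius = 0)))
  mal <- malapposition(recon$wire3d, recon$lumen, recon$frames)
  expect_equal(mal$max, 0.3, tolerance = 0.02)
  worst <- mal$samples[which.max(mal$samples$gap_mm), ]
  expect_true(worst$azimuth > pi - 0.3 && worst$azimuth < 1.5 * pi + 0.3)
})
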