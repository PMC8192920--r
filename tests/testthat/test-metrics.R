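# a "comb" wireframe: axial strut lines at fixed azimuths, radius profile
# r(z), so every cross-section sees one point per line
comb_wireframe <- function(r_fun, n_lines = 72L, length = 10, n = 101L) {
  z <- seq(0, length, length.out = n)
  th <- seq(0, 2 * pi, length.out = n_lines + 1L)[-(n_lines + 1L)]
  edges <- lapply(th, function(a) {
    r <- r_fun(z)
    list(from = 1L, to = 2L, kind = "strut", provenance = "observed",
         pts = cbind(r * cos(a), r * sin(a), z), station = z,
         azimuth = rep(a, n), dr = rep(0, n))
  })
  structure(list(nodes = NULL, edges = edges, graph = NULL,
                 stations_range = c(0, length)), class = "wireframe3d")
}

straight_frames <- function(length = 10) {
  centerline_frames(centerline(cbind(0, 0, seq(0, length, 0.1))))
}

test_that("MSD recovers cylinder and taper diameters", {
  fr <- straight_frames()
  cyl <- comb_wireframe(function(z) rep(1.5, length(z)))
  ser <- cross_section_series(cyl, fr, spacing = 0.1)
  msd <- mean_stent_diameter(ser)
  expect_equal(msd$msd, 3.0, tolerance = 0.02)

  tap <- comb_wireframe(function(z) 1.25 + 0.05 * z)  # 2.5 -> 3.5 mm
  msd_t <- mean_stent_diameter(cross_section_series(tap, fr, spacing = 0.1))
  expect_equal(msd_t$msd, 3.0, tolerance = 0.02)
  # per-station profile is linear
  fitl <- stats::lm(msd_t$diameters ~ msd_t$stations)
  expect_equal(unname(stats::coef(fitl)[2L]), 0.1, tolerance = 1e-3)
})

test_that("a single circular slice reports its diameter", {
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  ser <- structure(list(stations = 0,
                        slices = list(cbind(2 * cos(th), 2 * sin(th))),
                        points3d = NULL), class = "cross_section_series")
  msd <- mean_stent_diameter(ser)
  expect_equal(msd$msd, 4.0, tolerance = 0.01)
  # sparse slices are skipped with a warning
  ser$slices <- list(cbind(0, 0)[c(1, 1), , drop = FALSE])
  expect_warning(m2 <- mean_stent_diameter(ser), "skipped")
  expect_true(is.nan(m2$msd))
})

test_that("MSD is invariant under rigid motion of the scene", {
  fr <- straight_frames()
  cyl <- comb_wireframe(function(z) rep(1.4, length(z)), n_lines = 24L)
  msd0 <- mean_stent_diameter(cross_section_series(cyl, fr))$msd
  # rotate the whole scene (wireframe + centerline) by a rigid motion
  ang <- 0.7
  R <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0), c(-sin(ang), 0, cos(ang)))
  shift <- c(3, -2, 5)
  cyl2 <- cyl
  cyl2$edges <- lapply(cyl$edges, function(e) {
    e$pts <- sweep(e$pts %*% t(R), 2L, shift, "+")
    e
  })
  cl2 <- centerline(sweep(cbind(0, 0, seq(0, 10, 0.1)) %*% t(R), 2L, shift, "+"))
  msd1 <- mean_stent_diameter(cross_section_series(cyl2,
                                                   centerline_frames(cl2)))$msd
  expect_equal(msd1, msd0, tolerance = 1e-6)
})

test_that("ellipse ratio matches brute force and its invariants", {
  th <- seq(0, 2 * pi, length.out = 481L)[-481L]
  expect_equal(ellipse_ratio(cbind(cos(th), sin(th))), 1, tolerance = 1e-3)
  expect_equal(ellipse_ratio(cbind(2 * cos(th), sin(th))), 2, tolerance = 1e-3)
  square <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  expect_equal(ellipse_ratio(square), 1, tolerance = 1e-12)

  brute <- function(pts) {
    dm <- as.matrix(stats::dist(pts))
    X <- max(dm)
    ij <- which(dm == X, arr.ind = TRUE)[1L, ]
    e <- (pts[ij[2L], ] - pts[ij[1L], ]) / X
    ep <- c(-e[2L], e[1L])
    pr <- as.numeric(pts %*% ep)
    X / (max(pr) - min(pr))
  }
  set.seed(31)
  for (i in 1:10) {
    pts <- matrix(rnorm(2 * sample(50:500, 1L)), ncol = 2L)
    r0 <- ellipse_ratio(pts)
    expect_gte(r0, 1)
    expect_equal(r0, brute(pts), tolerance = 1e-12)
    # scale and rotation invariance
    a <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    expect_equal(ellipse_ratio(3.7 * pts %*% R), r0, tolerance = 1e-9)
  }
  expect_error(ellipse_ratio(cbind(1:5, 2 * (1:5))), "undefined-ratio")
  expect_error(ellipse_ratio(cbind(1, 1)), "invalid-input")
})

test_that("malapposition is exact for concentric circular fixtures", {
  fr <- straight_frames()
  # lumen: cylinder radius 1.5; strut ring radius 1.0 -> gap 0.5
  stations <- seq(0, 10, by = 1)
  contours <- rep(list(ellipse_contour(1.5, 1.5, 96L)), length(stations))
  lumen <- loft_surface(list(frames = frame_at(fr, stations),
                             contours = contours, stations = stations), 96L)
  ring <- comb_wireframe(function(z) rep(1.0, length(z)), n_lines = 36L,
                         length = 10, n = 11L)
  mal <- malapposition(ring, lumen, fr)
  expect_equal(mal$max, 0.5, tolerance = 1e-3)
  expect_equal(range(mal$samples$gap_mm), c(0.5, 0.5), tolerance = 1e-3)

  # strut lying on the wall: gap ~ 0
  wall <- comb_wireframe(function(z) rep(1.5, length(z)), n_lines = 36L,
                         length = 10, n = 11L)
  expect_lt(abs(malapposition(wall, lumen, fr)$max), 1e-3)
})

test_that("stent length is measured along the centerline", {
  fx <- small_noiseless()
  expect_equal(stent_length(fx$truth$wire3d), 8, tolerance = 1e-9)
  expect_equal(stent_length(fx$recon$wire3d), 8, tolerance = 0.05)
  empty <- structure(list(edges = list()), class = "wireframe3d")
  expect_error(stent_length(empty), "invalid-input")
})

test_that("curved stents report arc length, not chord", {
  spec <- phantom_spec(template = stent_template(rings = 5L,
                                                 nominal_diameter = 3,
                                                 nominal_length = 8),
                       centerline = list(family = "arc", radius = 20),
                       lumen = list(profile = "constant", radius = 1.5),
                       deployment_diameter = 3, jitter_sd = 0,
                       shadow = list(width_deg = 0), seed = 2L)
  truth <- deploy_stent(spec)
  expect_equal(stent_length(truth$wire3d), 8, tolerance = 1e-6)
  # the chord is visibly shorter than the arc for radius 20
  nodes <- truth$wire3d$nodes
  ends <- range(nodes$x)
  p0 <- colMeans(as.matrix(nodes[nodes$x == ends[1L], c("X", "Y", "Z")]))
  p1 <- colMeans(as.matrix(nodes[nodes$x == ends[2L], c("X", "Y", "Z")]))
  expect_lt(sqrt(sum((p1 - p0)^2)), 8)
})

test_that("Bland-Altman agrees with hand computation and is antisymmetric", {
  a <- c(1, 2, 3); b <- a
  ba0 <- bland_altman(a, b)
  expect_equal(c(ba0$mean_difference, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  ba_c <- bland_altman(a + 0.1, a)
  expect_equal(ba_c$mean_difference, 0.1, tolerance = 1e-12)
  expect_equal(ba_c$loa_low, 0.1, tolerance = 1e-12)

  ba <- bland_altman(c(0, 1, 2), c(1, 1, 1))  # d = {-1, 0, 1}
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)

  set.seed(8)
  x <- rnorm(20); y <- rnorm(20)
  f <- bland_altman(x, y); r <- bland_altman(y, x)
  expect_equal(f$mean_difference, -r$mean_difference)
  expect_equal(f$loa_low, -r$loa_high)
  expect_error(bland_altman(1:3, 1:4), "invalid-input")
})

test_that("TAWSS averages the wall shear stress over the cycle", {
  T <- 0.8
  t <- seq(0, T, length.out = 2001L)
  hist <- data.frame(element = rep(c("a", "b"), each = length(t)),
                     time = rep(t, 2L),
                     tau = c(rep(1, length(t)), sin(2 * pi * t / T)))
  out <- tawss(hist)
  expect_equal(unname(out["a"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(out["b"]), 2 / pi, tolerance = 1e-3)
  expect_error(tawss(data.frame(element = "a", time = c(0, 1), tau = c(1, 1))),
               "invalid-input")
  # CSV reader
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(element_id = "a", time = t, tau_w = 1), csv,
                   row.names = FALSE)
  expect_equal(unname(tawss(read_wss_csv(csv))["a"]), 1.0)
})
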