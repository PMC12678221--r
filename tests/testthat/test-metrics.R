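test_that("a straight profile has zero roughness whatever its slope", {
  X <- seq(0, 15, 0.05)
  for (slope in c(0, 0.3, -2)) {
    rep <- section_roughness(X, 1 + slope * X, dX = 5)
    expect_equal(rep$Ra_bar, 0, tolerance = 1e-12)
    expect_equal(rep$n_sections, 3L)
  }
})

test_that("a sinusoid over one section gives Ra = 2A/pi", {
  # cosine phase: even about the section center, so the least-squares
  # reference line is flat and Ra is the mean of |cos|
  X <- seq(0, 5, length.out = 2001)
  rep <- section_roughness(X, cos(2 * pi * X / 5), dX = 5)
  expect_equal(rep$Ra_bar, 2 / pi, tolerance = 0.005 * 2 / pi)
})

test_that("the averaged roughness is the plain mean of section values", {
  # build a profile whose two sections have known Ra 0.2 and 0.4
  X1 <- seq(0, 5 - 0.005, length.out = 1000)
  X2 <- seq(5, 10 - 0.005, length.out = 1000)
  h1 <- 0.2 * pi / 2 * cos(2 * pi * X1 / 5)
  h2 <- 0.4 * pi / 2 * cos(2 * pi * X2 / 5)
  rep <- section_roughness(c(X1, X2), c(h1, h2), dX = 5)
  expect_equal(rep$n_sections, 2L)
  expect_equal(rep$sections$Ra, c(0.2, 0.4), tolerance = 1e-3)
  expect_equal(rep$Ra_bar, mean(rep$sections$Ra))
})

test_that("roughness is invariant under translation and linear trends", {
  set.seed(21)
  X <- seq(0, 20, 0.1)
  h <- 0.3 * sin(X) + rnorm(length(X), 0, 0.05)
  r0 <- section_roughness(X, h, 5)$Ra_bar
  r_shift <- section_roughness(X + 100, h + 42, 5)$Ra_bar
  # the reference line absorbs a (moderate) linear trend; the rotation
  # rescales residuals by cos(atan(slope)), negligible at vessel slopes
  r_trend <- section_roughness(X, h + 0.05 * X, 5)$Ra_bar
  expect_equal(r_shift, r0, tolerance = 1e-9)
  expect_lt(abs(r_trend - r0), 0.01 * r0)
})

test_that("sections with too few samples are skipped with a warning", {
  X <- c(seq(0, 4.9, 0.1), 7.4, 9)        # second section: only 2 samples
  h <- sin(X)
  expect_warning(rep <- section_roughness(X, h, 5), "skipped")
  expect_equal(rep$n_sections, 1L)
})

test_that("geometry roughness of an analytic tube is essentially zero", {
  spec <- phantom_spec("straight", diameter = 7, length = 30)
  th <- 2 * pi * (0:63) / 64
  xs <- seq(0, 30, 0.5)
  curves <- list(list(x = xs,
                      Y = outer(rep(3.5, length(xs)), cos(th)),
                      Z = outer(rep(3.5, length(xs)), sin(th))))
  expect_lt(geometry_roughness(curves, 5)$Ra_bar, 1e-9)
})

test_that("a voxelized tilted tube has sub-voxel raw roughness", {
  spec <- phantom_spec("curved", diameter = 7, length = 40, bend_angle = 30)
  cl <- extract_surface_points(voxelize(spec, 0.7), 0, 1)
  res <- smooth_vessel(cl)
  ra <- geometry_roughness(res$curves_raw, 5)$Ra_bar
  expect_gt(ra, 0)
  expect_lt(ra, 0.7)
  # determinism: same input, same report
  res2 <- smooth_vessel(extract_surface_points(voxelize(spec, 0.7), 0, 1))
  expect_identical(geometry_roughness(res2$curves_raw, 5)$Ra_bar, ra)
})

test_that("mesh volumes match closed forms for reference solids", {
  expect_equal(mesh_volume(cube_mesh()), 1, tolerance = 1e-12)
  expect_equal(mesh_volume(tetra_mesh()), sqrt(2) / 12, tolerance = 1e-12)
  errs <- vapply(1:3, function(s)
    abs(mesh_volume(icosphere(s)) - 4 * pi / 3), 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / (4 * pi / 3), 0.01)
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  expect_error(mesh_volume(tri), "closed")
})

test_that("volume ratio follows the scaling law", {
  cube <- cube_mesh()
  expect_equal(volume_ratio(cube, cube), 1)
  big <- surface_mesh(cube$vertices * 1.01, cube$faces)
  expect_equal(volume_ratio(cube, big), 1.01^3, tolerance = 1e-12)
})

test_that("near-wall shear follows tau = mu u / y and Poiseuille", {
  expect_equal(wall_shear_from_near_wall(0.1, 1e-4), 4.0)
  expect_equal(wall_shear_from_near_wall(0, 1e-4), 0)
  expect_error(wall_shear_from_near_wall(1, 0), "y_p")
  # Poiseuille tube D = 7.11 mm, mean velocity 0.23 m/s, sampled near wall
  D <- 7.11e-3; R <- D / 2; ubar <- 0.23
  y_p <- 0.05e-3
  u_at <- 2 * ubar * (1 - ((R - y_p) / R)^2)    # parabolic profile
  tau <- wall_shear_from_near_wall(u_at, y_p)
  expect_lt(abs(tau / (8 * 0.004 * ubar / D) - 1), 0.02)
})

test_that("surface-averaged WSS is the area-weighted shear magnitude", {
  f1 <- wall_field(c(1, 1, 1), tau_x = c(2, -2, 2))
  expect_equal(surface_averaged_wss(f1), 2)
  f2 <- wall_field(c(1, 3), tau_x = c(1, 5))
  expect_equal(surface_averaged_wss(f2), 4)
  # doubling all areas changes nothing
  f3 <- wall_field(c(2, 6), tau_x = c(1, 5))
  expect_equal(surface_averaged_wss(f3), 4)
  # vector fields use the magnitude
  f4 <- wall_field(c(1, 1), tau_vec = rbind(c(3, 4, 0), c(0, 0, 5)))
  expect_equal(surface_averaged_wss(f4), 5)
})

test_that("TAWSS integrates the waveform over its period", {
  t <- seq(0, 1, length.out = 2001)
  expect_equal(tawss(t, rep(3, length(t))), 3)
  expect_equal(tawss(t, 2 + sin(2 * pi * t)), 2, tolerance = 1e-3)
  expect_warning(one <- tawss(1, 5), "single")
  expect_equal(one, 5)
  expect_error(tawss(c(0, 0.5, 0.5), c(1, 2, 3)), "increasing")
})

test_that("the tau_x distribution conserves area fractions", {
  f <- wall_field(c(1, 1, 2), tau_x = c(-1, 1, 0.5))
  pdf <- wss_pdf(f, seq(-2, 2, 0.5))
  expect_equal(sum(pdf$fraction), 1, tolerance = 1e-12)
  # two equal-area groups at -1 and +1 Pa
  f2 <- wall_field(c(2, 2), tau_x = c(-1, 1))
  pdf2 <- wss_pdf(f2, c(-2, 0, 2))
  expect_equal(pdf2$fraction, c(0.5, 0.5))
  # overflow bins appear when data exceed the edges
  f3 <- wall_field(c(1, 1, 1), tau_x = c(-10, 0, 10))
  pdf3 <- wss_pdf(f3, c(-1, 1))
  expect_equal(sum(pdf3$fraction), 1, tolerance = 1e-12)
  expect_true(is.infinite(pdf3$lo[1]) && is.infinite(pdf3$hi[nrow(pdf3)]))
})

test_that("the tau_x distribution equals brute-force accumulation", {
  set.seed(13)
  f <- wall_field(runif(500, 0.5, 2), tau_x = rnorm(500))
  edges <- seq(-3, 3, 0.25)
  pdf <- wss_pdf(f, edges)
  for (b in seq_len(length(edges) - 1)) {
    sel <- f$tau_x >= edges[b] & f$tau_x < edges[b + 1]
    if (b == length(edges) - 1)
      sel <- f$tau_x >= edges[b] & f$tau_x <= edges[b + 1]
    expect_equal(pdf$fraction[pdf$lo == edges[b]],
                 sum(f$facet_area[sel]) / sum(f$facet_area),
                 tolerance = 1e-12)
  }
})

test_that("the carotid waveform bracket matches the tabulated coefficients", {
  wm <- waveform_model("LCA")
  q0 <- waveform_flow(wm, 0)
  expect_equal(q0$bracket, 0.26 - 0.10 - 0.10 - 0.03 - 0.014,
               tolerance = 1e-12)
  expect_equal(q0$Q_art, wm$A_art * wm$beta * q0$bracket, tolerance = 1e-15)
  # periodicity
  t <- c(0.13, 0.5, 0.99)
  expect_equal(waveform_flow(wm, t)$bracket,
               waveform_flow(wm, t + wm$T)$bracket, tolerance = 1e-12)
  # period mean equals a0 (trapezoid over a full period)
  tt <- seq(0, wm$T, length.out = 4001)
  br <- waveform_flow(wm, tt)$bracket
  mean_br <- sum(diff(tt) * (br[-1] + br[-length(br)]) / 2) / wm$T
  expect_equal(mean_br, 0.26, tolerance = 1e-9)
})

test_that("vertebral inlets share the waveform but scale their own area", {
  lva <- waveform_model("LVA")
  lca <- waveform_model("LCA")
  expect_equal(lva$A_art, 1.79e-5)
  expect_equal(lva$beta, 3.77e-5)
  expect_equal(waveform_flow(lva, 0.3)$bracket,
               waveform_flow(lca, 0.3)$bracket)
})

test_that("the parabolic inlet profile matches its closed forms", {
  wm <- waveform_model("RCA")
  q <- waveform_flow(wm, 0.2)
  expect_equal(inlet_velocity_profile(wm, wm$R, 0.2), 0)
  expect_equal(inlet_velocity_profile(wm, 0, 0.2), q$Q_art / wm$A_art,
               tolerance = 1e-12)
  expect_error(inlet_velocity_profile(wm, wm$R * 1.01, 0.2), "r must")
  # area average over the inlet disk is half the centerline value
  nr <- 4000
  r <- sqrt(seq(0.5 / nr, 1 - 0.5 / nr, length.out = nr)) * wm$R
  u <- inlet_velocity_profile(wm, r, 0.2)
  expect_equal(mean(u), 0.5 * q$Q_art / wm$A_art, tolerance = 1e-3)
})

test_that("facet areas integrate a mesh's surface", {
  m <- cube_mesh()
  expect_equal(sum(facet_areas(m)), 6, tolerance = 1e-12)
  s <- icosphere(3)
  expect_lt(abs(sum(facet_areas(s)) / (4 * pi) - 1), 0.01)
})
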