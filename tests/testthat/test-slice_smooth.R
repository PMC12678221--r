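ring_sections <- function(offsets, N = 24, r = 3, shift = 0) {
  th <- 2 * pi * (seq_len(N) - 1) / N
  lapply(offsets, function(o) {
    p <- cbind(r * cos(th) + o, r * sin(th))
    if (shift > 0) p <- p[c((shift + 1):N, 1:shift), ]
    p
  })
}

test_that("cyclic shifts are recovered exactly against exhaustive search", {
  secs <- ring_sections(c(0, 0))
  secs[[2]] <- secs[[2]][c(4:24, 1:3), ]    # rotate second ring by 3
  al <- align_generators(secs)
  expect_lt(max(abs(al$sections[[2]] - al$sections[[1]])), 1e-9)
  # exhaustive oracle on a noisy pair: FFT pick equals brute force
  set.seed(5)
  a <- secs[[1]] + matrix(rnorm(48, 0, 0.05), ncol = 2)
  N <- nrow(a)
  ssd <- vapply(0:(N - 1), function(s) {
    idx <- ((seq_len(N) - 1 + s) %% N) + 1
    sum((a[idx, ] - secs[[1]])^2)
  }, 0)
  al2 <- align_generators(list(secs[[1]], a))
  got <- sum((al2$sections[[2]] - al2$sections[[1]])^2)
  expect_equal(got, min(ssd), tolerance = 1e-9)
})

test_that("reversed contour orientation is detected and undone", {
  secs <- ring_sections(c(0, 0))
  secs[[2]] <- secs[[2]][c(1, 24:2), ]      # reversed ring
  al <- align_generators(secs)
  expect_true(al$reversed[2])
  expect_lt(max(abs(al$sections[[2]] - al$sections[[1]])), 1e-9)
})

test_that("an aligned stack is a fixed point of alignment", {
  secs <- ring_sections(c(0, 0.1, 0.2))
  al <- align_generators(secs)
  al2 <- align_generators(al$sections)
  expect_equal(al2$shifts[-1], c(0L, 0L))
  expect_false(any(al2$reversed))
})

test_that("natural splines reproduce the hand-solved toy system", {
  secs <- list(list(x = 0, pts = cbind(0, 0)),
               list(x = 1, pts = cbind(1, 0)),
               list(x = 2, pts = cbind(0, 0)))
  gss <- fit_slice_splines(secs)
  d <- evaluate_splines(gss, step = 0.5)
  # natural spline through (0,0),(1,1),(2,0): M_interior = -3, y(0.5) = 0.6875
  expect_equal(d$Y[d$x == 0.5], 0.6875, tolerance = 1e-12)
  # independent oracle: stats::splinefun natural
  sf <- stats::splinefun(c(0, 1, 2), c(0, 1, 0), method = "natural")
  expect_equal(as.numeric(d$Y), sf(d$x), tolerance = 1e-12)
})

test_that("splines agree with stats::splinefun on random knot sets", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(3:12, 1)
    x <- sort(runif(n, 0, 10))
    while (min(diff(x)) < 1e-3) x <- sort(runif(n, 0, 10))
    y <- rnorm(n)
    secs <- lapply(seq_len(n), function(i) list(x = x[i],
                                                pts = cbind(y[i], -y[i])))
    gss <- fit_slice_splines(secs)
    xd <- seq(x[1], x[n], length.out = 101)
    got <- vesselsmooth:::eval_coef(gss$knots, gss$coef_y, xd)
    sf <- stats::splinefun(x, y, method = "natural")
    expect_equal(as.numeric(got), sf(xd), tolerance = 1e-9)
  }
})

test_that("splines reproduce linear data exactly", {
  x <- c(0, 1.5, 2, 4, 7)
  secs <- lapply(x, function(xi) list(x = xi, pts = cbind(2 * xi + 1, 0)))
  gss <- fit_slice_splines(secs)
  xd <- seq(0, 7, 0.25)
  got <- vesselsmooth:::eval_coef(gss$knots, gss$coef_y, xd)
  expect_equal(as.numeric(got), 2 * xd + 1, tolerance = 1e-12)
})

test_that("interior knots join with C2 continuity", {
  set.seed(3)
  x <- 0:6
  y <- rnorm(7)
  secs <- lapply(1:7, function(i) list(x = x[i], pts = cbind(y[i], 0)))
  gss <- fit_slice_splines(secs)
  h <- 1e-5
  for (k in 2:6) {
    eps <- 1e-9
    f <- function(xx) vesselsmooth:::eval_coef(gss$knots, gss$coef_y, xx)
    # value, first and second derivative from both sides
    for (d2 in list(
      c(f(x[k] - eps), f(x[k] + eps)),
      c((f(x[k]) - f(x[k] - h)) / h, (f(x[k] + h) - f(x[k])) / h),
      c((f(x[k]) - 2 * f(x[k] - h) + f(x[k] - 2 * h)) / h^2,
        (f(x[k] + 2 * h) - 2 * f(x[k] + h) + f(x[k])) / h^2)))
      expect_lt(abs(d2[1] - d2[2]), 1e-3)
  }
})

test_that("dense evaluation covers the span inclusively", {
  secs <- lapply(seq(0, 50, 0.5), function(xi)
    list(x = xi, pts = cbind(sin(xi), cos(xi))))
  gss <- fit_slice_splines(secs)
  d <- evaluate_splines(gss, step = 0.1)
  expect_equal(length(d$x), 501L)
  expect_equal(d$x[1], 0); expect_equal(d$x[501], 50)
  # samples at knots equal knot values
  at_knots <- d$x %in% seq(0, 50, 0.5)
  expect_equal(as.numeric(d$Y[d$x == 2, ]), sin(2), tolerance = 1e-9)
  expect_error(evaluate_splines(gss, step = 100), "span")
})

test_that("a two-knot fit falls back to linear with a warning", {
  secs <- list(list(x = 0, pts = cbind(0, 1)), list(x = 2, pts = cbind(4, 3)))
  expect_warning(gss <- fit_slice_splines(secs), "linear")
  expect_true(gss$linear_fallback)
  d <- evaluate_splines(gss, 0.5)
  expect_equal(as.numeric(d$Y), 2 * d$x, tolerance = 1e-12)
})

test_that("the noise filter matches the hand-worked examples", {
  # center window: mean 2, population sigma 4, median 0; 10 outside (-2, 6)
  expect_equal(noise_filter_series(c(0, 0, 10, 0, 0), q = 1, m = 2),
               c(0, 0, 0, 0, 0))
  # constant series is a fixed point (replacement median equals the value)
  expect_equal(noise_filter_series(rep(3, 7), q = 1, m = 2), rep(3, 7))
  # linear ramp: center 2 inside (2 - sqrt(2), 2 + sqrt(2)), unchanged
  expect_equal(noise_filter_series(0:4, q = 1, m = 2), as.numeric(0:4))
})

test_that("the filter only edits samples outside their judgment interval", {
  set.seed(9)
  v <- rnorm(200)
  out <- noise_filter_series(v, q = 1, m = 2)
  n <- length(v)
  expect_equal(out[c(1, 2, n - 1, n)], v[c(1, 2, n - 1, n)])  # ends untouched
  for (i in 3:(n - 2)) {
    w <- v[(i - 2):(i + 2)]
    mu <- mean(w); sig <- sqrt(mean((w - mu)^2))
    inside <- mu - sig < v[i] && v[i] < mu + sig
    if (out[i] != v[i]) {
      expect_false(inside)
      expect_equal(out[i], median(w))
    } else {
      expect_true(inside || v[i] == median(w))
    }
  }
})

test_that("filter decisions come from the original series, not cascaded edits", {
  v <- c(0, 0, 10, 10, 0, 0, 0)
  out <- noise_filter_series(v, q = 1, m = 2)
  # recompute expected replacements from the untouched series
  n <- length(v)
  expected <- v
  for (i in 3:(n - 2)) {
    w <- v[(i - 2):(i + 2)]
    mu <- mean(w); sig <- sqrt(mean((w - mu)^2))
    if (!(mu - sig < v[i] && v[i] < mu + sig))
      expected[i] <- median(w)
  }
  expect_equal(out, expected)
  expect_error(noise_filter_series(c(1, 2), q = 1, m = 2), "shorter")
})

test_that("smoothing a clean voxel tube keeps a closed mesh and its volume", {
  spec <- phantom_spec("straight", diameter = 7, length = 30)
  cl <- extract_surface_points(voxelize(spec, 0.7), 0, 1)
  res <- smooth_vessel(cl)
  expect_true(res$mesh$closed)
  expect_true(res$raw_mesh$closed)
  expect_lt(abs(volume_ratio(res$raw_mesh, res$mesh) - 1), 0.05)
})

test_that("the pipeline is deterministic down to the STL bytes", {
  spec <- std_phantom()
  vm <- voxelize(spec, 0.7)
  cl <- extract_surface_points(vm, 0.35, 42)
  m1 <- smooth_geometry(cl)
  m2 <- smooth_geometry(extract_surface_points(vm, 0.35, 42))
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(m1, p1); write_stl(m2, p2)
  expect_identical(readBin(p1, "raw", file.info(p1)$size),
                   readBin(p2, "raw", file.info(p2)$size))
})

test_that("smoothing moves the surface towards the analytic truth", {
  spec <- std_phantom()
  vm <- voxelize(spec, 0.7)
  cl <- extract_surface_points(vm, 0.35, 42)
  res <- smooth_vessel(cl)
  d_raw <- phantom_surface_distance(res$raw_mesh$vertices, spec)
  d_sm <- phantom_surface_distance(res$mesh$vertices, spec)
  expect_lt(d_sm, d_raw)
})

test_that("most reference points survive the filter unchanged", {
  spec <- std_phantom()
  cl <- extract_surface_points(voxelize(spec, 0.7), 0.35, 42)
  res <- smooth_vessel(cl)
  expect_lt(res$altered_fraction, 0.5)
  expect_gt(res$altered_fraction, 0)
})

test_that("volume stays within a few percent across phantom shapes", {
  for (spec in list(std_phantom(),
                    phantom_spec("straight", diameter = 7.1, length = 40),
                    phantom_spec("curved", diameter = 6, length = 40,
                                 bend_angle = 30))) {
    cl <- extract_surface_points(voxelize(spec, 0.7), 0.35, 11)
    res <- smooth_vessel(cl)
    expect_lt(abs(volume_ratio(res$raw_mesh, res$mesh) - 1), 0.05)
  }
})
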