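test_that("cartesian masks have the required structure", {
  m <- make_cartesian_mask(256, R = 2, seed = 1)
  expect_equal(length(m$kept_lines), 128)
  expect_true(0 %in% m$kept_lines)

  full <- make_cartesian_mask(16, R = 1, scheme = "full")
  expect_equal(length(full$kept_lines), 16)

  m8 <- make_cartesian_mask(8, R = 4, seed = 9)
  expect_equal(length(m8$kept_lines), 2)
  expect_true(0 %in% m8$kept_lines)
  expect_identical(m8$kept_lines, make_cartesian_mask(8, R = 4, seed = 9)$kept_lines)

  # Hermitian symmetry: a kept line's mirror is kept (Nyquist self-mirrors)
  for (scheme in c("uniform_random", "center_band_random")) {
    mm <- make_cartesian_mask(32, R = 4, scheme = scheme, seed = 3)
    k <- mm$kept_lines
    mirror <- ifelse(k == -16, -16, -k)
    expect_setequal(k, mirror)
  }
  expect_error(make_cartesian_mask(16, R = 0.5), "R")
  expect_error(make_cartesian_mask(16, R = 32), "R")
})

test_that("forward measurement matches the brute-force DFT on an impulse", {
  n <- 8
  f <- matrix(0, n, n); f[1, 1] <- 1
  model <- forward_model(make_cartesian_mask(n, R = 1, scheme = "full"), 0)
  g <- forward_measure(f, model)
  expect_equal(max(Mod(g$values - 1)), 0, tolerance = 1e-12)
  # brute-force double-sum DFT at a few frequencies for a random image
  set.seed(4)
  f2 <- matrix(rnorm(n * n), n)
  g2 <- forward_measure(f2, model)
  for (ky in c(-2, 0, 3)) for (kx in c(-1, 0, 2)) {
    s <- 0
    for (a in 0:(n - 1)) for (b in 0:(n - 1)) {
      s <- s + f2[a + 1, b + 1] * exp(-2i * pi * (ky * a + kx * b) / n)
    }
    expect_equal(g2$values[ky + n / 2 + 1, kx + n / 2 + 1], s, tolerance = 1e-9)
  }
})

test_that("k-space noise has the configured per-component std", {
  n <- 32
  model <- forward_model(make_cartesian_mask(n, R = 1, scheme = "full"), 2.5)
  draws <- unlist(lapply(1:60, function(i) {
    g <- forward_measure(matrix(0, n, n), model, seed = i)
    c(Re(g$values), Im(g$values))
  }))
  expect_gt(length(draws), 1e5)
  expect_equal(stats::sd(draws), 2.5, tolerance = 0.02)
})

test_that("noise lands only on sampled lines and zero-noise forward is linear", {
  n <- 16
  m <- make_cartesian_mask(n, R = 4, seed = 2)
  model <- forward_model(m, 3)
  g <- forward_measure(matrix(0, n, n), model, seed = 1)
  rows <- m$kept_lines + n / 2 + 1
  expect_true(all(Mod(g$values[-rows, ]) == 0))
  expect_true(all(Mod(g$values[rows, ]) > 0))

  model0 <- forward_model(m, 0)
  set.seed(1)
  a <- matrix(rnorm(n * n), n); b <- matrix(rnorm(n * n), n)
  gsum <- forward_measure(a + 2 * b, model0)$values
  expect_equal(gsum, forward_measure(a, model0)$values + 2 * forward_measure(b, model0)$values,
               tolerance = 1e-10)
})

test_that("zero-filled reconstruction matches brute-force IDFT conventions", {
  ones <- matrix(1 + 0i, 2, 2)
  g <- structure(list(values = ones,
                      mask = make_cartesian_mask(2, R = 1, scheme = "full"),
                      kspace_std = 0, seed = 0), class = "kspace_data")
  expect_equal(pseudoinverse_reconstruct(g), matrix(c(1, 0, 0, 0), 2, 2),
               tolerance = 1e-12)
  g0 <- structure(list(values = matrix(0 + 0i, 4, 4),
                       mask = make_cartesian_mask(4, R = 1, scheme = "full"),
                       kspace_std = 0, seed = 0), class = "kspace_data")
  expect_equal(pseudoinverse_reconstruct(g0), matrix(0, 4, 4))
  expect_equal(magnitude_reconstruct(g0), matrix(0, 4, 4))
})

test_that("full-mask zero-noise measurement inverts exactly", {
  n <- 16
  set.seed(8)
  f <- matrix(runif(n * n), n)
  model <- forward_model(make_cartesian_mask(n, R = 1, scheme = "full"), 0)
  g <- forward_measure(f, model)
  expect_equal(pseudoinverse_reconstruct(g), f, tolerance = 1e-12)
  expect_equal(magnitude_reconstruct(g), f, tolerance = 1e-12)
})

test_that("reconstruction noise scales as sigma over N", {
  n <- 64; sigma <- 4
  model <- forward_model(make_cartesian_mask(n, R = 1, scheme = "full"), sigma)
  px <- unlist(lapply(1:30, function(i) {
    pseudoinverse_reconstruct(forward_measure(matrix(0, n, n), model, seed = i))
  }))
  expect_equal(stats::sd(px), sigma / n, tolerance = 0.02)
})

test_that("operator algebra: projector identities hold at float precision", {
  n <- 32
  set.seed(10)
  f <- matrix(rnorm(n * n), n)
  for (R in c(1, 1.25, 2, 4)) {
    scheme <- if (R == 1) "full" else "uniform_random"
    m <- make_cartesian_mask(n, R = R, scheme = scheme, seed = 21)
    p1 <- measurement_component(f, m)
    p2 <- measurement_component(p1, m)
    expect_lt(max(abs(p2 - p1)), 1e-10)
    # DFT of the measurement component agrees with DFT(f) on kept lines, 0 off
    kf <- ambientsom:::fft2_centered(f)
    kp <- ambientsom:::fft2_centered(p1)
    rows <- m$kept_lines + n / 2 + 1
    expect_lt(max(Mod(kp[rows, ] - kf[rows, ])), 1e-9)
    if (length(rows) < n) expect_lt(max(Mod(kp[-rows, ])), 1e-9)
  }
  full <- make_cartesian_mask(n, R = 1, scheme = "full")
  expect_equal(measurement_component(f, full), f, tolerance = 1e-12)
})

test_that("the projector adjoint satisfies the inner-product identity", {
  n <- 16
  set.seed(3)
  f <- matrix(rnorm(n * n), n); v <- matrix(rnorm(n * n), n)
  for (R in c(1.25, 2, 4)) {
    m <- make_cartesian_mask(n, R = R, seed = 5)
    ip1 <- sum(v * measurement_component(f, m))
    ip2 <- sum(ambientsom:::measurement_component_adjoint(v, m) * f)
    expect_equal(ip1, ip2, tolerance = 1e-10)
  }
})

test_that("corrected fake reconstruction follows its two branches", {
  n <- 16
  model0 <- forward_model(make_cartesian_mask(n, R = 1, scheme = "full"), 0)
  set.seed(6)
  f_pos <- matrix(runif(n * n), n)
  expect_equal(corrected_fake_reconstruct(f_pos, model0), f_pos, tolerance = 1e-12)

  f_neg <- f_pos; f_neg[3, 5] <- -0.5
  out <- corrected_fake_reconstruct(f_neg, model0)
  expect_equal(out[3, 5], -0.5, tolerance = 1e-12)
  expect_equal(out, f_neg, tolerance = 1e-12)

  # with noise: equals the composed oracle on nonnegative objects,
  # and equals f + abs(IDFT(n)) on the ReLU-zeroed pixels
  model <- forward_model(make_cartesian_mask(n, R = 1, scheme = "full"), 2)
  out2 <- corrected_fake_reconstruct(f_pos, model, seed = 31)
  oracle <- magnitude_reconstruct(forward_measure(f_pos, model, seed = 31))
  expect_identical(out2, oracle)
  f_mix <- f_pos; f_mix[1:2, ] <- -f_pos[1:2, ]
  out3 <- corrected_fake_reconstruct(f_mix, model, seed = 32)
  noise_mag <- magnitude_reconstruct(forward_measure(matrix(0, n, n), model, seed = 32))
  neg <- f_mix < 0
  expect_equal(out3[neg], (f_mix + noise_mag)[neg], tolerance = 1e-12)

  mu <- make_cartesian_mask(n, R = 2, seed = 1)
  expect_error(corrected_fake_reconstruct(f_pos, forward_model(mu, 0)), "full")
})

test_that("k-space containers round-trip and masks export", {
  n <- 8
  m <- make_cartesian_mask(n, R = 2, seed = 4)
  g <- forward_measure(matrix(1, n, n), forward_model(m, 1), seed = 2)
  path <- tempfile(fileext = ".rds")
  write_kspace(g, path)
  back <- read_kspace(path)
  expect_identical(back$values, g$values)
  p <- export_mask_png(m, tempfile(fileext = ".png"))
  expect_true(file.exists(p))
})
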