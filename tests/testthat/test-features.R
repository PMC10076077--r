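test_that("Savitzky-Golay derivatives are exact on low-order polynomials", {
  fs <- 500
  t <- (0:99) / fs
  # constant position: zero velocity and acceleration
  rec <- gaze_recording(x = rep(5, 100), y = rep(5, 100), t = t, fs = fs)
  d <- differentiate(rec)
  inner <- !d$missing
  expect_true(all(abs(d$vel[inner]) < 1e-8))
  expect_true(all(abs(d$acc[inner]) < 1e-8))

  # linear ramp at 10 deg/s
  rec <- gaze_recording(x = t * 10, y = rep(0, 100), t = t, fs = fs)
  d <- differentiate(rec)
  expect_equal(d$vel[!d$missing], rep(10, sum(!d$missing)), tolerance = 1e-8)
  expect_true(all(abs(d$acc[!d$missing]) < 1e-6))

  # quadratic: acceleration 2 deg/s^2, cross-checked against a central
  # finite-difference oracle on the noiseless signal
  rec <- gaze_recording(x = t^2, y = rep(0, 100), t = t, fs = fs)
  d <- differentiate(rec)
  expect_equal(d$acc[!d$missing], rep(2, sum(!d$missing)), tolerance = 1e-6)
  fd <- diff(diff(rec$x)) * fs^2
  expect_equal(mean(d$acc[!d$missing]), mean(fd), tolerance = 1e-6)
  expect_error(differentiate(gaze_recording(x = 1:3, y = 1:3, fs = fs)),
               "shorter than")
})

test_that("sample angles follow the counter-clockwise convention on [0, 2*pi)", {
  fs <- 500
  mk <- function(x, y) gaze_recording(x = x, y = y, fs = fs)
  expect_equal(sample_angle(mk(c(0, 1, 2), c(0, 0, 0)))[2], 0)
  expect_equal(sample_angle(mk(c(0, 1, 0), c(0, 0, 0)))[2], pi)
  expect_equal(sample_angle(mk(c(0, 1, 1), c(0, 0, 1)))[2], pi / 2)
  # right turn wraps to 3*pi/2 (atan2-of-cross/dot vector-geometry oracle)
  expect_equal(sample_angle(mk(c(0, 1, 1), c(0, 0, -1)))[2], 3 * pi / 2)
  # boundary samples and zero-length displacements are undefined
  a <- sample_angle(mk(c(0, 1, 1, 2), c(0, 0, 0, 0)))
  expect_true(is.na(a[1]) && is.na(a[4]))
  expect_true(is.na(a[2]) && is.na(a[3]))
})

test_that("angles of an isotropic random walk are uniform on the circle", {
  set.seed(42)
  n <- 20000
  rec <- gaze_recording(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)), fs = 500)
  a <- sample_angle(rec)
  a <- a[!is.na(a)]
  resultant <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  expect_lt(resultant, 0.02)
})

test_that("pad_blinks marks a symmetric margin and is idempotent", {
  fs <- 500
  n <- 200
  blink <- rep(FALSE, n)
  blink[100:110] <- TRUE
  rec <- gaze_recording(x = rnorm(n), y = rnorm(n), fs = fs, blink = blink)
  out <- pad_blinks(rec, 50)
  expect_true(all(out$missing[75:135]))
  expect_false(any(out$missing[c(1:74, 136:n)]))
  expect_equal(out$blink, blink)
  expect_identical(pad_blinks(out, 50)$missing, out$missing)

  # no blinks: identity; zero padding: blink samples only
  rec2 <- gaze_recording(x = rnorm(n), y = rnorm(n), fs = fs)
  expect_identical(pad_blinks(rec2, 50), rec2)
  out0 <- pad_blinks(rec, 0)
  expect_equal(which(out0$missing), 100:110)
})

test_that("scale_features divides vel/acc and tracks the factor", {
  f <- feature_series(vel = c(300, 10), acc = c(1000, 20),
                      angle = c(0, 1), scale_factor = 1)
  g <- scale_features(f, 100)
  expect_equal(g$vel, c(3, 0.1))
  expect_equal(g$acc, c(10, 0.2))
  expect_equal(g$angle, f$angle)
  expect_equal(g$scale_factor, 100)
  expect_equal(scale_features(f, 1), f)
  expect_error(scale_features(f, -2), "positive")
})

test_that("gamma scale estimates transfer across feature scalings", {
  set.seed(3)
  p <- default_parameters(2, scale_factor = 10)
  sim <- simulate_hmm(p, 3000)
  f1 <- sim$features
  f2 <- scale_features(f1, 10)
  s1 <- default_parameters(2, scale_factor = 10)
  s2 <- default_parameters(2, scale_factor = 100)
  fit1 <- fit_hmm(f1, k = 2, start = s1)
  fit2 <- fit_hmm(f2, k = 2, start = s2)
  c1 <- coef(fit1)
  c2 <- coef(fit2)
  sc <- grepl("^beta_(vel|acc)_", names(c1))
  expect_equal(c2[sc] * 10, c1[sc], tolerance = 1e-4)
  expect_equal(c2[!sc], c1[!sc], tolerance = 1e-4)
  expect_identical(fit1$states, fit2$states)
  # raw-scale reporting undoes the scaling
  expect_equal(coef(fit2, scale = "raw")[sc], coef(fit1, scale = "raw")[sc],
               tolerance = 1e-4)
})
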