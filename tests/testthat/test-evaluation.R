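test_that("rmdspd matches hand-computed values and conventions", {
  expect_equal(rmdspd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmdspd(2, 3), 0.5)
  # zero truths (circular means) are replaced by 2*pi
  expect_equal(rmdspd(0, pi), 0.5)
  # circular scoring wraps near-2*pi estimates back to small errors
  expect_gt(rmdspd(0, 2 * pi - 0.01), 0.9)
  expect_lt(rmdspd(0, 2 * pi - 0.01, circular = TRUE), 0.01)
  # scale invariance
  set.seed(51)
  tr <- runif(20, 1, 5)
  est <- tr * runif(20, 0.8, 1.2)
  expect_equal(rmdspd(tr, est), rmdspd(10 * tr, 10 * est))
  expect_error(rmdspd(1:3, 1:2), "align")
})

test_that("Cohen's kappa matches the definitional formula and an oracle", {
  expect_equal(cohens_kappa(c(1, 2, 1), c(1, 2, 1)), 1)
  # 2x2 contingency (50, 10; 10, 30): direct (p_o - p_e)/(1 - p_e)
  a <- rep(c(1, 1, 2, 2), c(50, 10, 10, 30))
  b <- rep(c(1, 2, 1, 2), c(50, 10, 10, 30))
  p_o <- 80 / 100
  p_e <- 0.6 * 0.6 + 0.4 * 0.4
  expect_equal(cohens_kappa(a, b), (p_o - p_e) / (1 - p_e))
  # independent cross-check
  skip_if_not_installed("e1071")
  expect_equal(cohens_kappa(a, b),
               e1071::classAgreement(table(a, b))$kappa)
  set.seed(52)
  x <- sample(1:3, 2000, replace = TRUE)
  y <- sample(1:3, 2000, replace = TRUE)
  expect_equal(cohens_kappa(x, y),
               e1071::classAgreement(table(x, y))$kappa)
})

test_that("independent labelings have near-zero kappa", {
  set.seed(53)
  x <- sample(1:4, 1e5, replace = TRUE)
  y <- sample(1:4, 1e5, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y)), 0.02)
})

test_that("label-switch resolution finds the best permutation", {
  set.seed(54)
  truth <- sample(1:3, 500, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  swap <- c(2L, 1L, 3L)
  est <- swap[truth]
  m <- best_permutation_match(truth, est)
  expect_equal(m$kappa, 1)
  expect_equal(m$permutation[est], truth)
  # identity stays identity when already optimal
  m2 <- best_permutation_match(truth, truth)
  expect_identical(m2$permutation, 1:3)
  # never below the identity kappa; agrees with explicit 6-permutation
  # brute force using independently generated labels
  est3 <- sample(1:3, 500, replace = TRUE)
  m3 <- best_permutation_match(truth, est3)
  expect_gte(m3$kappa, cohens_kappa(truth, est3))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  brute <- max(vapply(perms, function(p)
    cohens_kappa(truth, p[est3]), numeric(1)))
  expect_equal(m3$kappa, brute)
})

test_that("recovery regression returns OLS intercept and slope", {
  tr <- seq(1, 5, length.out = 20)
  expect_equal(recovery_regression(tr, tr),
               c(intercept = 0, slope = 1))
  expect_equal(recovery_regression(tr, tr + 2),
               c(intercept = 2, slope = 1))
  set.seed(55)
  est <- 0.5 * tr + rnorm(20, 0, 1e-3)
  r <- recovery_regression(tr, est)
  expect_equal(unname(r["slope"]), 0.5, tolerance = 0.01)
  expect_error(recovery_regression(rep(1, 5), 1:5), "constant")
})

test_that("model weights convert criteria as Schwarz weights", {
  expect_equal(model_weights(c(10, 10)), c(0.5, 0.5))
  w <- model_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)))
  set.seed(56)
  cr <- runif(5, 100, 200)
  expect_equal(sum(model_weights(cr)), 1)
  # invariant to adding a constant
  expect_equal(model_weights(cr), model_weights(cr + 1234))
  # smallest criterion gets the largest weight
  expect_equal(which.max(model_weights(cr)), which.min(cr))
  expect_error(model_weights(c(1, NA)), "finite")
})

test_that("agreement_report summarizes two labelings", {
  fs <- 500
  t <- (0:99) / fs
  a <- rep(c("fixation", "saccade", "fixation"), c(40, 10, 50))
  r0 <- agreement_report(a, a, t)
  expect_equal(unname(r0$rmsd), c(0, 0))
  expect_equal(r0$disagreement, 0)
  expect_true(all(diag(as.matrix(r0$confusion)) == 1))
  expect_equal(unname(r0$event_kappa), c(1, 1))

  # complementary labelings disagree on every sample
  b <- rep(c("saccade", "fixation", "saccade"), c(40, 10, 50))
  expect_equal(agreement_report(a, b, t)$disagreement, 1)

  # hand-computed RMSD for constructed labelings (relative normalization)
  b2 <- rep(c("fixation", "saccade", "fixation"), c(45, 5, 50))
  rep2 <- agreement_report(b2, a, t)
  # fixation: durations a = (0.078, 0.118) -> b2 = (0.088, 0.108);
  # counts both 2
  ev_a <- event_descriptives(build_events(a, t))
  ev_b <- event_descriptives(build_events(b2, t))
  for (ty in c("fixation", "saccade")) {
    ra <- ev_a[ev_a$type == ty, ]
    rb <- ev_b[ev_b$type == ty, ]
    dev <- c((rb$mean_duration - ra$mean_duration) / ra$mean_duration,
             (rb$sd_duration - ra$sd_duration) /
               ifelse(ra$sd_duration == 0, 1, ra$sd_duration),
             (rb$n - ra$n) / ra$n)
    expect_equal(unname(rep2$rmsd[ty]), sqrt(mean(dev^2)), tolerance = 1e-10)
  }
  # confusion columns sum to one
  expect_equal(unname(colSums(as.matrix(rep2$confusion))), c(1, 1))
})
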