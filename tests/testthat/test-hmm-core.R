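toy_params <- function(k) {
  em <- list(state_emission(3, 0.2, 3, 7, "uniform"),
             state_emission(3, 5, 3, 200, "von_mises", mu = 0, kappa = 5),
             state_emission(3, 1.5, 3, 150, "von_mises", mu = pi,
                            kappa = 5))[seq_len(k)]
  rho <- c(0.6, 0.3, 0.1)[seq_len(k)]
  rho <- rho / sum(rho)
  hmm_parameters(rho, gazehmm:::transition_matrix(k, 0.8), em)
}

test_that("forward log-likelihood equals exhaustive path enumeration", {
  set.seed(21)
  for (k in 2:3) {
    p <- toy_params(k)
    sim <- simulate_hmm(p, 6)
    oracle <- enumerate_paths(p, sim$features)
    expect_equal(sequence_loglik(p, sim$features), oracle$loglik,
                 tolerance = 1e-10)
  }
})

test_that("Viterbi equals the argmax over all enumerated paths", {
  set.seed(22)
  for (rep in 1:5) {
    p <- toy_params(3)
    sim <- simulate_hmm(p, 6)
    oracle <- enumerate_paths(p, sim$features)
    expect_identical(viterbi_decode(p, sim$features), oracle$best)
  }
  # a single extreme-velocity sample inside a sticky chain yields a
  # single-sample excursion to the saccade state
  p <- toy_params(2)
  p$A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
  feats <- toy_features(vel = c(0.5, 0.6, 40, 0.5, 0.4, 0.6),
                        acc = c(5, 6, 600, 6, 5, 6),
                        angle = rep(0.2, 6))
  path <- viterbi_decode(p, feats)
  oracle <- enumerate_paths(p, feats)
  expect_identical(path, oracle$best)
  expect_identical(path, c(1L, 1L, 2L, 1L, 1L, 1L))
})

test_that("k = 1 degenerates to an i.i.d. model", {
  em <- list(state_emission(2, 1, 2, 1, "uniform"))
  p <- hmm_parameters(1, matrix(1, 1, 1), em)
  feats <- toy_features(vel = c(1, 2, 3), acc = c(1, 1, 2),
                        angle = c(0, 1, 2))
  expect_equal(sequence_loglik(p, feats),
               sum(emission_logdensity(em[[1]], feats$vel, feats$acc,
                                       feats$angle)))
  expect_identical(viterbi_decode(p, feats), rep(1L, 3))
})

test_that("missing samples are integrated out of the likelihood", {
  set.seed(23)
  p <- toy_params(2)
  sim <- simulate_hmm(p, 6)
  feats <- sim$features
  # all missing: every path has emission density one, loglik = 0
  allmiss <- feats
  allmiss$missing <- rep(TRUE, 6)
  expect_equal(sequence_loglik(p, allmiss), 0)
  # one missing sample: matches enumeration with that row integrated out
  onemiss <- feats
  onemiss$missing[3] <- TRUE
  oracle <- enumerate_paths(p, onemiss)
  expect_equal(sequence_loglik(p, onemiss), oracle$loglik, tolerance = 1e-10)
  # posterior rows still sum to one on missing samples
  ld <- gazehmm:::emission_logdensity_matrix(p, onemiss)
  es <- gazehmm:::hmm_estep_cpp(ld, p$rho, p$A)
  expect_equal(rowSums(es$gamma), rep(1, 6), tolerance = 1e-10)
})

test_that("EM increases the likelihood monotonically and recovers truth", {
  set.seed(24)
  truth <- default_parameters(2, scale_factor = 10)
  sim <- simulate_hmm(truth, 10000)
  fit <- fit_hmm(sim$features, k = 2, start = random_starts(truth))
  expect_true(fit$converged)
  # monotone trace (within numerical tolerance)
  rel <- diff(fit$loglik_trace) / (abs(head(fit$loglik_trace, -1)) + 1e-10)
  expect_true(all(rel > -1e-8))
  # final loglik at least the starting loglik
  expect_gte(fit$loglik, fit$loglik_trace[1])
  # proportional deviations below 0.1 for every recoverable parameter
  tt <- gazehmm:::as_parameter_table(truth)
  keep <- !grepl("^rho_", tt$parameter)
  est <- coef(fit)[tt$parameter[keep]]
  tr <- tt$value[keep]
  dev <- (est - tr) / ifelse(tr == 0, 2 * pi, tr)
  circ <- grepl("^mu_", tt$parameter[keep])
  dev[circ] <- (((est[circ] - tr[circ]) + pi) %% (2 * pi) - pi) / (2 * pi)
  expect_true(all(abs(dev) < 0.1))
  # posteriors are proper distributions
  expect_equal(rowSums(fit$posteriors), rep(1, 10000), tolerance = 1e-10)
  expect_true(all(fit$states %in% 1:2))
})

test_that("EM started at the maximum stops immediately", {
  set.seed(25)
  truth <- default_parameters(2, scale_factor = 10)
  sim <- simulate_hmm(truth, 2000)
  fit1 <- fit_hmm(sim$features, k = 2, start = random_starts(truth))
  fit2 <- fit_hmm(sim$features, k = 2, start = fit1$params)
  expect_true(fit2$converged)
  expect_lte(fit2$n_iter, 3)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-6)
})

test_that("information criteria follow their definitions", {
  set.seed(26)
  # k = 1: completed and marginal likelihood coincide, so icl = bic
  em <- list(state_emission(2, 1, 2, 1, "uniform"))
  p1 <- hmm_parameters(1, matrix(1, 1, 1), em)
  sim <- simulate_hmm(p1, 200)
  fit1 <- fit_hmm(sim$features, k = 1, start = p1)
  expect_equal(fit1$icl, fit1$bic, tolerance = 1e-8)
  expect_equal(fit1$bic, -2 * fit1$loglik + fit1$n_free * log(fit1$n_obs))

  # k = 3 toy fit: icl >= bic always
  truth <- default_parameters(3, scale_factor = 10)
  sim3 <- simulate_hmm(truth, 1500)
  fit3 <- fit_hmm(sim3$features, k = 3, start = random_starts(truth))
  expect_gte(fit3$icl, fit3$bic)
  expect_equal(information_criteria(fit3),
               c(bic = fit3$bic, icl = fit3$icl))
  # free-parameter count: (k-1) + k(k-1) + 4k + 2(k-1)
  expect_equal(fit3$n_free, 2 + 6 + 12 + 4)
})

test_that("default and randomized starting values follow the scheme", {
  s4 <- default_starts(4)
  expect_equal(s4$rho, rep(0.25, 4))
  expect_equal(diag(s4$A), rep(0.9, 4))
  expect_equal(rowSums(s4$A), rep(1, 4))
  expect_equal(s4$emissions[[1]]$angle_kind, "uniform")
  expect_error(default_starts(7), "1..5")

  # random starts: gamma(shape 3, scale theta/2) has mode theta
  set.seed(27)
  draws <- rgamma(1e5, shape = 3, scale = 4 / 2)
  d <- density(draws)
  expect_equal(d$x[which.max(d$y)], 4, tolerance = 0.4)
  truth <- default_parameters(3, scale_factor = 10)
  rs <- random_starts(truth)
  expect_equal(rs$rho, rep(1 / 3, 3))
  expect_true(all(rs$A == 1 / 3))
  expect_equal(rs$emissions[[2]]$mu, truth$emissions[[2]]$mu)
  expect_gt(rs$emissions[[2]]$kappa, 0)
})

test_that("the state-order sanity check warns on violated ordering", {
  set.seed(28)
  truth <- default_parameters(2, scale_factor = 10)
  sim <- simulate_hmm(truth, 2000)
  fit <- fit_hmm(sim$features, k = 2, start = random_starts(truth))
  expect_silent(sanity_check(fit))
  swapped <- fit
  swapped$params$emissions <- rev(swapped$params$emissions)
  # emission list order no longer matches the event semantics
  swapped$params$emissions[[1]]$angle_kind <- "uniform"
  w <- capture_warnings(sanity_check(swapped))
  expect_length(w, 2)
  expect_match(w, "mean velocity", all = TRUE)
})
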