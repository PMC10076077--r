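# Independent oracles and fixture builders used across the test files.

# Emission log-density matrix computed directly from the component
# densities (not via the package's matrix builder), for the enumeration
# oracle.
oracle_logdens <- function(params, feats) {
  n <- length(feats$vel)
  k <- params$k
  ld <- matrix(0, n, k)
  for (j in seq_len(k)) {
    e <- params$emissions[[j]]
    for (t in seq_len(n)) {
      if (feats$missing[t]) next
      d <- dgamma(max(feats$vel[t], 1e-6), shape = e$alpha_vel,
                  scale = e$beta_vel, log = TRUE) +
        dgamma(max(feats$acc[t], 1e-6), shape = e$alpha_acc,
               scale = e$beta_acc, log = TRUE)
      d <- d + if (e$angle_kind == "uniform") -log(2 * pi) else
        e$kappa * cos(feats$angle[t] - e$mu) - log(2 * pi) -
          log(besselI(e$kappa, 0, expon.scaled = TRUE)) - e$kappa
      ld[t, j] <- d
    }
  }
  ld
}

# Exhaustive enumeration over all k^n state paths: joint log-probability
# of each path, the marginal log-likelihood, and the best path (ties
# resolved toward the lexicographically smallest path, i.e. lower state
# indices first).
enumerate_paths <- function(params, feats) {
  n <- length(feats$vel)
  k <- params$k
  ld <- oracle_logdens(params, feats)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n))[, n:1, drop = FALSE])
  lp <- apply(paths, 1, function(s) {
    v <- log(params$rho[s[1]]) + ld[1, s[1]]
    for (t in seq_len(n)[-1])
      v <- v + log(params$A[s[t - 1], s[t]]) + ld[t, s[t]]
    v
  })
  m <- max(lp)
  # expand.grid reversed above makes rows lexicographic, so which.max
  # returns the smallest tied path
  list(loglik = m + log(sum(exp(lp - m))),
       best = as.integer(paths[which.max(lp), ]),
       logprobs = lp)
}

# Small deterministic feature series for toy problems.
toy_features <- function(vel, acc, angle, missing = NULL) {
  feature_series(vel = vel, acc = acc, angle = angle, missing = missing,
                 scale_factor = 1)
}

# A synthetic position trace alternating fixations and saccades, with an
# optional blink stretch, for end-to-end pipeline tests.
make_position_trace <- function(fs = 500, n_fix = 4, fix_dur = 0.4,
                                sacc_dur = 0.04, amp = 8, jitter = 0.01,
                                blink_at = NULL, blink_dur = 0.1) {
  x <- c(); y <- c(); truth <- c()
  x0 <- 0
  for (i in seq_len(n_fix)) {
    nf <- round(fix_dur * fs)
    x <- c(x, x0 + cumsum(rnorm(nf, 0, jitter)))
    y <- c(y, cumsum(rnorm(nf, 0, jitter)))
    truth <- c(truth, rep("fixation", nf))
    if (i < n_fix) {
      ns <- round(sacc_dur * fs)
      # smooth (cosine) ramp to the next fixation position
      ramp <- (1 - cos(seq(0, pi, length.out = ns))) / 2
      x <- c(x, x0 + amp * ramp)
      y <- c(y, rep(tail(y, 1), ns))
      truth <- c(truth, rep("saccade", ns))
      x0 <- x0 + amp
    }
  }
  n <- length(x)
  blink <- rep(FALSE, n)
  if (!is.null(blink_at)) {
    i0 <- round(blink_at * fs)
    blink[i0:(i0 + round(blink_dur * fs))] <- TRUE
  }
  rec <- gaze_recording(x = x, y = y, fs = fs, blink = blink)
  list(recording = rec, truth = truth)
}
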