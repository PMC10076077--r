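# Generative simulator and the parameter-recovery study harness.

#' Simulate features from the generative model
#'
#' Draws a hidden state sequence from the initial and transition submodels
#' and per-sample features from each state's emission distributions:
#' gamma velocity and acceleration, circular-uniform angle for state 1 and
#' von Mises angles for the other states. The simulator works directly on
#' the feature level (velocity/acceleration/angle), matching the model's
#' sampling space; position-level synthesis is out of scope.
#'
#' @param params an [hmm_parameters()] object.
#' @param n number of samples (`>= 1`).
#' @param missing optional logical mask of samples to flag missing.
#' @return list with `states` (integer vector) and `features`
#'   (a [feature_series()]).
#' @export
simulate_hmm <- function(params, n, missing = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  k <- params$k
  states <- integer(n)
  states[1] <- sample.int(k, 1, prob = params$rho)
  if (n > 1) {
    # draw all uniforms at once; invert each row's CDF as we walk the chain
    cumA <- t(apply(params$A, 1, cumsum))
    u <- runif(n - 1)
    for (t in 2:n) {
      states[t] <- findInterval(u[t - 1], cumA[states[t - 1], ],
                                left.open = TRUE) + 1L
    }
  }
  vel <- numeric(n); acc <- numeric(n); ang <- numeric(n)
  for (j in seq_len(k)) {
    idx <- which(states == j)
    if (length(idx) == 0) next
    e <- params$emissions[[j]]
    vel[idx] <- rgamma(length(idx), shape = e$alpha_vel, scale = e$beta_vel)
    acc[idx] <- rgamma(length(idx), shape = e$alpha_acc, scale = e$beta_acc)
    ang[idx] <- if (e$angle_kind == "uniform") {
      runif(length(idx), 0, 2 * pi)
    } else {
      rvonmises(length(idx), e$mu, e$kappa)
    }
  }
  if (is.null(missing)) missing <- rep(FALSE, n)
  feats <- feature_series(vel = vel, acc = acc, angle = ang,
                          missing = missing, scale_factor = 1)
  list(states = states, features = feats)
}

#' Inject measurement noise into simulated features
#'
#' Replaces each non-missing velocity and acceleration value `y` by a draw
#' from a gamma distribution with shape 3 and scale `(y/2) * tau`, keeping
#' the values positive and moderately skewed, and adds von Mises white
#' noise with mean 0 and concentration `kappa_noise` to each angle,
#' re-wrapping to `[0, 2*pi)`.
#'
#' @param feats a [feature_series()].
#' @param tau velocity/acceleration noise factor (`>= 1`).
#' @param kappa_noise concentration of the angular noise (`> 0`); large
#'   values leave the angles essentially unchanged.
#' @return the noisy [feature_series()].
#' @export
inject_noise <- function(feats, tau, kappa_noise) {
  if (tau < 1) stop("'tau' must be >= 1")
  if (kappa_noise <= 0) stop("'kappa_noise' must be > 0")
  obs <- !feats$missing
  m <- sum(obs)
  feats$vel[obs] <- rgamma(m, shape = 3, scale = feats$vel[obs] / 2 * tau)
  feats$acc[obs] <- rgamma(m, shape = 3, scale = feats$acc[obs] / 2 * tau)
  feats$angle[obs] <- (feats$angle[obs] + rvonmises(m, 0, kappa_noise)) %%
    (2 * pi)
  feats
}

# Manipulated parameters and their variation intervals for the
# parameter-variation study: one joint diagonal-transition manipulation,
# the four gamma parameters of every state, and the concentration of every
# von Mises state -- q = 10/15/20 parameters for k = 2/3/4. Gamma shapes
# vary on [1, 5]; gamma scales on [default/2, 2*default]; the transition
# diagonal on [0.6, 0.95]; concentrations on the inverse scale,
# 1/kappa in [0.1, 1].
part1_parameter_grid <- function(k, defaults) {
  rows <- list(data.frame(parameter = "a_diag", lower = 0.6, upper = 0.95,
                          inverse = FALSE))
  for (j in seq_len(k)) {
    e <- defaults$emissions[[j]]
    rows[[length(rows) + 1]] <- data.frame(
      parameter = sprintf(c("alpha_vel_%d", "beta_vel_%d",
                            "alpha_acc_%d", "beta_acc_%d"), j),
      lower = c(1, e$beta_vel / 2, 1, e$beta_acc / 2),
      upper = c(5, e$beta_vel * 2, 5, e$beta_acc * 2),
      inverse = FALSE)
    if (j >= 2) {
      rows[[length(rows) + 1]] <- data.frame(
        parameter = sprintf("kappa_%d", j), lower = 0.1, upper = 1,
        inverse = TRUE)
    }
  }
  do.call(rbind, rows)
}

# Set one manipulated parameter to a new value inside a parameter object.
set_parameter <- function(params, name, value) {
  if (name == "a_diag") {
    params$A <- transition_matrix(params$k, value)
    return(params)
  }
  m <- regmatches(name, regexec("^(alpha_vel|beta_vel|alpha_acc|beta_acc|kappa|mu)_([0-9]+)$", name))[[1]]
  if (length(m) == 0) stop("unknown parameter name: ", name)
  field <- m[2]
  j <- as.integer(m[3])
  params$emissions[[j]][[field]] <- value
  params
}

#' Simulation designs
#'
#' `part1_design()` builds the parameter-variation design: for each
#' manipulated parameter of the k-state model, `n_reps` datasets of `N`
#' samples in which that parameter sweeps its interval in equidistant
#' steps (concentrations sweep on the inverse scale) while all other
#' parameters keep their defaults. `part2_design()` builds the
#' noise-and-sample-size design: for each sample size in `N`, `n_reps`
#' datasets at default parameters whose noise level sweeps
#' `tau in [1, 5]` and `1/kappa_noise in [0.1, 10]` jointly in equidistant
#' steps.
#'
#' @param k number of states (2-4 in the study).
#' @param n_reps datasets per manipulated parameter (part 1) or per sample
#'   size (part 2). The full study used 100; desk-scale runs use 10.
#' @param N samples per dataset (part 1) or vector of sample sizes
#'   (part 2).
#' @param scale_factor feature scaling of the study (default 10).
#' @return an object of class `"simulation_design"`: a data.frame of
#'   dataset cells plus the default parameter set as attribute.
#' @export
part1_design <- function(k, n_reps = 10, N = 2500, scale_factor = 10) {
  defaults <- default_parameters(k, scale_factor = scale_factor)
  grid <- part1_parameter_grid(k, defaults)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    val <- seq(g$lower, g$upper, length.out = n_reps)
    if (g$inverse) val <- 1 / val
    data.frame(part = 1, k = k, N = N, rep = seq_len(n_reps),
               varied = g$parameter, value = val, tau = NA_real_,
               kappa_noise = NA_real_)
  }))
  structure(cells, class = c("simulation_design", "data.frame"),
            defaults = defaults, scale_factor = scale_factor)
}

#' @rdname part1_design
#' @export
part2_design <- function(k, n_reps = 10, N = c(500, 2500, 10000),
                         scale_factor = 10) {
  defaults <- default_parameters(k, scale_factor = scale_factor)
  tau <- seq(1, 5, length.out = n_reps)
  kap <- 1 / seq(0.1, 10, length.out = n_reps)
  cells <- do.call(rbind, lapply(N, function(nn) {
    data.frame(part = 2, k = k, N = nn, rep = seq_len(n_reps),
               varied = "noise", value = tau, tau = tau, kappa_noise = kap)
  }))
  structure(cells, class = c("simulation_design", "data.frame"),
            defaults = defaults, scale_factor = scale_factor)
}

#' Run a parameter-recovery study
#'
#' For every dataset cell of the design: build the true parameters,
#' simulate a feature series, optionally inject noise, draw randomized
#' starting values ([random_starts()]), fit by EM, decode with Viterbi,
#' and record all true and estimated parameter values together with
#' Cohen's kappa between true and decoded state sequences. Failed fits
#' are recorded in the failure log and excluded from the results, never
#' aborting the sweep.
#'
#' @param design a [part1_design()] or [part2_design()] object.
#' @param control a [hmm_control()] list.
#' @param seed optional integer seed for reproducibility.
#' @param verbose print progress?
#' @return an object of class `"recovery_study"`: list with `estimates`
#'   (long data.frame of cell, varied parameter, parameter, truth,
#'   estimate), `kappas` (per-dataset Cohen's kappa), `failures`, and the
#'   design.
#' @export
run_recovery_study <- function(design, control = hmm_control(),
                               seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  defaults <- attr(design, "defaults")
  est_rows <- vector("list", nrow(design))
  kap_rows <- vector("list", nrow(design))
  failures <- list()
  for (i in seq_len(nrow(design))) {
    cell <- design[i, ]
    truth <- defaults
    if (cell$varied != "noise")
      truth <- set_parameter(truth, cell$varied, cell$value)
    sim <- simulate_hmm(truth, cell$N)
    feats <- sim$features
    if (!is.na(cell$tau))
      feats <- inject_noise(feats, cell$tau, cell$kappa_noise)
    start <- random_starts(truth)
    fit <- tryCatch(
      fit_hmm(feats, k = cell$k, start = start, control = control),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(cell = i, varied = cell$varied, value = cell$value,
                   rep = cell$rep, message = conditionMessage(fit))
      next
    }
    tt <- as_parameter_table(truth)
    ee <- as_parameter_table(fit$params)
    est_rows[[i]] <- data.frame(
      cell = i, k = cell$k, N = cell$N, rep = cell$rep,
      varied = cell$varied, varied_value = cell$value,
      parameter = tt$parameter, truth = tt$value, estimate = ee$value)
    kap_rows[[i]] <- data.frame(
      cell = i, k = cell$k, N = cell$N, rep = cell$rep,
      varied = cell$varied, varied_value = cell$value,
      kappa = cohens_kappa(sim$states, fit$states),
      converged = fit$converged)
    if (verbose && i %% 20 == 0)
      message("recovery study: ", i, "/", nrow(design), " datasets done")
  }
  structure(list(estimates = do.call(rbind, est_rows),
                 kappas = do.call(rbind, kap_rows),
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 design = design),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  n_total <- nrow(x$design)
  n_fail <- if (is.null(x$failures)) 0 else nrow(x$failures)
  cat("Recovery study: ", n_total, " datasets (", n_fail, " failed fits)\n",
      sep = "")
  if (!is.null(x$kappas)) {
    cat("Cohen's kappa: median ",
        format(median(x$kappas$kappa), digits = 3), ", range [",
        format(min(x$kappas$kappa), digits = 3), ", ",
        format(max(x$kappas$kappa), digits = 3), "]\n", sep = "")
  }
  invisible(x)
}

#' RMdSPD summary of a recovery study
#'
#' Root median square proportion deviation of the estimated parameters.
#' The defining median runs across simulated datasets: with
#' `by = "parameter"` (the default) each estimated parameter is pooled
#' across every dataset of the study, matching the definition of the
#' measure (the median over all simulations in which the parameter was
#' estimated); `by = "varied"` computes it separately within each
#' manipulated-parameter cell, the grid shown in recovery figures, which
#' needs larger per-cell replication to be stable. Initial-state
#' probabilities are excluded by default: with one sequence per dataset
#' they are driven to a vertex of the simplex and carry no information.
#' Von Mises means are scored with circular (wrapped) deviations.
#'
#' @param study a `"recovery_study"` object.
#' @param by `"parameter"` or `"varied"` (see above).
#' @param include_rho include the initial-state probabilities?
#' @return data.frame with columns `parameter`, `rmdspd` (plus `varied`
#'   when `by = "varied"`).
#' @export
recovery_rmdspd <- function(study, by = c("parameter", "varied"),
                            include_rho = FALSE) {
  by <- match.arg(by)
  est <- study$estimates
  if (is.null(est) || nrow(est) == 0) stop("study holds no successful fits")
  if (!include_rho) est <- est[!grepl("^rho_", est$parameter), ]
  groups <- if (by == "parameter") split(est, est$parameter) else
    split(est, list(est$varied, est$parameter), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    circ <- grepl("^mu_", g$parameter[1])
    r <- data.frame(parameter = g$parameter[1],
                    rmdspd = rmdspd(g$truth, g$estimate, circular = circ))
    if (by == "varied") r <- cbind(varied = g$varied[1], r)
    r
  }))
  rownames(out) <- NULL
  if (by == "varied") out[order(out$varied, out$parameter), ] else
    out[order(out$parameter), ]
}
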