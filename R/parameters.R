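# Parameter containers for the generative model: per-state emission
# parameters and the full HMM parameter set (initial, transition, response
# submodels), plus the package's default parameter tables and starting
# values.

#' Per-state emission parameters
#'
#' Velocity and acceleration follow gamma distributions in a shape/scale
#' parametrization; the sample-to-sample direction change follows either a
#' circular uniform distribution on `[0, 2*pi)` (state 1, fixations, whose
#' drift has no preferred direction) or a von Mises distribution (all other
#' states).
#'
#' @param alpha_vel,beta_vel gamma shape and scale for velocity (`> 0`).
#' @param alpha_acc,beta_acc gamma shape and scale for acceleration (`> 0`).
#' @param angle_kind `"uniform"` or `"von_mises"`.
#' @param mu von Mises mean direction in radians (wrapped to `[0, 2*pi)`);
#'   ignored for the uniform kind.
#' @param kappa von Mises concentration (`>= 0`); ignored for the uniform
#'   kind.
#' @return an object of class `"state_emission"`.
#' @export
state_emission <- function(alpha_vel, beta_vel, alpha_acc, beta_acc,
                           angle_kind = c("uniform", "von_mises"),
                           mu = NULL, kappa = NULL) {
  angle_kind <- match.arg(angle_kind)
  for (p in c(alpha_vel, beta_vel, alpha_acc, beta_acc))
    if (!is.finite(p) || p <= 0)
      stop("gamma shapes and scales must be positive and finite")
  if (angle_kind == "von_mises") {
    if (is.null(mu) || is.null(kappa))
      stop("'mu' and 'kappa' are required for a von Mises angle component")
    if (!is.finite(kappa) || kappa < 0) stop("'kappa' must be >= 0")
    mu <- mu %% (2 * pi)
  } else {
    mu <- NULL
    kappa <- NULL
  }
  structure(list(alpha_vel = alpha_vel, beta_vel = beta_vel,
                 alpha_acc = alpha_acc, beta_acc = beta_acc,
                 angle_kind = angle_kind, mu = mu, kappa = kappa),
            class = "state_emission")
}

#' HMM parameter set
#'
#' Bundles the three submodels of the generative model: the initial-state
#' probabilities `rho`, the transition matrix `A`, and the per-state
#' emission parameters. State 1 carries the circular-uniform angle
#' component (fixations); states 2 and above carry von Mises components
#' (saccades, PSOs, smooth pursuits, and an optional unnamed fifth state
#' for exploratory model comparison).
#'
#' @param rho initial-state probability vector of length `k` (sums to 1).
#' @param A `k x k` transition matrix (rows sum to 1).
#' @param emissions list of `k` [state_emission()] objects; the first must
#'   have the uniform angle kind, the rest von Mises.
#' @return an object of class `"hmm_parameters"`.
#' @export
hmm_parameters <- function(rho, A, emissions) {
  k <- length(rho)
  if (k < 1 || k > 5) stop("number of states must be between 1 and 5")
  A <- as.matrix(A)
  if (!all(dim(A) == c(k, k))) stop("'A' must be a ", k, " x ", k, " matrix")
  if (any(rho < 0) || any(A < 0) || any(rho > 1) || any(A > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(rho) - 1) > 1e-8) stop("'rho' must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-8)) stop("rows of 'A' must sum to 1")
  if (length(emissions) != k) stop("need one emission object per state")
  if (emissions[[1]]$angle_kind != "uniform")
    stop("state 1 must use the uniform angle component")
  if (k > 1 && any(vapply(emissions[-1], function(e) e$angle_kind,
                          "") != "von_mises"))
    stop("states 2..k must use von Mises angle components")
  structure(list(k = k, rho = rho, A = A, emissions = emissions),
            class = "hmm_parameters")
}

#' @export
print.hmm_parameters <- function(x, digits = 3, ...) {
  cat("Gaze HMM parameters (", x$k, " state",
      if (x$k > 1) "s", ")\n", sep = "")
  cat("rho:", format(round(x$rho, digits)), "\n")
  cat("A:\n")
  print(round(x$A, digits))
  tab <- as_parameter_table(x)
  em <- tab[!(tab$parameter %in% sprintf("rho_%d", 1:5)) &
              !grepl("^a_", tab$parameter), , drop = FALSE]
  cat("emissions:\n")
  print(em, row.names = FALSE, digits = digits)
  invisible(x)
}

# Event semantics attached to state indices (fifth state deliberately
# unnamed; it is supported for model comparison only).
state_event_names <- function(k) {
  nm <- c("fixation", "saccade", "pso", "pursuit", "state5")
  nm[seq_len(k)]
}

#' Default emission parameter table
#'
#' Package defaults for the per-state emission parameters, expressed on the
#' raw feature scale (deg/s and deg/s^2). They place fixations at low
#' velocity/acceleration with directionless drift, saccades at high
#' velocity and acceleration with consistent direction, PSOs at moderate
#' velocity but high acceleration with direction reversals around 180
#' degrees, and smooth pursuit at moderate velocity with low acceleration.
#' Divide the scale parameters by the configured `scale_factor` before
#' fitting or simulating (10 for the simulation defaults, 100 for
#' classification).
#'
#' @return data.frame with one row per state, columns `alpha_vel`,
#'   `beta_vel`, `alpha_acc`, `beta_acc`, `mu`, `kappa` (`NA` for the
#'   uniform state 1).
#' @export
default_emission_table <- function() {
  data.frame(
    state = 1:5,
    event = c("fixation", "saccade", "pso", "pursuit", "state5"),
    alpha_vel = c(3, 3, 3, 3, 3),
    beta_vel  = c(2, 50, 15, 7, 1),
    alpha_acc = c(3, 3, 3, 3, 3),
    beta_acc  = c(70, 2000, 1500, 70, 30),
    mu        = c(NA, 0, pi, 0, 0),
    kappa     = c(NA, 5, 5, 5, 1)
  )
}

#' Default parameters / default starting values
#'
#' Builds the package-default HMM parameter set for `k` states: uniform
#' initial probabilities `rho = 1/k`, transition diagonal 0.9 with the
#' remaining mass spread evenly across each row, and emission parameters
#' from [default_emission_table()] with gamma scales divided by
#' `scale_factor`. These serve both as the generating values of the
#' simulation study (`scale_factor = 10`) and as the deterministic EM
#' starting values for classification (`scale_factor = 100`).
#'
#' @param k number of states (1-5).
#' @param scale_factor positive divisor applied to the gamma scale
#'   parameters (matches the feature scaling in use).
#' @param a_diag self-transition probability placed on the diagonal of `A`.
#' @return an [hmm_parameters()] object.
#' @export
default_parameters <- function(k, scale_factor = 1, a_diag = 0.9) {
  if (!(k %in% 1:5)) stop("'k' must be an integer in 1..5")
  if (scale_factor <= 0) stop("'scale_factor' must be positive")
  tab <- default_emission_table()
  em <- lapply(seq_len(k), function(j) {
    r <- tab[j, ]
    if (j == 1) {
      state_emission(r$alpha_vel, r$beta_vel / scale_factor,
                     r$alpha_acc, r$beta_acc / scale_factor, "uniform")
    } else {
      state_emission(r$alpha_vel, r$beta_vel / scale_factor,
                     r$alpha_acc, r$beta_acc / scale_factor, "von_mises",
                     mu = r$mu, kappa = r$kappa)
    }
  })
  A <- transition_matrix(k, a_diag)
  hmm_parameters(rep(1 / k, k), A, em)
}

#' @rdname default_parameters
#' @export
default_starts <- function(k, scale_factor = 100) {
  default_parameters(k, scale_factor = scale_factor, a_diag = 0.9)
}

# k x k transition matrix with diagonal a_diag and the leftover mass split
# evenly over the off-diagonal entries of each row.
transition_matrix <- function(k, a_diag) {
  if (k == 1) return(matrix(1, 1, 1))
  if (a_diag < 0 || a_diag > 1) stop("'a_diag' must lie in [0, 1]")
  A <- matrix((1 - a_diag) / (k - 1), k, k)
  diag(A) <- a_diag
  A
}

#' Randomized EM starting values
#'
#' Draws starting values for the positive emission parameters (gamma
#' shapes/scales and von Mises concentrations) from gamma distributions
#' with shape 3 and scale `theta/2`, so that the starting-value
#' distribution is positive, moderately skewed, and has its mode at the
#' true value `theta`. Von Mises mean directions start at their true
#' values; initial-state and transition probabilities start uniform at
#' `1/k`.
#'
#' @param truth an [hmm_parameters()] object supplying the true values.
#' @return an [hmm_parameters()] object of randomized starting values.
#' @export
random_starts <- function(truth) {
  k <- truth$k
  draw <- function(theta) rgamma(1, shape = 3, scale = theta / 2)
  em <- lapply(truth$emissions, function(e) {
    if (e$angle_kind == "uniform") {
      state_emission(draw(e$alpha_vel), draw(e$beta_vel),
                     draw(e$alpha_acc), draw(e$beta_acc), "uniform")
    } else {
      state_emission(draw(e$alpha_vel), draw(e$beta_vel),
                     draw(e$alpha_acc), draw(e$beta_acc), "von_mises",
                     mu = e$mu, kappa = draw(e$kappa))
    }
  })
  hmm_parameters(rep(1 / k, k), matrix(1 / k, k, k), em)
}

# Flatten an hmm_parameters object into a tidy (parameter, value) table.
# Used by the recovery study to pair true and estimated values.
as_parameter_table <- function(params) {
  k <- params$k
  rows <- list()
  rows[[1]] <- data.frame(parameter = sprintf("rho_%d", seq_len(k)),
                          value = params$rho)
  a <- expand.grid(i = seq_len(k), j = seq_len(k))
  rows[[2]] <- data.frame(parameter = sprintf("a_%d%d", a$i, a$j),
                          value = params$A[cbind(a$i, a$j)])
  for (j in seq_len(k)) {
    e <- params$emissions[[j]]
    pp <- data.frame(
      parameter = sprintf(c("alpha_vel_%d", "beta_vel_%d",
                            "alpha_acc_%d", "beta_acc_%d"), j),
      value = c(e$alpha_vel, e$beta_vel, e$alpha_acc, e$beta_acc))
    if (e$angle_kind == "von_mises") {
      pp <- rbind(pp, data.frame(
        parameter = sprintf(c("mu_%d", "kappa_%d"), j),
        value = c(e$mu, e$kappa)))
    }
    rows[[2 + j]] <- pp
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Count of freely estimated parameters: (k-1) initial probabilities,
# k(k-1) transition probabilities, 4k gamma parameters, and (mu, kappa)
# for each von Mises state. State 1's uniform angle has no free
# parameters.
n_free_parameters <- function(k) {
  (k - 1) + k * (k - 1) + 4 * k + 2 * (k - 1)
}
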