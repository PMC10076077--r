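# EM estimation of the gaze HMM, Viterbi decoding, likelihood and
# information criteria.

#' EM fit control settings
#'
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations.
#' @param bic_n `"all"` counts every sample (missing included, since they
#'   contribute a trivial factor of one to the likelihood) in the BIC/ICL
#'   sample size; `"observed"` counts only non-missing samples.
#' @return list of control settings.
#' @export
hmm_control <- function(tol = 1e-8, max_iter = 500,
                        bic_n = c("all", "observed")) {
  list(tol = tol, max_iter = max_iter, bic_n = match.arg(bic_n))
}

#' Fit the gaze HMM by expectation-maximization
#'
#' Maximum-likelihood estimation of the initial-state, transition and
#' emission parameters. The E-step runs the scaled forward-backward
#' recursions (in C++); the M-step updates `rho` and `A` in closed form
#' from expected counts and each state's emission parameters by exact
#' weighted maximum likelihood (Newton iterations on the gamma profile
#' likelihood and the Bessel-ratio equation of the von Mises
#' concentration). Missing samples contribute an emission density of one
#' and are therefore carried by the transition structure alone.
#'
#' @param feats a [feature_series()].
#' @param k number of hidden states (1-5).
#' @param start an [hmm_parameters()] object of starting values; defaults
#'   to [default_starts()] with the feature series' scale factor.
#' @param control a [hmm_control()] list.
#' @return an object of class `"gazehmm_fit"` with the estimated
#'   parameters, log-likelihood trace, posterior state probabilities,
#'   Viterbi state sequence, convergence flag and BIC/ICL.
#' @export
fit_hmm <- function(feats, k = NULL, start = NULL, control = hmm_control()) {
  if (is.null(k)) {
    if (is.null(start)) stop("supply 'k' or 'start'")
    k <- start$k
  }
  if (!(k %in% 1:5)) stop("'k' must be an integer in 1..5")
  if (is.null(start)) start <- default_starts(k, feats$scale_factor)
  if (start$k != k) stop("'start' has ", start$k, " states, expected ", k)
  n <- length(feats$vel)
  if (n == 0) stop("empty feature series")
  n_free <- n_free_parameters(k)
  n_used <- sum(!feats$missing)
  if (n_used < 10 * n_free)
    warning("only ", n_used, " non-missing samples for ", n_free,
            " free parameters; estimates may be unstable")

  params <- start
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  obs <- !feats$missing
  vel <- pmax(feats$vel, .FEATURE_EPS)
  acc <- pmax(feats$acc, .FEATURE_EPS)

  repeat {
    iter <- iter + 1L
    ld <- emission_logdensity_matrix(params, feats)
    es <- hmm_estep_cpp(ld, params$rho, params$A)
    ll <- es$loglik
    if (!is.finite(ll)) stop("non-finite log-likelihood at iteration ", iter)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev)) {
      rel <- (ll - ll_prev) / (abs(ll_prev) + 1e-10)
      if (rel < -1e-8)
        warning("log-likelihood decreased at iteration ", iter,
                " (relative change ", signif(rel, 3), ")")
      if (abs(rel) < control$tol) { converged <- TRUE; break }
    }
    ll_prev <- ll
    if (iter >= control$max_iter) break

    gam <- es$gamma
    # closed-form multinomial updates
    rho <- gam[1, ]
    rho <- rho / sum(rho)
    A <- es$xi_sum
    if (k > 1) A <- A / rowSums(A) else A <- matrix(1, 1, 1)
    # exact weighted-MLE emission updates; missing samples carry no
    # emission information
    em <- vector("list", k)
    for (j in seq_len(k)) {
      w <- gam[obs, j]
      gv <- gamma_wmle(vel[obs], w, sprintf("velocity gamma of state %d", j))
      ga <- gamma_wmle(acc[obs], w,
                       sprintf("acceleration gamma of state %d", j))
      if (params$emissions[[j]]$angle_kind == "uniform") {
        em[[j]] <- state_emission(gv["shape"], gv["scale"],
                                  ga["shape"], ga["scale"], "uniform")
      } else {
        vm <- vonmises_wmle(feats$angle[obs], w,
                            sprintf("von Mises component of state %d", j))
        em[[j]] <- state_emission(gv["shape"], gv["scale"],
                                  ga["shape"], ga["scale"], "von_mises",
                                  mu = vm["mu"], kappa = vm["kappa"])
      }
    }
    params <- hmm_parameters(rho, A, em)
  }

  posteriors <- es$gamma
  colnames(posteriors) <- state_event_names(k)
  states <- viterbi_decode(params, feats)
  n_obs <- if (control$bic_n == "all") n else n_used
  ll_completed <- completed_loglik(params, feats, states)
  fit <- structure(list(
    params = params, loglik = ll, loglik_trace = ll_trace, n_obs = n_obs,
    n_free = n_free, posteriors = posteriors, states = states,
    converged = converged, n_iter = iter,
    bic = -2 * ll + n_free * log(n_obs),
    icl = -2 * ll_completed + n_free * log(n_obs),
    scale_factor = feats$scale_factor, control = control,
    feats = feats), class = "gazehmm_fit")
  fit
}

#' Marginal log-likelihood of a feature series under the model
#'
#' Scaled forward recursion over all state paths; missing samples
#' contribute a density of one.
#'
#' @param params an [hmm_parameters()] object.
#' @param feats a [feature_series()].
#' @return the log-likelihood (a scalar).
#' @export
sequence_loglik <- function(params, feats) {
  ld <- emission_logdensity_matrix(params, feats)
  hmm_loglik_cpp(ld, params$rho, params$A)
}

#' Viterbi decoding of the most probable state path
#'
#' Max-product dynamic program returning the jointly most probable hidden
#' state sequence; ties break toward the lower state index. Missing
#' samples are decoded from the transition structure alone.
#'
#' @inheritParams sequence_loglik
#' @return integer vector of state indices in `1..k`.
#' @export
viterbi_decode <- function(params, feats) {
  ld <- emission_logdensity_matrix(params, feats)
  as.integer(hmm_viterbi_cpp(ld, params$rho, params$A))
}

#' Per-sample posterior decoding
#'
#' Argmax of the smoothed posterior state probabilities, the per-sample
#' alternative to the MAP sequence of [viterbi_decode()]. Ties break
#' toward the lower state index.
#'
#' @inheritParams sequence_loglik
#' @return integer vector of state indices in `1..k`.
#' @export
posterior_decode <- function(params, feats) {
  ld <- emission_logdensity_matrix(params, feats)
  es <- hmm_estep_cpp(ld, params$rho, params$A)
  max.col(es$gamma, ties.method = "first")
}

# Completed-data log-likelihood along a given state path.
completed_loglik <- function(params, feats, states) {
  ld <- emission_logdensity_matrix(params, feats)
  n <- length(states)
  lp <- log(params$rho[states[1]]) + ld[1, states[1]]
  if (n > 1) {
    lp <- lp + sum(log(params$A[cbind(states[-n], states[-1])])) +
      sum(ld[cbind(2:n, states[-1])])
  }
  lp
}

#' Information criteria of a fit
#'
#' `bic = -2 * loglik + n_free * log(n_obs)`; `icl` replaces the marginal
#' log-likelihood by the completed-data log-likelihood evaluated along the
#' Viterbi path, penalizing classification uncertainty, so `icl >= bic`.
#'
#' @param fit a `"gazehmm_fit"` object.
#' @return named numeric vector with elements `bic` and `icl`.
#' @export
information_criteria <- function(fit) {
  c(bic = fit$bic, icl = fit$icl)
}

#' Sanity check of the fitted state ordering
#'
#' Verifies that the fitted states carry the intended event semantics:
#' state 1 (fixation) should have the lowest mean velocity and state 2
#' (saccade) the highest. Violations produce a warning naming the
#' offending ordering; states are never silently permuted.
#'
#' @param fit a `"gazehmm_fit"` object.
#' @return invisibly, `TRUE` if the ordering holds.
#' @export
sanity_check <- function(fit) {
  k <- fit$params$k
  if (k < 2) return(invisible(TRUE))
  mv <- vapply(fit$params$emissions,
               function(e) e$alpha_vel * e$beta_vel, numeric(1))
  ok <- TRUE
  if (which.min(mv) != 1) {
    warning("state ", which.min(mv), " has a lower mean velocity than ",
            "state 1; fitted states may not match the intended events")
    ok <- FALSE
  }
  if (which.max(mv) != 2) {
    warning("state ", which.max(mv), " has a higher mean velocity than ",
            "state 2; fitted states may not match the intended events")
    ok <- FALSE
  }
  invisible(ok)
}

#' @export
print.gazehmm_fit <- function(x, ...) {
  cat("Gaze HMM fit: k = ", x$params$k, ", log-likelihood ",
      format(x$loglik, digits = 8), "\n", sep = "")
  cat(if (x$converged) "converged" else "NOT converged", " after ",
      x$n_iter, " iterations; BIC ", format(x$bic, digits = 8), ", ICL ",
      format(x$icl, digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gazehmm_fit <- function(object, ...) {
  print(object)
  print(object$params)
  tab <- table(factor(object$states, levels = seq_len(object$params$k),
                      labels = state_event_names(object$params$k)))
  cat("decoded state occupancy:\n")
  print(tab)
  invisible(object)
}

#' @export
coef.gazehmm_fit <- function(object, scale = c("fitted", "raw"), ...) {
  scale <- match.arg(scale)
  tab <- as_parameter_table(object$params)
  if (scale == "raw") {
    # gamma scales were fitted on features divided by scale_factor
    sc <- grepl("^beta_(vel|acc)_", tab$parameter)
    tab$value[sc] <- tab$value[sc] * object$scale_factor
  }
  setNames(tab$value, tab$parameter)
}

#' @export
logLik.gazehmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = object$n_obs,
            class = "logLik")
}

#' @export
predict.gazehmm_fit <- function(object, newdata = NULL,
                                method = c("viterbi", "posterior"), ...) {
  method <- match.arg(method)
  feats <- if (is.null(newdata)) object$feats else newdata
  if (method == "viterbi") viterbi_decode(object$params, feats)
  else posterior_decode(object$params, feats)
}

#' @export
simulate.gazehmm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$feats$vel)
  out <- lapply(seq_len(nsim), function(i) simulate_hmm(object$params, n))
  if (nsim == 1) out[[1]] else out
}
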