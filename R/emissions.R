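# Emission distributions: gamma (velocity, acceleration) and circular
# (uniform / von Mises) components, their weighted maximum-likelihood
# updates for the EM M-step, and a von Mises sampler.

# Features below this value are clamped before density evaluation: the
# gamma density is degenerate at 0 for shape < 1.
.FEATURE_EPS <- 1e-6

#' Von Mises density
#'
#' Density of the von Mises distribution on the full circle, the circular
#' analogue of the Gaussian. `kappa = 0` reduces to the circular uniform
#' density `1/(2*pi)`.
#'
#' @param theta angle(s) in radians.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, `>= 0`.
#' @param log logical; return log-density?
#' @return numeric vector of (log-)densities.
#' @export
dvonmises <- function(theta, mu, kappa, log = FALSE) {
  if (kappa < 0) stop("'kappa' must be >= 0")
  # log I0(kappa) via the exponentially scaled Bessel function keeps
  # kappa ~ 700+ from overflowing.
  ld <- kappa * cos(theta - mu) - log(2 * pi) -
    (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
  if (log) ld else exp(ld)
}

#' Von Mises random deviates
#'
#' Best & Fisher (1979) wrapped-Cauchy rejection sampler. Angles are
#' returned wrapped to `[0, 2*pi)`.
#'
#' @param n number of draws.
#' @inheritParams dvonmises
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("'kappa' must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    need <- n - got
    # acceptance rate is >= 65% for all kappa; oversample modestly
    m <- ceiling(need * 1.6) + 5L
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- f[ok]
    sgn <- sign(u3[ok] - 0.5)
    th <- sgn * acos(pmin(pmax(acc, -1), 1)) + mu
    take <- min(length(th), need)
    if (take > 0) out[(got + 1L):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  out %% (2 * pi)
}

# Weighted gamma MLE (shape/scale). Maximizes sum(w * dgamma(y, ., log=TRUE))
# by Newton iteration on the profile equation
#   log(alpha) - digamma(alpha) = log(wmean(y)) - wmean(log y)
# with the Minka/Choi-Wette closed-form initial value.
gamma_wmle <- function(y, w, label = "gamma component") {
  sw <- sum(w)
  if (sw <= 0) stop("degenerate fit: no posterior weight for ", label)
  m <- sum(w * y) / sw
  lm <- sum(w * log(y)) / sw
  s <- log(m) - lm
  if (!is.finite(s) || s <= 1e-12)
    stop("degenerate data for ", label, ": feature is (near-)constant")
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    da <- f / fp
    a_new <- a - da
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * a) { a <- a_new; break }
    a <- a_new
  }
  c(shape = a, scale = m / a)
}

# Weighted von Mises MLE. Mean direction is closed form; kappa inverts the
# Bessel ratio A1(kappa) = I1/I0 by the standard piecewise approximation
# (Fisher 1993) followed by Newton refinement, using
# dA1/dkappa = 1 - A1/kappa - A1^2.
vonmises_wmle <- function(theta, w, label = "von Mises component") {
  sw <- sum(w)
  if (sw <= 0) stop("degenerate fit: no posterior weight for ", label)
  C <- sum(w * cos(theta)) / sw
  S <- sum(w * sin(theta)) / sw
  mu <- atan2(S, C) %% (2 * pi)
  R <- sqrt(C^2 + S^2)
  if (R >= 1 - 1e-12) R <- 1 - 1e-12
  if (R < 1e-12) return(c(mu = mu, kappa = 0))
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  A1 <- function(k) {
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  }
  for (i in 1:50) {
    a1 <- A1(k)
    f <- a1 - R
    fp <- 1 - a1 / k - a1^2
    if (!is.finite(fp) || fp <= 0) break
    k_new <- k - f / fp
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * max(k, 1)) { k <- k_new; break }
    k <- k_new
  }
  c(mu = mu, kappa = min(k, 1e5))
}

#' Per-sample emission log-density for one state
#'
#' Sum of the three conditionally independent component log-densities:
#' gamma for velocity, gamma for acceleration, and circular uniform or von
#' Mises for the sample-to-sample direction change. Missing samples are
#' integrated out, i.e. contribute a density of one (log-density 0).
#'
#' @param em a [state_emission()] object.
#' @param vel,acc,angle numeric observation vectors (equal length).
#' @param missing logical vector; `TRUE` entries get log-density 0.
#' @return numeric vector of log-densities.
#' @export
emission_logdensity <- function(em, vel, acc, angle, missing = NULL) {
  n <- length(vel)
  if (is.null(missing)) missing <- rep(FALSE, n)
  out <- numeric(n)
  obs <- !missing
  if (any(obs)) {
    v <- pmax(vel[obs], .FEATURE_EPS)
    a <- pmax(acc[obs], .FEATURE_EPS)
    ld <- dgamma(v, shape = em$alpha_vel, scale = em$beta_vel, log = TRUE) +
      dgamma(a, shape = em$alpha_acc, scale = em$beta_acc, log = TRUE)
    ld <- ld + if (em$angle_kind == "uniform") {
      -log(2 * pi)
    } else {
      dvonmises(angle[obs], em$mu, em$kappa, log = TRUE)
    }
    out[obs] <- ld
  }
  out
}

# N x k matrix of emission log-densities for all states.
emission_logdensity_matrix <- function(params, feats) {
  k <- params$k
  n <- length(feats$vel)
  ld <- matrix(0, n, k)
  for (j in seq_len(k)) {
    ld[, j] <- emission_logdensity(params$emissions[[j]], feats$vel,
                                   feats$acc, feats$angle, feats$missing)
  }
  if (any(!is.finite(ld)))
    stop("non-finite emission log-density; check features and parameters")
  ld
}
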