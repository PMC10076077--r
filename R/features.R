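# Feature extraction: Savitzky-Golay velocity and acceleration,
# sample-to-sample direction change, blink padding, and feature scaling.

#' Construct a feature series
#'
#' Container for the three per-sample emission features: speed (deg/s),
#' acceleration magnitude (deg/s^2) and sample-to-sample direction change
#' in radians on `[0, 2*pi)`, together with a shared missing mask and the
#' cumulative scale factor applied to velocity and acceleration.
#'
#' @param vel,acc non-negative numeric vectors.
#' @param angle numeric vector of angles in `[0, 2*pi)` (`NA` where
#'   missing).
#' @param missing logical mask, same length.
#' @param scale_factor positive number already divided out of `vel`/`acc`.
#' @param fs sampling frequency in Hz.
#' @param t optional timestamps.
#' @return an object of class `"feature_series"`.
#' @export
feature_series <- function(vel, acc, angle, missing = NULL,
                           scale_factor = 1, fs = NULL, t = NULL) {
  n <- length(vel)
  if (length(acc) != n || length(angle) != n)
    stop("feature vectors must have equal length")
  if (is.null(missing)) missing <- rep(FALSE, n)
  missing <- missing | !is.finite(vel) | !is.finite(acc) | !is.finite(angle)
  if (any(vel[!missing] < 0) || any(acc[!missing] < 0))
    stop("velocity and acceleration must be non-negative")
  if (any(angle[!missing] < 0 | angle[!missing] >= 2 * pi))
    stop("angles must lie in [0, 2*pi)")
  if (scale_factor <= 0) stop("'scale_factor' must be positive")
  structure(list(vel = vel, acc = acc, angle = angle, missing = missing,
                 scale_factor = scale_factor, fs = fs, t = t),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat("Feature series: ", length(x$vel), " samples, ", sum(x$missing),
      " missing, scale factor ", x$scale_factor, "\n", sep = "")
  invisible(x)
}

#' Savitzky-Golay velocity and acceleration
#'
#' Smoothed first and second derivatives of the gaze position are obtained
#' with a Savitzky-Golay filter ([signal::sgolayfilt()]); speed and
#' acceleration are the Euclidean norms of the derivative vectors.
#' Samples within half a filter window of either edge are marked missing,
#' as are samples that were already missing in the recording (positions
#' are linearly interpolated across missing stretches before filtering so
#' the filter stays defined, but those samples never enter the fit).
#'
#' @param rec a [gaze_recording()].
#' @param window_ms filter window length in milliseconds; rounded to the
#'   nearest odd number of samples, minimum 5.
#' @param polyorder polynomial order of the filter.
#' @return list with components `vel` (deg/s), `acc` (deg/s^2) and
#'   `missing`.
#' @export
differentiate <- function(rec, window_ms = 20, polyorder = 2) {
  n <- length(rec$t)
  w <- round(window_ms / 1000 * rec$fs)
  if (w %% 2 == 0) w <- w + 1
  w <- max(w, 5, polyorder + 1 + (polyorder %% 2 == 0))
  if (w %% 2 == 0) w <- w + 1
  if (n < w)
    stop("recording (", n, " samples) is shorter than the filter window (",
         w, " samples)")
  fill <- function(z) {
    if (!any(!is.finite(z))) return(z)
    idx <- seq_len(n)
    ok <- is.finite(z)
    if (sum(ok) < 2) stop("too few finite positions to differentiate")
    approx(idx[ok], z[ok], xout = idx, rule = 2)$y
  }
  x <- fill(rec$x)
  y <- fill(rec$y)
  ts <- 1 / rec$fs
  dx <- signal::sgolayfilt(x, p = polyorder, n = w, m = 1, ts = ts)
  dy <- signal::sgolayfilt(y, p = polyorder, n = w, m = 1, ts = ts)
  ddx <- signal::sgolayfilt(x, p = polyorder, n = w, m = 2, ts = ts)
  ddy <- signal::sgolayfilt(y, p = polyorder, n = w, m = 2, ts = ts)
  vel <- sqrt(dx^2 + dy^2)
  acc <- sqrt(ddx^2 + ddy^2)
  half <- (w - 1) / 2
  missing <- rec$missing
  missing[c(seq_len(half), n - seq_len(half) + 1)] <- TRUE
  list(vel = vel, acc = acc, missing = missing)
}

#' Sample-to-sample direction change
#'
#' For each interior sample t, the signed planar angle between the
#' displacement vectors (t-1 -> t) and (t -> t+1), counter-clockwise
#' positive, wrapped to `[0, 2*pi)` by adding `2*pi` to negative values.
#' The first and last samples and any sample adjacent to a zero-length
#' displacement or a missing position get `NA`.
#'
#' @param rec a [gaze_recording()].
#' @return numeric vector of angles (`NA` where undefined).
#' @export
sample_angle <- function(rec) {
  n <- length(rec$x)
  if (n < 3) stop("need at least 3 samples to compute angles")
  dx <- diff(rec$x)
  dy <- diff(rec$y)
  # v1 = displacement into sample t, v2 = displacement out of it
  v1x <- dx[-(n - 1)]; v1y <- dy[-(n - 1)]
  v2x <- dx[-1];       v2y <- dy[-1]
  cross <- v1x * v2y - v1y * v2x
  dot <- v1x * v2x + v1y * v2y
  a <- atan2(cross, dot)
  a[a < 0] <- a[a < 0] + 2 * pi
  zero <- (v1x == 0 & v1y == 0) | (v2x == 0 & v2y == 0)
  a[zero] <- NA_real_
  c(NA_real_, a, NA_real_)
}

#' Pad blinks with a missing margin
#'
#' Eye-trackers often record a few samples of spuriously high velocity
#' just before and after losing the pupil during a blink. All samples
#' whose timestamp lies within `pad_ms` of any blink sample (inclusive)
#' are therefore marked missing before classification; blink flags are
#' preserved. Idempotent.
#'
#' @param rec a [gaze_recording()].
#' @param pad_ms padding margin in milliseconds (default 50).
#' @return the recording with an updated `missing` mask.
#' @export
pad_blinks <- function(rec, pad_ms = 50) {
  if (pad_ms < 0) stop("'pad_ms' must be >= 0")
  idx <- which(rec$blink)
  if (length(idx) == 0) return(rec)
  pad <- pad_ms / 1000
  miss <- rec$missing | rec$blink
  # mark whole [t_start - pad, t_end + pad] windows around contiguous
  # blink runs (few runs, so a loop over runs is cheap)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  eps <- 1e-9 / rec$fs  # inclusive boundary despite float rounding
  for (r in runs) {
    lo <- rec$t[r[1]] - pad - eps
    hi <- rec$t[r[length(r)]] + pad + eps
    miss[rec$t >= lo & rec$t <= hi] <- TRUE
  }
  rec$missing <- miss
  rec
}

#' Scale velocity and acceleration
#'
#' Divides velocity and acceleration by `factor` (angles are untouched)
#' and records the cumulative scale factor, so fitted gamma scale
#' parameters can be reported on either the scaled or the raw feature
#' scale. Scaling large velocity values down (factor 100 for
#' classification, 10 in the simulation defaults) improves the numerical
#' behaviour of the gamma fits without changing the model: gamma
#' distributions are a scale family, so shapes and decoded states are
#' unaffected.
#'
#' @param feats a [feature_series()].
#' @param factor positive scale divisor.
#' @return the rescaled [feature_series()].
#' @export
scale_features <- function(feats, factor) {
  if (!is.finite(factor) || factor <= 0) stop("'factor' must be positive")
  feats$vel <- feats$vel / factor
  feats$acc <- feats$acc / factor
  feats$scale_factor <- feats$scale_factor * factor
  feats
}

#' Full feature-extraction pipeline
#'
#' [pad_blinks()] then [differentiate()] then [sample_angle()] then
#' [scale_features()], returning a [feature_series()] whose missing mask
#' is the union of recorded missing samples, blink padding, filter edge
#' effects and undefined angles.
#'
#' @param rec a [gaze_recording()].
#' @param sg_window_ms,sg_polyorder Savitzky-Golay settings.
#' @param blink_pad_ms blink padding in milliseconds.
#' @param scale_factor divisor for velocity/acceleration.
#' @return a [feature_series()].
#' @export
compute_features <- function(rec, sg_window_ms = 20, sg_polyorder = 2,
                             blink_pad_ms = 50, scale_factor = 100) {
  rec <- pad_blinks(rec, blink_pad_ms)
  d <- differentiate(rec, sg_window_ms, sg_polyorder)
  ang <- sample_angle(rec)
  miss <- d$missing | is.na(ang)
  feats <- feature_series(vel = d$vel, acc = d$acc, angle = ang,
                          missing = miss, scale_factor = 1, fs = rec$fs,
                          t = rec$t)
  scale_features(feats, scale_factor)
}
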