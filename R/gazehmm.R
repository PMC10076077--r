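# Top-level interface: the gazehmm() classifier, its S3 methods, and
# multi-k model comparison.

#' Classify eye-tracking samples with a generative HMM
#'
#' Runs the full pipeline: read/validate the recording, pad blinks,
#' extract Savitzky-Golay velocity and acceleration and the
#' sample-to-sample direction change, scale the features, fit a k-state
#' HMM by EM, decode the most probable state sequence with Viterbi, apply
#' the postprocessing relabeling rules, label missing samples as noise,
#' and build the event table. With `n_states = 2` only fixations and
#' saccades are classified; 3 adds PSOs and 4 smooth pursuits.
#'
#' @param data a [gaze_recording()], a data.frame with columns `t`, `x`,
#'   `y` (and optionally `blink`), or a path to a delimited text file.
#' @param fs sampling frequency in Hz (required unless `data` is already
#'   a recording).
#' @param n_states number of hidden states (2-4 for named events; 5
#'   supported for model comparison).
#' @param column_map column-name mapping used when `data` is a file path.
#' @param sg_window_ms,sg_polyorder Savitzky-Golay filter settings.
#' @param blink_pad_ms missing margin around blinks in milliseconds.
#' @param scale_factor divisor applied to velocity/acceleration before
#'   fitting (default 100).
#' @param min_saccade_ms minimum saccade duration of the postprocessing.
#' @param start optional [hmm_parameters()] starting values; defaults to
#'   [default_starts()].
#' @param control a [hmm_control()] list.
#' @param postprocess apply the relabeling rules?
#' @return an object of class `"gazehmm"` with the recording, features,
#'   inner `"gazehmm_fit"`, per-sample `labels`, and `events` table.
#' @examples
#' params <- default_parameters(2, scale_factor = 10)
#' sim <- simulate_hmm(params, 400)
#' fit <- fit_hmm(sim$features, k = 2, start = params)
#' table(true = sim$states, decoded = fit$states)
#' @export
gazehmm <- function(data, fs = NULL, n_states = 3,
                    column_map = c(t = "t", x = "x", y = "y",
                                   blink = "blink"),
                    sg_window_ms = 20, sg_polyorder = 2, blink_pad_ms = 50,
                    scale_factor = 100, min_saccade_ms = 10, start = NULL,
                    control = hmm_control(), postprocess = TRUE) {
  rec <- if (inherits(data, "gaze_recording")) {
    data
  } else if (is.character(data)) {
    if (is.null(fs)) stop("'fs' is required when reading from a file")
    read_gaze(data, fs = fs, column_map = column_map)
  } else if (is.data.frame(data)) {
    if (is.null(fs)) stop("'fs' is required")
    gaze_recording(x = data$x, y = data$y, t = data$t, fs = fs,
                   blink = data$blink)
  } else {
    stop("'data' must be a recording, data.frame or file path")
  }
  feats <- compute_features(rec, sg_window_ms = sg_window_ms,
                            sg_polyorder = sg_polyorder,
                            blink_pad_ms = blink_pad_ms,
                            scale_factor = scale_factor)
  fit <- fit_hmm(feats, k = n_states, start = start, control = control)
  sanity_check(fit)
  labels <- states_to_labels(fit$states)
  if (postprocess) labels <- relabel(labels, rec$fs, min_saccade_ms)
  labels <- label_noise(labels, feats$missing)
  events <- build_events(labels, rec$t, vel = feats$vel * feats$scale_factor)
  structure(list(call = match.call(), recording = rec, features = feats,
                 fit = fit, labels = labels, events = events,
                 config = list(n_states = n_states,
                               sg_window_ms = sg_window_ms,
                               sg_polyorder = sg_polyorder,
                               blink_pad_ms = blink_pad_ms,
                               scale_factor = scale_factor,
                               min_saccade_ms = min_saccade_ms)),
            class = "gazehmm")
}

#' @export
print.gazehmm <- function(x, ...) {
  cat("gazehmm classification (", x$config$n_states, " states)\n", sep = "")
  print(x$recording)
  cat("log-likelihood ", format(x$fit$loglik, digits = 8),
      if (x$fit$converged) " (converged)" else " (NOT converged)",
      "\n", sep = "")
  tab <- table(factor(x$labels, levels = EVENT_LEVELS))
  tab <- tab[tab > 0]
  cat("sample labels:\n")
  print(tab)
  cat(nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' @export
summary.gazehmm <- function(object, ...) {
  print(object)
  cat("\nevent descriptives (durations in s):\n")
  print(event_descriptives(object$events), row.names = FALSE, digits = 4)
  cat("\nfitted parameters:\n")
  print(object$fit$params)
  invisible(object)
}

#' @export
coef.gazehmm <- function(object, ...) coef(object$fit, ...)

#' @export
logLik.gazehmm <- function(object, ...) logLik(object$fit)

#' @export
predict.gazehmm <- function(object, newdata = NULL, ...) {
  predict(object$fit, newdata = newdata, ...)
}

#' @export
simulate.gazehmm <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Plot a classified recording
#'
#' Two panels: horizontal/vertical gaze position over time colored by
#' event label, and the velocity trace on a log scale.
#'
#' @param x a `"gazehmm"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gazehmm <- function(x, ...) {
  cols <- c(fixation = "#1b9e77", saccade = "#d95f02", pso = "#7570b3",
            pursuit = "#e7298a", state5 = "#66a61e", noise = "grey60")
  col <- cols[x$labels]
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$recording$t, x$recording$x, col = col, pch = 16, cex = 0.4,
       xlab = "time (s)", ylab = "position (deg)", ...)
  points(x$recording$t, x$recording$y, col = col, pch = 1, cex = 0.4)
  legend("topright", legend = names(cols), col = cols, pch = 16, cex = 0.7)
  v <- x$features$vel * x$features$scale_factor
  plot(x$recording$t, pmax(v, 1e-3), col = col, pch = 16, cex = 0.4,
       log = "y", xlab = "time (s)", ylab = "velocity (deg/s)")
  invisible(x)
}

#' Compare models with different numbers of states
#'
#' Fits the HMM for each candidate number of states on the same feature
#' series and reports log-likelihood, free-parameter count, BIC, ICL and
#' the corresponding model weights (Schwarz weights for BIC and their ICL
#' analogue). Failed fits are reported with `NA` criteria and excluded
#' from the weights.
#'
#' @param feats a [feature_series()] (or a `"gazehmm"` object, whose
#'   features are reused).
#' @param k_list candidate numbers of states, a subset of `1:5`.
#' @param control a [hmm_control()] list.
#' @return an object of class `"gazehmm_comparison"`: data.frame with one
#'   row per candidate model.
#' @export
compare_models <- function(feats, k_list = 1:5, control = hmm_control()) {
  if (inherits(feats, "gazehmm")) feats <- feats$features
  if (!all(k_list %in% 1:5)) stop("'k_list' must be a subset of 1:5")
  rows <- lapply(k_list, function(k) {
    fit <- tryCatch(
      fit_hmm(feats, k = k,
              start = default_starts(k, feats$scale_factor),
              control = control),
      error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(k = k, loglik = NA_real_, n_free = n_free_parameters(k),
                 bic = NA_real_, icl = NA_real_, converged = FALSE,
                 error = conditionMessage(fit))
    } else {
      data.frame(k = k, loglik = fit$loglik, n_free = fit$n_free,
                 bic = fit$bic, icl = fit$icl, converged = fit$converged,
                 error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$bic))) stop("all candidate models failed to fit")
  ok <- !is.na(out$bic)
  out$w_bic <- out$w_icl <- NA_real_
  if (sum(ok) == 1) {
    out$w_bic[ok] <- out$w_icl[ok] <- 1
  } else {
    out$w_bic[ok] <- model_weights(out$bic[ok])
    out$w_icl[ok] <- model_weights(out$icl[ok])
  }
  class(out) <- c("gazehmm_comparison", "data.frame")
  out
}

#' @export
print.gazehmm_comparison <- function(x, ...) {
  cat("Model comparison across numbers of states:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
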