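# Postprocessing of decoded state sequences: heuristic relabeling rules,
# noise labeling of missing samples, and the event table.

EVENT_LEVELS <- c("fixation", "saccade", "pso", "pursuit", "state5", "noise")

#' Map decoded states to event labels
#'
#' @param states integer state sequence in `1..k`.
#' @return character vector of event labels (`fixation`, `saccade`,
#'   `pso`, `pursuit`, `state5`).
#' @export
states_to_labels <- function(states) {
  state_event_names(5)[states]
}

# Maximal runs of equal labels.
label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(type = r$values, start = ends - r$lengths + 1L, end = ends,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Relabel implausible short events
#'
#' Applies the heuristic cleanup rules to the decoded label sequence,
#' iterating left to right over maximal runs: (a) one-sample fixation or
#' pursuit runs, (b) saccade runs strictly shorter than `min_saccade_ms`
#' (run length divided by `fs`; a run of exactly the threshold duration is
#' kept), and (c) PSO runs whose preceding event is not a saccade are
#' relabeled to the type of the previous event. A leading offending run
#' with no previous event merges into the following event. Noise runs are
#' transparent: they are never relabeled and the "previous event" of rule
#' (c) is the nearest preceding non-noise event. Merges cascade (a merge
#' that creates adjacent same-type runs coalesces them immediately) and
#' the result is stable under a second pass.
#'
#' @param labels character vector of per-sample event labels.
#' @param fs sampling frequency in Hz.
#' @param min_saccade_ms minimum saccade duration in milliseconds
#'   (default 10).
#' @return the relabeled character vector.
#' @export
relabel <- function(labels, fs, min_saccade_ms = 10) {
  min_len <- min_saccade_ms / 1000 * fs
  repeat {
    runs <- label_runs(labels)
    changed <- FALSE
    for (i in seq_len(nrow(runs))) {
      type <- runs$type[i]
      if (type == "noise") next
      offending <-
        (type %in% c("fixation", "pursuit") && runs$length[i] == 1L) ||
        (type == "saccade" && runs$length[i] < min_len) ||
        (type == "pso" && !identical(prev_non_noise(runs, i), "saccade"))
      if (!offending) next
      prev <- prev_non_noise(runs, i)
      new_type <- if (!is.null(prev)) {
        prev
      } else {
        nxt <- next_non_noise(runs, i)
        if (is.null(nxt)) break  # nothing to merge into
        nxt
      }
      if (identical(new_type, type)) next
      labels[runs$start[i]:runs$end[i]] <- new_type
      changed <- TRUE
      break  # recompute runs so merges coalesce before continuing
    }
    if (!changed) break
  }
  labels
}

prev_non_noise <- function(runs, i) {
  j <- i - 1L
  while (j >= 1L && runs$type[j] == "noise") j <- j - 1L
  if (j >= 1L) runs$type[j] else NULL
}

next_non_noise <- function(runs, i) {
  j <- i + 1L
  while (j <= nrow(runs) && runs$type[j] == "noise") j <- j + 1L
  if (j <= nrow(runs)) runs$type[j] else NULL
}

#' Label missing samples as noise
#'
#' Samples flagged missing before classification (blinks, blink padding,
#' filter edges, undefined angles) are labeled `noise` regardless of the
#' decoded state; all other labels are untouched.
#'
#' @param labels character vector of per-sample event labels.
#' @param missing logical mask aligned with `labels`.
#' @return the updated label vector.
#' @export
label_noise <- function(labels, missing) {
  if (length(labels) != length(missing))
    stop("'labels' and 'missing' must align")
  labels[missing] <- "noise"
  labels
}

#' Build the event table
#'
#' Maximal runs of equal labels become events. Event durations follow the
#' convention `Dur(e) = max(t_e) - max(t_{e-1})` — the time elapsed since
#' the last sample of the previous event — so that durations telescope to
#' the span of the recording; the first event uses its own span
#' (`max(t_1) - min(t_1)`).
#'
#' @param labels character vector of per-sample event labels.
#' @param t timestamps in seconds, aligned with `labels`.
#' @param vel optional per-sample velocity used for the per-event mean.
#' @return an object of class `"event_table"`: data.frame with columns
#'   `event`, `type`, `onset`, `offset`, `duration`, `i_start`, `i_end`,
#'   `mean_vel`.
#' @export
build_events <- function(labels, t, vel = NULL) {
  if (length(labels) != length(t)) stop("'labels' and 't' must align")
  if (length(labels) == 0) {
    out <- data.frame(event = integer(0), type = character(0),
                      onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), i_start = integer(0),
                      i_end = integer(0), mean_vel = numeric(0))
    class(out) <- c("event_table", "data.frame")
    return(out)
  }
  runs <- label_runs(labels)
  offset <- t[runs$end]
  duration <- c(offset[1] - t[runs$start[1]],
                if (nrow(runs) > 1) diff(offset))
  mean_vel <- if (is.null(vel)) NA_real_ else
    vapply(seq_len(nrow(runs)), function(i) {
      v <- vel[runs$start[i]:runs$end[i]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  out <- data.frame(event = seq_len(nrow(runs)), type = runs$type,
                    onset = t[runs$start], offset = offset,
                    duration = duration, i_start = runs$start,
                    i_end = runs$end, mean_vel = mean_vel,
                    stringsAsFactors = FALSE)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Per-event-type descriptives
#'
#' Mean and SD of event duration and event counts per type, the
#' ingredients of the duration/count RMSD comparison.
#'
#' @param events an [build_events()] table.
#' @return data.frame with columns `type`, `n`, `mean_duration`,
#'   `sd_duration`.
#' @export
event_descriptives <- function(events) {
  if (nrow(events) == 0)
    return(data.frame(type = character(0), n = integer(0),
                      mean_duration = numeric(0), sd_duration = numeric(0)))
  groups <- split(events$duration, events$type)
  data.frame(type = names(groups),
             n = vapply(groups, length, integer(1)),
             mean_duration = vapply(groups, mean, numeric(1)),
             sd_duration = vapply(groups, function(d)
               if (length(d) > 1) sd(d) else 0, numeric(1)),
             row.names = NULL)
}
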