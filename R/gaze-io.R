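# Reading and writing gaze sample tables. Gaze data have no standard
# bioinformatics container; the package reads plain delimited text
# (comma / tab / semicolon auto-detected) with configurable column names
# and writes plain CSV back out.

#' Construct a validated gaze recording
#'
#' @param x,y gaze position in degrees of visual angle.
#' @param t timestamps in seconds, strictly increasing. If `NULL`,
#'   synthesized as `(index - 1) / fs`.
#' @param fs nominal sampling frequency in Hz.
#' @param blink optional per-sample logical blink indicator (defaults to
#'   all `FALSE`).
#' @return an object of class `"gaze_recording"` with fields `t`, `x`,
#'   `y`, `blink`, `missing`, `fs`. Non-finite positions are flagged
#'   missing.
#' @export
gaze_recording <- function(x, y, t = NULL, fs, blink = NULL) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be a positive frequency in Hz")
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  if (length(t) != n) stop("'t' must align with 'x' and 'y'")
  if (n > 1 && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  if (is.null(blink)) blink <- rep(FALSE, n)
  blink <- as.logical(blink)
  blink[is.na(blink)] <- FALSE
  if (length(blink) != n) stop("'blink' must align with the samples")
  if (n > 1) {
    md <- median(diff(t))
    if (abs(md - 1 / fs) > 0.1 / fs)
      warning("median sample interval (", signif(md, 4),
              " s) deviates more than 10% from 1/fs = ", signif(1 / fs, 4),
              " s")
  }
  missing <- !is.finite(x) | !is.finite(y)
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 blink = blink, missing = missing, fs = fs),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat("Gaze recording: ", length(x$t), " samples at ", x$fs, " Hz (",
      signif(diff(range(x$t)), 4), " s), ", sum(x$blink), " blink, ",
      sum(x$missing), " missing\n", sep = "")
  invisible(x)
}

#' Read a gaze sample table
#'
#' Reads a delimited text file of gaze samples. The delimiter is
#' auto-detected among comma, tab and semicolon. Column names are mapped
#' through `column_map`; a missing time column is synthesized from the
#' sample index and `fs`, and a missing blink column defaults to all
#' `FALSE`. Non-finite positions are flagged missing.
#'
#' @param path path to the file.
#' @param fs sampling frequency in Hz.
#' @param column_map named character vector mapping the roles `t`, `x`,
#'   `y`, `blink` to column names in the file.
#' @return a [gaze_recording()].
#' @export
read_gaze <- function(path, fs,
                      column_map = c(t = "t", x = "x", y = "y",
                                     blink = "blink")) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- names(which.max(vapply(
    c("," = ",", "\t" = "\t", ";" = ";"),
    function(s) lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))),
    integer(1))))
  dat <- read.table(path, header = TRUE, sep = sep, dec = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("x", "y")
  for (role in need) {
    col <- column_map[[role]]
    if (is.null(col) || !(col %in% names(dat)))
      stop("input format error: required column '", col %||% role,
           "' (role '", role, "') not found in ", path)
  }
  t <- if (!is.null(column_map[["t"]]) && column_map[["t"]] %in% names(dat))
    dat[[column_map[["t"]]]] else NULL
  blink <- if (!is.null(column_map[["blink"]]) &&
               column_map[["blink"]] %in% names(dat))
    dat[[column_map[["blink"]]]] else NULL
  gaze_recording(x = dat[[column_map[["x"]]]], y = dat[[column_map[["y"]]]],
                 t = t, fs = fs, blink = blink)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write labeled samples and events
#'
#' Writes two CSV files: `<prefix>_samples.csv` with per-sample `t`, `x`,
#' `y`, `label`, and `<prefix>_events.csv` with one row per event (id,
#' type, onset, offset, duration, mean velocity). Both round-trip
#' losslessly through [utils::read.csv()] up to floating-point text
#' precision.
#'
#' @param rec the classified [gaze_recording()].
#' @param labels character vector of per-sample event labels.
#' @param events an event table from [build_events()].
#' @param path_prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_outputs <- function(rec, labels, events, path_prefix) {
  if (length(labels) != length(rec$t))
    stop("'labels' must align with the recording")
  sample_path <- paste0(path_prefix, "_samples.csv")
  event_path <- paste0(path_prefix, "_events.csv")
  write.csv(data.frame(t = rec$t, x = rec$x, y = rec$y, label = labels),
            sample_path, row.names = FALSE)
  ev <- as.data.frame(events)
  write.csv(ev, event_path, row.names = FALSE)
  invisible(c(samples = sample_path, events = event_path))
}
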