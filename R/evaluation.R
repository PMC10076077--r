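# Recovery and agreement metrics: RMdSPD, Cohen's kappa, label-switch
# resolution, recovery regressions, BIC/ICL model weights, and the
# two-labeling agreement report.

#' Root median square proportion deviation
#'
#' `sqrt(median(((est - truth) / truth)^2))` across replications — a
#' robust relative error between true and estimated parameter values.
#' Zero truths (circular mean directions at 0) are replaced by `2*pi`
#' before division. With `circular = TRUE` the deviations `est - truth`
#' are wrapped to `(-pi, pi]` first, so an estimate just below the wrap
#' point of the circle is not scored as a full-circle error. Values below
#' 0.1 are conventionally read as good, 0.1-0.5 as moderate and above 0.5
#' as bad recovery.
#'
#' @param truth,est equal-length numeric vectors.
#' @param circular wrap deviations to `(-pi, pi]` (for angular
#'   parameters)?
#' @return the RMdSPD (a non-negative scalar).
#' @export
rmdspd <- function(truth, est, circular = FALSE) {
  if (length(truth) != length(est)) stop("'truth' and 'est' must align")
  if (length(truth) == 0) stop("empty parameter vectors")
  denom <- ifelse(truth == 0, 2 * pi, truth)
  dev <- est - truth
  if (circular) dev <- ((dev + pi) %% (2 * pi)) - pi
  sqrt(median((dev / denom)^2))
}

#' Cohen's kappa between two label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` over per-sample
#' labels, multi-category by default. With `binary_for` the comparison
#' collapses to one-vs-rest agreement for a single event type, the
#' convention used when comparing classifiers per event.
#'
#' @param seq_a,seq_b equal-length label sequences (any atomic type).
#' @param binary_for optional single label; both sequences are reduced to
#'   `label` vs `other` before computing kappa.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(seq_a, seq_b, binary_for = NULL) {
  if (length(seq_a) != length(seq_b)) stop("sequences must align")
  if (length(seq_a) == 0) stop("empty sequences")
  if (!is.null(binary_for)) {
    seq_a <- ifelse(seq_a == binary_for, binary_for, ".other")
    seq_b <- ifelse(seq_b == binary_for, binary_for, ".other")
  }
  lev <- sort(unique(c(seq_a, seq_b)))
  a <- factor(seq_a, levels = lev)
  b <- factor(seq_b, levels = lev)
  tab <- table(a, b) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (p_e >= 1 - 1e-12) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Resolve label switching by permutation search
#'
#' Hidden-state labels in mixture/HMM estimation are identified only up to
#' permutation. This searches all permutations of the state labels of
#' `est` and returns the one maximizing Cohen's kappa against `truth`,
#' along with that kappa. The identity permutation is reported when it is
#' already maximal.
#'
#' @param truth,est integer state sequences over `1..k`.
#' @param k number of states (defaults to the largest label observed).
#' @return list with `permutation` (integer vector; new label of state i
#'   is `permutation[i]`) and `kappa`.
#' @export
best_permutation_match <- function(truth, est, k = max(truth, est)) {
  perms <- all_permutations(k)
  best <- NULL
  best_kappa <- -Inf
  for (p in perms) {
    kap <- cohens_kappa(truth, p[est])
    if (kap > best_kappa + 1e-12) { best_kappa <- kap; best <- p }
  }
  list(permutation = best, kappa = best_kappa)
}

# All permutations of 1..k, identity first (so ties keep it).
all_permutations <- function(k) {
  k <- as.integer(k)
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (pos in seq_len(k)) {
    for (s in sub) out[[length(out) + 1]] <- append(s, k, after = k - pos)
  }
  # reorder so the identity comes first
  ids <- vapply(out, function(p) all(p == seq_len(k)), logical(1))
  c(out[ids], out[!ids])
}

#' Recovery regression of estimates on truths
#'
#' Ordinary least squares of the estimated parameter values on the true
#' values. Slopes close to one indicate that parameter change is
#' captured; intercepts different from zero indicate estimation bias.
#'
#' @param truths,estimates equal-length numeric vectors (at least 3
#'   pairs; truths must vary).
#' @return named numeric vector `c(intercept, slope)`.
#' @export
recovery_regression <- function(truths, estimates) {
  if (length(truths) < 3) stop("need at least 3 pairs")
  if (sd(truths) == 0) stop("'truths' are constant; regression undefined")
  fit <- lm(estimates ~ truths)
  setNames(coef(fit), c("intercept", "slope"))
}

#' BIC/ICL model weights
#'
#' Converts information-criterion values of competing models into weights
#' `w_m = exp(-Delta_m / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_m = criterion_m - min(criterion)` (Schwarz weights when applied
#' to BIC values). The weights sum to one and the smallest criterion gets
#' the largest weight; adding a constant to all criteria leaves them
#' unchanged.
#'
#' @param criteria numeric vector of at least two finite criterion
#'   values.
#' @return numeric vector of weights summing to 1.
#' @export
model_weights <- function(criteria) {
  if (length(criteria) < 2) stop("need at least two criterion values")
  if (any(!is.finite(criteria))) stop("criterion values must be finite")
  d <- criteria - min(criteria)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Agreement report between two labelings
#'
#' Compares two per-sample event labelings of the same recording:
#' per-event-type mean/SD duration and counts for both labelings, an RMSD
#' summary of those three quantities per type, per-event one-vs-rest
#' Cohen's kappa, a confusion matrix normalized so the columns (the
#' `labels_b` reference totals) sum to one, and the overall disagreement
#' (the fraction of samples labeled differently).
#'
#' The three RMSD components live on different scales, so each deviation
#' is divided by the reference value before aggregation
#' (`normalize = "relative"`, the default); `normalize = "raw"` aggregates
#' the plain deviations.
#'
#' @param labels_a,labels_b aligned per-sample label vectors (`labels_b`
#'   is the reference).
#' @param t timestamps in seconds.
#' @param normalize `"relative"` or `"raw"` RMSD aggregation.
#' @return list with `descriptives`, `rmsd`, `event_kappa`, `confusion`,
#'   `disagreement`.
#' @export
agreement_report <- function(labels_a, labels_b, t,
                             normalize = c("relative", "raw")) {
  normalize <- match.arg(normalize)
  if (length(labels_a) != length(labels_b) || length(labels_a) != length(t))
    stop("label sequences and timestamps must align")
  ev_a <- event_descriptives(build_events(labels_a, t))
  ev_b <- event_descriptives(build_events(labels_b, t))
  types <- sort(unique(c(ev_a$type, ev_b$type)))
  desc <- merge(ev_a, ev_b, by = "type", all = TRUE,
                suffixes = c("_a", "_b"))
  for (cl in c("n_a", "n_b")) desc[[cl]][is.na(desc[[cl]])] <- 0L

  rmsd <- vapply(types, function(ty) {
    row <- desc[desc$type == ty, ]
    av <- c(row$mean_duration_a, row$sd_duration_a, row$n_a)
    bv <- c(row$mean_duration_b, row$sd_duration_b, row$n_b)
    av[is.na(av)] <- 0; bv[is.na(bv)] <- 0
    dev <- av - bv
    if (normalize == "relative") dev <- dev / ifelse(bv == 0, 1, bv)
    sqrt(mean(dev^2))
  }, numeric(1))

  event_kappa <- vapply(types, function(ty)
    cohens_kappa(labels_a, labels_b, binary_for = ty), numeric(1))

  lev <- sort(unique(c(labels_a, labels_b)))
  conf <- table(factor(labels_a, lev), factor(labels_b, lev))
  totals <- colSums(conf)
  conf_norm <- sweep(conf, 2, ifelse(totals == 0, 1, totals), "/")

  list(descriptives = desc,
       rmsd = setNames(rmsd, types),
       event_kappa = setNames(event_kappa, types),
       confusion = conf_norm,
       disagreement = mean(labels_a != labels_b))
}
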