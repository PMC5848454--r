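## Evaluation harness: intensity clamping, probe splitting, PCC, ROC AUC,
## paired tests, per-RBP aggregation.

#' Clamp intensity outliers at an upper percentile
#'
#' Values above the empirical percentile (type-7, linear interpolation) are
#' replaced by the percentile value; everything else is unchanged and order
#' is preserved. Default 99.95, the standard outlier cap for probe
#' intensities. Idempotent.
#'
#' @param intensities non-empty numeric vector.
#' @param percentile percentile in (0, 100).
#' @return clamped vector.
#' @export
clamp_intensities <- function(intensities, percentile = 99.95) {
  if (length(intensities) == 0) stop_input("empty intensity vector")
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile >= 100)
    stop_input("'percentile' must lie in (0, 100)")
  cap <- quantile(intensities, percentile / 100, type = 7, names = FALSE,
                  na.rm = FALSE)
  pmin(intensities, cap)
}

#' Split a probe set into two halves (sets A and B)
#'
#' Seeded uniform disjoint ~50/50 split covering all probes; set A receives
#' the extra probe when the count is odd.
#'
#' @param probes a [probe_set()] with at least 2 probes.
#' @param seed RNG seed.
#' @return list with elements `A` and `B`, both [probe_set()]s.
#' @export
split_ab <- function(probes, seed = 1) {
  stopifnot(inherits(probes, "probe_set"))
  n <- length(probes)
  if (n < 2) stop_input("need at least 2 probes to split")
  perm <- with_seed(seed, sample.int(n))
  a_idx <- sort(perm[seq_len(ceiling(n / 2))])
  b_idx <- sort(perm[(ceiling(n / 2) + 1):n])
  list(A = probes[a_idx], B = probes[b_idx])
}

.new_eval_result <- function(metric, value, n, method_id) {
  structure(list(metric = metric, value = as.numeric(value),
                 n = as.integer(n), method_id = as.character(method_id)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (n = %d%s)\n", toupper(x$metric), x$value, x$n,
              if (nzchar(x$method_id)) paste0(", ", x$method_id) else ""))
  invisible(x)
}

#' Pearson correlation between predicted and observed values
#'
#' @param predicted,observed equal-length numeric vectors.
#' @param method_id optional tag recorded in the result.
#' @return an `eval_result` with `metric = "pcc"`.
#' @export
eval_pcc <- function(predicted, observed, method_id = "") {
  if (length(predicted) != length(observed))
    stop_input("'predicted' and 'observed' lengths differ")
  if (length(predicted) < 2) stop_input("need at least 2 observations")
  if (sd(predicted) == 0 || sd(observed) == 0)
    stop_degenerate("zero variance: PCC undefined")
  .new_eval_result("pcc", cor(predicted, observed), length(predicted),
                   method_id)
}

#' ROC AUC of scores against binary labels
#'
#' Computed exactly via the midrank Mann-Whitney identity, so tied scores
#' contribute 0.5 per tied positive/negative pair.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length, both classes present.
#' @inheritParams eval_pcc
#' @return an `eval_result` with `metric = "auc"`.
#' @export
eval_auc <- function(scores, labels, method_id = "") {
  if (length(scores) != length(labels))
    stop_input("'scores' and 'labels' lengths differ")
  if (!all(labels %in% c(0, 1))) stop_input("'labels' must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_degenerate("both classes must be present for AUC")
  r <- rank(scores)  # midranks
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  .new_eval_result("auc", auc, length(scores), method_id)
}

#' Paired t-test between two matched performance vectors
#'
#' Two-sided paired Student t-test, e.g. between per-experiment PCCs of two
#' methods evaluated on the same experiments.
#'
#' @param metric_a,metric_b equal-length (>= 3) paired numeric vectors.
#' @param alternative passed to [stats::t.test()] (default two-sided).
#' @return the p-value.
#' @export
paired_ttest <- function(metric_a, metric_b, alternative = "two.sided") {
  if (length(metric_a) != length(metric_b))
    stop_input("paired vectors must have equal length")
  if (length(metric_a) < 3) stop_input("need at least 3 pairs")
  d <- metric_a - metric_b
  if (sd(d) == 0)
    stop_degenerate("zero-variance differences: paired t-test undefined")
  t.test(metric_a, metric_b, paired = TRUE,
         alternative = alternative)$p.value
}

#' Average a metric per RBP
#'
#' Collapses repeated entries (e.g. several test sets per RBP) to one mean
#' per `rbp_id`, in order of first occurrence.
#'
#' @param entries data.frame with columns `rbp_id` and `value`.
#' @return data.frame with one row per `rbp_id` and its mean `value`.
#' @export
aggregate_mean_per_rbp <- function(entries) {
  if (!is.data.frame(entries) || nrow(entries) == 0 ||
      !all(c("rbp_id", "value") %in% names(entries)))
    stop_input("'entries' must be a non-empty data.frame(rbp_id, value)")
  ids <- unique(entries$rbp_id)
  means <- vapply(ids, function(id)
    mean(entries$value[entries$rbp_id == id]), 0)
  data.frame(rbp_id = ids, value = unname(means), stringsAsFactors = FALSE)
}
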