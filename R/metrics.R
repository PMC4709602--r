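# Evaluation metrics over pooled LOOCV trials: ROC/AUC by threshold
# sweep, confusion-matrix summaries at fixed specificity, precision and
# recall at k, fold enrichment, percentile retrieval.

# Threshold sweep over pooled (score, label) pairs. Ties are grouped, so
# the trapezoidal area equals the Mann-Whitney statistic with half credit
# for tied positive/negative pairs.
.sweep_roc <- function(score, label) {
  stopifnot(length(score) == length(label), is.logical(label))
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC requires both positive and negative labels")
  }
  o <- order(score, decreasing = TRUE, method = "radix")
  s <- score[o]
  y <- label[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)  # end of each tie group
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  points <- tibble(threshold = c(Inf, thr),
                   fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) *
               (head(points$tpr, -1L) + tail(points$tpr, -1L)) / 2)
  # confusion counts at every threshold, reused by confusion_metrics()
  list(auc = auc, points = points,
       counts = tibble(threshold = thr, tp = tp, fp = fp,
                       fn = n_pos - tp, tn = n_neg - fp))
}

#' ROC curve and AUC over pooled LOOCV trials
#'
#' Pools the (score, label) pairs of every trial - the held-out protein
#' of each trial is the positive, its fellow candidates the negatives -
#' and sweeps the score threshold. The area under the curve is computed
#' by trapezoidal integration and equals the normalized Mann-Whitney
#' statistic.
#'
#' @param trials An `lpihn_loocv` tibble from [run_loocv()].
#' @return An object of class `lpihn_roc`: list with `auc` and a tibble
#'   `points` of `(threshold, fpr, tpr)` rows, `fpr` being `1 -
#'   specificity` and `tpr` sensitivity.
#' @export
roc_auc <- function(trials) {
  pooled <- .pool_trials(trials)
  res <- .sweep_roc(pooled$score, pooled$label)
  structure(list(auc = res$auc, points = res$points), class = "lpihn_roc")
}

#' @export
print.lpihn_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d threshold points)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

# Sn/Sp/Acc/Pre/MCC from raw confusion counts. MCC is 0 whenever any
# factor of its denominator vanishes.
.confusion_from_counts <- function(tp, fp, tn, fn) {
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tn + tp) / (tn + tp + fn + fp)
  no_pos <- (tp + fp) == 0
  pre <- if (no_pos) 0 else tp / (tp + fp)
  denom <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  tibble(sn = sn, sp = sp, acc = acc, pre = pre, mcc = mcc,
         no_positive_predictions = no_pos)
}

#' Confusion-matrix metrics at fixed specificity
#'
#' For each requested specificity level, chooses the pooled score
#' threshold whose specificity is closest to the level while remaining at
#' or above it (predicting positive means score >= threshold), then
#' reports sensitivity, accuracy, precision and Matthews correlation
#' coefficient at that operating point. When no positive predictions are
#' made, precision is reported as 0 and flagged.
#'
#' @param trials An `lpihn_loocv` tibble from [run_loocv()].
#' @param sp_levels Specificity operating points; default
#'   `c(0.99, 0.95, 0.90)`.
#' @return A tibble with one row per level: `sp_target`, `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `sn`, `sp`, `acc`, `pre`, `mcc`,
#'   `no_positive_predictions`.
#' @export
confusion_metrics <- function(trials, sp_levels = c(0.99, 0.95, 0.90)) {
  pooled <- .pool_trials(trials)
  res <- .sweep_roc(pooled$score, pooled$label)
  cnt <- res$counts
  n_pos <- cnt$tp[1L] + cnt$fn[1L]
  n_neg <- cnt$fp[1L] + cnt$tn[1L]
  # prepend the all-negative operating point (threshold above every score)
  cnt <- dplyr::bind_rows(
    tibble(threshold = Inf, tp = 0, fp = 0, fn = n_pos, tn = n_neg), cnt)
  sp_all <- cnt$tn / (cnt$tn + cnt$fp)
  out <- lapply(sp_levels, function(lev) {
    .check_prob(lev, "sp_level", lo_open = FALSE, hi_open = FALSE)
    ok <- which(sp_all >= lev)
    # smallest specificity still >= the level; among ties, most positives
    best <- ok[order(sp_all[ok], -cnt$tp[ok])][1L]
    row <- cnt[best, ]
    dplyr::bind_cols(
      tibble(sp_target = lev, threshold = row$threshold,
             tp = row$tp, fp = row$fp, tn = row$tn, fn = row$fn),
      .confusion_from_counts(row$tp, row$fp, row$tn, row$fn))
  })
  dplyr::bind_rows(out)
}

#' Precision and recall at rank cutoff k
#'
#' For each `k`, a trial counts as recovered when its held-out protein is
#' ranked within the top `k` candidates. Precision at `k` is the pooled
#' fraction of top-`k` slots occupied by true interactions,
#' `(# trials with rank <= k) / (n_trials * k)`; recall at `k` is
#' `(# trials with rank <= k) / n_trials`, non-decreasing in `k`.
#'
#' @param trials An `lpihn_loocv` tibble from [run_loocv()].
#' @param k_max Largest cutoff; defaults to the number of proteins.
#'   Values above the protein count are clamped with a warning.
#' @return A tibble with columns `k`, `precision`, `recall`.
#' @export
precision_recall_at_k <- function(trials, k_max = NULL) {
  m <- attr(trials, "n_proteins") %||% max(trials$n_candidates)
  k_max <- k_max %||% m
  if (k_max > m) {
    warn(sprintf("k_max = %d exceeds the %d proteins; clamped", k_max, m))
    k_max <- m
  }
  n_trials <- nrow(trials)
  ks <- seq_len(k_max)
  hits <- vapply(ks, function(k) sum(trials$rank <= k), numeric(1))
  tibble(k = ks, precision = hits / (n_trials * ks), recall = hits / n_trials)
}

#' Mean fold enrichment of held-out ranks
#'
#' A trial whose held-out protein ranks `n`-th among `N` candidates has
#' fold enrichment `N / (2 n)`; a uniformly random ranker has expectation
#' about 1, so values well above 1 indicate signal. Returns the mean over
#' trials.
#'
#' @param trials An `lpihn_loocv` tibble from [run_loocv()].
#' @return A single number, the mean fold enrichment.
#' @export
fold_enrichment <- function(trials) {
  mean(trials$n_candidates / (2 * trials$rank))
}

#' Retrieval counts within top percentiles
#'
#' For each percentile `q`, counts the trials whose held-out protein is
#' ranked within the top `q` percent of its candidate list, using the
#' ceiling cutoff `ceiling(q * N / 100)` so the bucket is never empty.
#'
#' @param trials An `lpihn_loocv` tibble from [run_loocv()].
#' @param percentiles Percentile levels in (0, 100].
#' @return A tibble with columns `percentile` and `count`, `count`
#'   non-decreasing.
#' @export
percentile_retrieval <- function(trials,
                                 percentiles = c(1, 2, 5, 10, 25, 50, 100)) {
  stopifnot(all(percentiles > 0 & percentiles <= 100))
  counts <- vapply(percentiles, function(q) {
    sum(trials$rank <= ceiling(q * trials$n_candidates / 100))
  }, numeric(1))
  tibble(percentile = percentiles, count = counts)
}
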