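# broom-style tidiers for the LOOCV result.

#' Tidy the per-trial LOOCV table
#'
#' Drops the list-columns, leaving one plain row per trial.
#'
#' @param x An `lpihn_loocv` tibble from [run_loocv()].
#' @param ... Unused.
#' @return A tibble with columns `query`, `held_out`, `rank`,
#'   `n_candidates`, `fold_enrichment`.
#' @export
tidy.lpihn_loocv <- function(x, ...) {
  tibble(query = x$query,
         held_out = x$held_out,
         rank = x$rank,
         n_candidates = x$n_candidates,
         fold_enrichment = x$n_candidates / (2 * x$rank))
}

#' One-row summary of a LOOCV run
#'
#' @param x An `lpihn_loocv` tibble from [run_loocv()].
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_trials`, `n_queries`,
#'   `n_proteins`, `auc`, `mean_fold_enrichment`, `recall_at_10`.
#' @export
glance.lpihn_loocv <- function(x, ...) {
  tibble(
    method = attr(x, "method") %||% NA_character_,
    n_trials = nrow(x),
    n_queries = length(unique(x$query)),
    n_proteins = attr(x, "n_proteins") %||% NA_integer_,
    auc = roc_auc(x)$auc,
    mean_fold_enrichment = fold_enrichment(x),
    recall_at_10 = mean(x$rank <= 10)
  )
}

#' Plot LOOCV results
#'
#' `type = "roc"` draws the pooled ROC curve with the chance diagonal;
#' `type = "pr"` the precision-recall-at-k curve; `type = "ranks"` a
#' histogram of held-out ranks.
#'
#' @param object An `lpihn_loocv` tibble from [run_loocv()].
#' @param type One of `"roc"`, `"pr"`, `"ranks"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lpihn_loocv <- function(object, type = c("roc", "pr", "ranks"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    return(autoplot(roc_auc(object)))
  }
  if (type == "pr") {
    prk <- precision_recall_at_k(object)
    return(
      ggplot2::ggplot(prk, ggplot2::aes(x = .data$recall, y = .data$precision)) +
        ggplot2::geom_step() +
        ggplot2::labs(x = "Recall at k", y = "Precision at k",
                      title = "Precision-recall over rank cutoffs") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0.5,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "Rank of held-out protein", y = "Trials",
                  title = "Held-out rank distribution") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lpihn_loocv
#' @export
autoplot.lpihn_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("Pooled ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}
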