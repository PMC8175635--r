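#' ROC curve and AUROC
#'
#' The area under the ROC curve is computed as the Mann-Whitney U statistic
#' scaled by `n_pos * n_neg`, with tied scores given half credit (midrank
#' convention — short fragments can tie). The curve itself is a threshold
#' sweep over the distinct scores.
#'
#' @param scores Numeric classifier scores (higher = more positive-like).
#' @param labels Class labels: logical, 0/1, or a two-level factor where the
#'   second level is the positive class.
#' @return An object of class `roc_result`: `auc`, `curve` (tibble of
#'   `threshold`, `fpr`, `tpr`, starting at (0,0) and ending at (1,1)),
#'   `n_pos`, `n_neg`, `bootstrap_se` (`NA` until [bootstrap_auc_se()] is
#'   used), `n_bootstrap`.
#' @examples
#' auroc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) abort("`scores` and `labels` lengths differ")
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores) # midranks handle ties
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yo <- y[ord]
  tp <- cumsum(yo); fp <- cumsum(1 - yo)
  last_of_tie <- !duplicated(s, fromLast = TRUE)
  curve <- tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp[last_of_tie] / n_neg),
    tpr = c(0, tp[last_of_tie] / n_pos)
  )
  structure(
    list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg,
         bootstrap_se = NA_real_, n_bootstrap = NA_integer_),
    class = "roc_result"
  )
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2]))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  u <- sort(unique(labels))
  if (length(u) > 2) abort("labels must have two levels")
  as.integer(labels == u[length(u)])
}

#' Bootstrap standard error of the AUROC
#'
#' Standard deviation of the AUC over `n_bootstrap` resamples drawn with
#' replacement, stratified by class so every replicate contains both classes.
#'
#' @param scores,labels As in [auroc()].
#' @param n_bootstrap Number of resamples (default 30).
#' @param seed Optional integer seed.
#' @return The numeric bootstrap standard error.
#' @export
bootstrap_auc_se <- function(scores, labels, n_bootstrap = 30, seed = NULL) {
  y <- as_binary_labels(labels)
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("both classes must be present")
  }
  aucs <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      auroc(scores[idx], y[idx])$auc
    }, numeric(1))
  })
  sd(aucs)
}

#' Precision and recall as a function of the lambda cutoff
#'
#' At each cutoff, sequences with `lambda >= cutoff` are called viral;
#' precision is TP/(TP+FP) (reported `NA` when nothing is called), recall is
#' TP/(TP+FN). The cutoff where precision and recall cross (smallest
#' `|precision - recall|`) is attached as attribute `crossing`.
#'
#' @param scores,labels As in [auroc()].
#' @param cutoffs Cutoff grid (default: the distinct scores, ascending).
#' @return Tibble with `cutoff`, `precision`, `recall`, `f1`, and attribute
#'   `crossing`.
#' @export
precision_recall_vs_lambda <- function(scores, labels, cutoffs = NULL) {
  y <- as_binary_labels(labels)
  cutoffs <- cutoffs %||% sort(unique(scores))
  rows <- purrr::map(cutoffs, function(co) {
    called <- scores >= co
    tp <- sum(called & y == 1L)
    precision <- if (sum(called) == 0L) NA_real_ else tp / sum(called)
    recall <- tp / sum(y == 1L)
    f1 <- if (is.na(precision) || precision + recall == 0) {
      NA_real_
    } else {
      2 * precision * recall / (precision + recall)
    }
    tibble(cutoff = co, precision = precision, recall = recall, f1 = f1)
  })
  out <- dplyr::bind_rows(rows)
  defined <- !is.na(out$precision)
  crossing <- if (any(defined)) {
    out$cutoff[defined][which.min(abs(out$precision - out$recall)[defined])]
  } else {
    NA_real_
  }
  attr(out, "crossing") <- crossing
  out
}

#' False-positive rate on contaminant (e.g. eukaryotic) fragments
#'
#' Fraction of contaminant-only fragments whose lambda score exceeds the
#' cutoff, i.e. `1 - ECDF(cutoff)` of the contaminant scores.
#'
#' @param scores Lambda scores of contaminant fragments.
#' @param cutoff Lambda cutoff for the viral call.
#' @return Numeric FPR in `[0, 1]`.
#' @export
contaminant_fpr <- function(scores, cutoff) {
  if (length(scores) == 0L) abort("`scores` is empty")
  mean(scores > cutoff)
}

#' @export
print.roc_result <- function(x, ...) {
  se <- if (is.na(x$bootstrap_se)) "" else sprintf(" (bootstrap SE %.4f, n = %d)",
                                                   x$bootstrap_se, x$n_bootstrap)
  cat(sprintf("<roc_result> AUC = %.4f%s; %d positive vs %d negative\n",
              x$auc, se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Tidy / glance / plot methods for ROC results
#'
#' `tidy()` returns the ROC curve points; `glance()` a one-row summary;
#' `autoplot()` the ROC curve with the chance diagonal.
#'
#' @param x,object A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, bootstrap_se = x$bootstrap_se,
         n_bootstrap = x$n_bootstrap, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname tidy.roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}

#' Plot precision and recall against the lambda cutoff
#'
#' @param pr A [precision_recall_vs_lambda()] table.
#' @return A ggplot object; the precision/recall crossing cutoff is marked.
#' @export
plot_precision_recall <- function(pr) {
  long <- tidyr::pivot_longer(pr[, c("cutoff", "precision", "recall")],
                              c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                          colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda ~ "cutoff"), y = NULL, colour = NULL)
  crossing <- attr(pr, "crossing")
  if (!is.null(crossing) && !is.na(crossing)) {
    p <- p + ggplot2::geom_vline(xintercept = crossing, linetype = "dotted")
  }
  p
}
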