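#' Score contigs with the lambda likelihood-ratio statistic
#'
#' For each sequence, the viral and host mean log-likelihoods are the maxima
#' over the respective GC-binned model ensembles; lambda compares them so
#' that `lambda > 1` means the viral likelihood exceeds the host likelihood
#' (under the default `"decision"` orientation, `lambda = ll_host/ll_virus`
#' on negative mean log-likelihoods). Because lambda is a ratio of mean
#' log-likelihoods it is invariant to the logarithm base.
#'
#' If the classifier carries a bacterial null distribution, each scoreable
#' sequence also receives an empirical p-value (fraction of null fragments
#' with strictly greater lambda, taken from the query's length stratum) and a
#' Benjamini-Hochberg q-value computed across the scored set.
#'
#' @param x Query sequences: tibble with an id column (`id`/`fragment_id`/
#'   `pair_id`) and `sequence`, or a character vector.
#' @param classifier A [build_classifier()] object.
#' @param call_threshold Lambda cutoff for the `viral` call (strictly
#'   greater; default 1, the natural likelihood-ratio decision point).
#' @return A tibble with one row per input, in input order: `id`, `length`,
#'   `ll_virus`, `ll_host`, `lambda`, `pvalue`, `qvalue`, `call`
#'   (`viral`/`host`/`unscoreable`). Unscoreable records are flagged, never
#'   dropped.
#' @export
score_sequences <- function(x, classifier, call_threshold = 1) {
  stopifnot(inherits(classifier, "markov_classifier"))
  qry <- as_fragment_input(x)
  k <- classifier$k
  nv <- length(classifier$virus$models)
  comp <- ll_components(qry$sequence,
                        c(classifier$virus$models, classifier$host$models), k)
  ll <- comp$sums / comp$nwin
  ll_virus <- do.call(pmax, as.data.frame(ll[, seq_len(nv), drop = FALSE]))
  ll_host <- do.call(pmax, as.data.frame(ll[, -seq_len(nv), drop = FALSE]))
  lam <- lambda_from_ll(ll_virus, ll_host, classifier$orientation)
  out <- tibble(
    id = qry$id,
    length = nchar(qry$sequence),
    ll_virus = ll_virus,
    ll_host = ll_host,
    lambda = lam,
    pvalue = NA_real_,
    qvalue = NA_real_,
    call = dplyr::case_when(
      is.na(lam) ~ "unscoreable",
      lam > call_threshold ~ "viral",
      TRUE ~ "host"
    )
  )
  attach_pvalues(out, classifier)
}

lambda_from_ll <- function(ll_virus, ll_host, orientation) {
  lam <- if (orientation == "decision") ll_host / ll_virus else ll_virus / ll_host
  lam[is.na(ll_virus) | is.na(ll_host)] <- NA_real_
  lam
}

attach_pvalues <- function(scores, classifier) {
  if (is.null(classifier$null_scores)) return(scores)
  ok <- !is.na(scores$lambda)
  p <- rep(NA_real_, nrow(scores))
  for (len in unique(scores$length[ok])) {
    sel <- ok & scores$length == len
    p[sel] <- empirical_pvalue(scores$lambda[sel],
                               null_for_length(classifier, len))
  }
  scores$pvalue <- p
  scores$qvalue[ok] <- qvalues(p[ok])
  scores
}

#' Empirical p-value against a bacterial null distribution
#'
#' `p = (# null scores strictly greater than lambda) / n_null`. With
#' `smoothing = TRUE` the add-one form `(count + 1) / (n + 1)` is used, which
#' avoids exact zeros.
#'
#' @param lambda Numeric vector of query lambda scores.
#' @param null Numeric vector of null lambda scores (order irrelevant).
#' @param smoothing Use add-one smoothing (default `FALSE`).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' empirical_pvalue(c(1.2, 0.95), c(0.9, 1.0, 1.1))
#' @export
empirical_pvalue <- function(lambda, null, smoothing = FALSE) {
  if (is.null(null) || length(null) == 0L) {
    abort("classifier built without null fragments: no null distribution available")
  }
  sorted <- sort(null)
  n <- length(sorted)
  greater <- n - findInterval(lambda, sorted)
  if (smoothing) (greater + 1) / (n + 1) else greater / n
}

#' False-discovery-rate adjusted q-values
#'
#' Benjamini-Hochberg by default; `"storey"` additionally scales by the
#' estimated null proportion `pi0 = min(1, 2 * mean(p > 0.5))`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"storey"`.
#' @return Numeric vector of monotone q-values in `[0, 1]`.
#' @examples
#' qvalues(c(0.01, 0.02, 0.03, 0.04))
#' @export
qvalues <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, 2 * mean(p > 0.5, na.rm = TRUE))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Score paired-end reads jointly
#'
#' The two mates of a pair are scored as one unit: each model's mean
#' log-likelihood is taken over the union of both mates' scoreable windows
#' (windows never span the mate junction), and lambda is formed exactly as in
#' [score_sequences()]. The record length is the summed mate length. A pair
#' is unscoreable only if both mates are.
#'
#' @param pairs Tibble with columns `pair_id`, `mate1`, `mate2`.
#' @param classifier A [build_classifier()] object.
#' @param call_threshold As in [score_sequences()].
#' @return Score tibble as in [score_sequences()] (`id` = `pair_id`).
#' @export
score_read_pairs <- function(pairs, classifier, call_threshold = 1) {
  stopifnot(inherits(classifier, "markov_classifier"))
  if (!all(c("pair_id", "mate1", "mate2") %in% names(pairs))) {
    abort("`pairs` must have columns `pair_id`, `mate1`, `mate2`")
  }
  k <- classifier$k
  models <- c(classifier$virus$models, classifier$host$models)
  nv <- length(classifier$virus$models)
  c1 <- ll_components(pairs$mate1, models, k)
  c2 <- ll_components(pairs$mate2, models, k)
  s1 <- c1$sums; s1[is.na(s1)] <- 0
  s2 <- c2$sums; s2[is.na(s2)] <- 0
  nwin <- c1$nwin + c2$nwin
  ll <- (s1 + s2) / nwin # nwin == 0 -> NaN -> unscoreable
  ll[nwin == 0, ] <- NA_real_
  ll_virus <- do.call(pmax, as.data.frame(ll[, seq_len(nv), drop = FALSE]))
  ll_host <- do.call(pmax, as.data.frame(ll[, -seq_len(nv), drop = FALSE]))
  lam <- lambda_from_ll(ll_virus, ll_host, classifier$orientation)
  out <- tibble(
    id = as.character(pairs$pair_id),
    length = nchar(pairs$mate1) + nchar(pairs$mate2),
    ll_virus = ll_virus,
    ll_host = ll_host,
    lambda = lam,
    pvalue = NA_real_,
    qvalue = NA_real_,
    call = dplyr::case_when(
      is.na(lam) ~ "unscoreable",
      lam > call_threshold ~ "viral",
      TRUE ~ "host"
    )
  )
  attach_pvalues(out, classifier)
}

#' Partition read pairs by lambda score before assembly
#'
#' Scores every pair and splits the input into kept (putative viral),
#' discarded, and unscoreable pairs under exactly one of two rules:
#'
#' * `lambda_min`: keep pairs with `lambda >= lambda_min`;
#' * `top_fraction`: keep the top `f` fraction of scoreable pairs by lambda
#'   (the cut at the empirical `1 - f` quantile; ties broken by `pair_id`
#'   order, deterministic).
#'
#' @param pairs Tibble with `pair_id`, `mate1`, `mate2` (additional columns
#'   such as qualities are carried through).
#' @param classifier A [build_classifier()] object.
#' @param lambda_min Lambda threshold rule.
#' @param top_fraction Top-fraction rule, in `(0, 1)`.
#' @param unscoreable What to do with unscoreable pairs: `"discard"`
#'   (default; conservative for viral assembly — they end up in the
#'   `unscoreable` partition, not among kept reads) or `"keep"`.
#' @return A list with tibbles `kept`, `discarded`, `unscoreable` (the input
#'   rows plus their score columns), and a one-row `summary` tibble
#'   (`n_input`, `n_kept`, `n_discarded`, `n_unscoreable`, `rule`,
#'   `cutoff` — the realized lambda cutoff — and `fraction_kept`). The three
#'   partitions always add up to the input.
#' @export
filter_read_pairs <- function(pairs, classifier, lambda_min = NULL,
                              top_fraction = NULL,
                              unscoreable = c("discard", "keep")) {
  unscoreable <- match.arg(unscoreable)
  if (is.null(lambda_min) == is.null(top_fraction)) {
    abort("supply exactly one of `lambda_min` or `top_fraction`")
  }
  scores <- score_read_pairs(pairs, classifier)
  full <- dplyr::bind_cols(as_tibble(pairs),
                           scores[, c("lambda", "pvalue", "qvalue", "call")])
  is_un <- is.na(full$lambda)
  if (!is.null(lambda_min)) {
    keep <- !is_un & full$lambda >= lambda_min
    cutoff <- lambda_min
    rule <- sprintf("lambda_min=%g", lambda_min)
  } else {
    if (top_fraction <= 0 || top_fraction >= 1) {
      abort("`top_fraction` must lie in (0, 1)")
    }
    scoreable_idx <- which(!is_un)
    n_keep <- floor(top_fraction * length(scoreable_idx) + 1e-9)
    ord <- scoreable_idx[order(-full$lambda[scoreable_idx],
                               as.character(full$pair_id[scoreable_idx]))]
    keep <- rep(FALSE, nrow(full))
    keep[head(ord, n_keep)] <- TRUE
    cutoff <- if (n_keep > 0) min(full$lambda[keep]) else Inf
    rule <- sprintf("top_fraction=%g", top_fraction)
  }
  if (unscoreable == "keep") keep[is_un] <- TRUE
  kept <- full[keep, ]
  discarded <- full[!keep & !is_un, ]
  unscored <- full[!keep & is_un, ]
  list(
    kept = kept,
    discarded = discarded,
    unscoreable = unscored,
    summary = tibble(
      n_input = nrow(full),
      n_kept = nrow(kept),
      n_discarded = nrow(discarded),
      n_unscoreable = nrow(unscored),
      rule = rule,
      cutoff = cutoff,
      fraction_kept = nrow(kept) / max(1L, nrow(full))
    )
  )
}
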