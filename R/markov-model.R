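#' Estimate a k-th order Markov transition model from k-mer counts
#'
#' Turns strand-symmetric counts `N(w)` into smoothed log transition
#' probabilities `log P(x | u)` for every context `u` (a `k`-mer) and next
#' base `x`. Two normalisations are available:
#'
#' * `"row"` (default): `P(x|u) = (N(ux) + c) / (sum_x' N(ux') + 4c)` — a
#'   proper conditional distribution for every context, including contexts
#'   never observed in training.
#' * `"prefix"`: `P(x|u) = (N(ux) + c) / (N(u) + 4c)`, using the context
#'   k-mer count itself as the denominator (the textbook maximum-likelihood
#'   form). This differs from `"row"` only through sequence-boundary effects
#'   and slightly under-normalises each row; it is retained for fidelity
#'   checks of the estimator's strand-symmetry identities.
#'
#' Additive smoothing with pseudocount `c > 0` keeps every transition finite:
#' at high orders (e.g. the default order 9 used for classification) most
#' 10-mers are unseen in any finite corpus.
#'
#' @param table A [count_kmers()] result.
#' @param pseudocount Additive smoothing constant `c > 0` per (context, base)
#'   cell. Default 1.
#' @param mode `"row"` or `"prefix"` (see above).
#' @param gc_bin Optional numeric `(low, high)` GC-fraction interval this
#'   model covers (recorded metadata).
#' @param label Optional corpus label (recorded metadata).
#' @return An object of class `markov_model`: `k`, `log_transition` (numeric
#'   vector of length `4^(k+1)`, natural-log probabilities in lexicographic
#'   word order, entry for word `ux` holding `log P(x|u)`), `pseudocount`,
#'   `mode`, `gc_bin`, `training` metadata.
#' @examples
#' m <- estimate_transitions(count_kmers("AAAA", k = 1))
#' exp(m$log_transition[kmer_index("AA")]) # (3 + 1) / (3 + 4) = 4/7
#' @export
estimate_transitions <- function(table, pseudocount = 1,
                                 mode = c("row", "prefix"),
                                 gc_bin = c(0, 1), label = NULL) {
  stopifnot(inherits(table, "kmer_counts"))
  mode <- match.arg(mode)
  if (length(pseudocount) != 1L || is.na(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be a single value > 0 (zero-count contexts would give log 0)")
  }
  k <- table$k
  num <- log(table$counts + pseudocount)
  den <- if (mode == "row") {
    rs <- rowSums(matrix(table$counts, ncol = 4L, byrow = TRUE))
    log(rs + 4 * pseudocount)
  } else {
    log(table$context_counts + 4 * pseudocount)
  }
  structure(
    list(
      k = k,
      log_transition = num - rep(den, each = 4L),
      pseudocount = pseudocount,
      mode = mode,
      gc_bin = as.numeric(gc_bin),
      training = list(label = label, n_sequences = table$n_sequences)
    ),
    class = "markov_model"
  )
}

#' Mean log-likelihood of sequences under a Markov model
#'
#' For a sequence `y` of length `N` and a model of order `k`, returns the mean
#' over all scoreable `(k+1)`-windows of `log P(y[i+k] | y[i..i+k-1])`
#' (natural log). Windows containing a non-ACGT character are skipped. A
#' sequence with no scoreable window (too short, or all windows ambiguous) is
#' unscoreable and yields `NA` rather than a misleading score.
#'
#' @param x Character vector of DNA sequences.
#' @param model A [estimate_transitions()] result.
#' @return Numeric vector of mean log-likelihoods (`<= 0`), `NA` where
#'   unscoreable.
#' @examples
#' m <- estimate_transitions(count_kmers("AAAA", k = 1))
#' log_likelihood("AAA", m) # log(4/7)
#' @export
log_likelihood <- function(x, model) {
  stopifnot(inherits(model, "markov_model"))
  k <- model$k
  lt <- model$log_transition
  vapply(as.character(x), function(s) {
    codes <- seq_codes(toupper(s))
    if (length(codes) < k + 1L) return(NA_real_)
    v <- lt[cpp_window_index(codes, k)]
    n <- sum(!is.na(v))
    if (n == 0L) NA_real_ else sum(v, na.rm = TRUE) / n
  }, numeric(1), USE.NAMES = FALSE)
}

# per-sequence (sum of window log-probs, number of windows) for a list of
# models sharing one order; the window indices are computed once per sequence.
# Returns list(sums = n x n_models matrix, nwin = length-n vector).
ll_components <- function(seqs, models, k) {
  nm <- length(models)
  res <- vapply(as.character(seqs), function(s) {
    codes <- seq_codes(toupper(s))
    if (length(codes) < k + 1L) return(c(rep(NA_real_, nm), 0))
    idx <- cpp_window_index(codes, k)
    idx <- idx[!is.na(idx)]
    n <- length(idx)
    if (n == 0L) return(c(rep(NA_real_, nm), 0))
    c(vapply(models, function(m) sum(m$log_transition[idx]), numeric(1)), n)
  }, numeric(nm + 1L), USE.NAMES = FALSE)
  res <- matrix(res, nrow = nm + 1L)
  list(sums = t(res[seq_len(nm), , drop = FALSE]), nwin = res[nm + 1L, ])
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf(
    "<markov_model> order k = %d, %s mode, pseudocount %g, GC bin [%.3f, %.3f]\n",
    x$k, x$mode, x$pseudocount, x$gc_bin[1], x$gc_bin[2]
  ))
  invisible(x)
}

#' Tidy a Markov model into a context/base/probability table
#'
#' @param x A `markov_model`.
#' @param ... Unused.
#' @return A tibble with columns `context`, `base`, `log_prob`, `prob`
#'   (one row per transition cell). Only sensible for small orders.
#' @export
tidy.markov_model <- function(x, ...) {
  if (x$k > 6) abort("tidy() on a markov_model is only supported for k <= 6")
  ctx <- kmer_strings(x$k)
  tibble(
    context = rep(ctx, each = 4L),
    base = rep(.BASES, times = length(ctx)),
    log_prob = x$log_transition,
    prob = exp(x$log_transition)
  )
}
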