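#' Synthetic benchmark sweep over Markov orders and fragment lengths
#'
#' Runs the full train/score/evaluate pipeline on synthetic genomes: two
#' Markov generators (a viral-like and a host-like chain, distinguished by GC
#' content and context structure) provide training genomes and fresh test
#' fragments; a classifier is trained per Markov order and evaluated at each
#' fragment length, reporting AUROC with a stratified bootstrap standard
#' error. A grid cell with `length <= order` cannot be scored and is skipped
#' with a warning.
#'
#' @param orders Classifier Markov orders to sweep.
#' @param lengths Test fragment lengths (bp) to sweep.
#' @param bins GC-quantile bins per class (default 2 — synthetic corpora are
#'   narrow in GC).
#' @param gc Length-2 vector: target GC of the viral-like and host-like
#'   generators.
#' @param generator_order Order of the generating chains (default 2).
#' @param train_bp Training bases per class (default 200000, split over
#'   `2 * bins` genomes).
#' @param n_test Test fragments per class per length (default 500).
#' @param n_bootstrap Bootstrap resamples for the SE (default 30).
#' @param pseudocount,mode Passed to [build_classifier()].
#' @param seed Integer seed controlling generators, fragments, and
#'   bootstrap; fixed seeds give identical reports.
#' @return A tibble of class `markovir_benchmark` with one row per grid
#'   cell: `order`, `length`, `auc`, `bootstrap_se`, `n_pos`, `n_neg`.
#' @export
benchmark_grid <- function(orders = c(2, 4), lengths = c(200, 500, 1000),
                           bins = 2, gc = c(0.4, 0.6), generator_order = 2,
                           train_bp = 2e5, n_test = 500, n_bootstrap = 30,
                           pseudocount = 1, mode = "row", seed = 1) {
  gen_v <- markov_generator(generator_order, gc = gc[1], seed = seed + 101L)
  gen_h <- markov_generator(generator_order, gc = gc[2], seed = seed + 202L)
  n_genomes <- max(2L * as.integer(bins), 4L)
  glen <- ceiling(train_bp / n_genomes)
  make_corpus <- function(gen, tag, off) {
    tibble(
      genome_id = sprintf("%s%02d", tag, seq_len(n_genomes)),
      sequence = vapply(seq_len(n_genomes), function(i) {
        synthesize_genome(gen, glen, seed = seed + off + i)
      }, character(1))
    )
  }
  virus_train <- make_corpus(gen_v, "virus", 1000L)
  host_train <- make_corpus(gen_h, "host", 2000L)
  rows <- list()
  for (k in orders) {
    feasible <- lengths[lengths > k]
    for (L in setdiff(lengths, feasible)) {
      warn(sprintf("skipping infeasible grid cell: length %d <= order %d", L, k))
    }
    if (length(feasible) == 0L) next
    clf <- build_classifier(virus_train, host_train, k = k, bins = bins,
                            pseudocount = pseudocount, mode = mode)
    for (L in feasible) {
      test <- benchmark_test_fragments(gen_v, gen_h, L, n_test,
                                       seed = seed + 31L * k + L)
      sc <- score_sequences(test, clf)
      lab <- as.integer(test$label == "virus")
      roc <- auroc(sc$lambda, lab)
      se <- bootstrap_auc_se(sc$lambda, lab, n_bootstrap = n_bootstrap,
                             seed = seed + 7L * k + L)
      rows[[length(rows) + 1L]] <- tibble(
        order = k, length = L, auc = roc$auc, bootstrap_se = se,
        n_pos = roc$n_pos, n_neg = roc$n_neg
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("markovir_benchmark", class(out))
  out
}

# n fresh fragments of length L per class, drawn from freshly synthesized
# genomes of each generator
benchmark_test_fragments <- function(gen_v, gen_h, L, n, seed) {
  one <- function(gen, lab, s) {
    g <- synthesize_genome(gen, n * L, seed = s)
    fr <- fragment_genomes(tibble(genome_id = paste0(lab, "_test"),
                                  sequence = g, label = lab), L)
    fr[seq_len(n), ]
  }
  dplyr::bind_rows(one(gen_v, "virus", seed), one(gen_h, "host", seed + 1L))
}

#' @rdname benchmark_grid
#' @param object A `markovir_benchmark` table.
#' @param ... Unused.
#' @export
autoplot.markovir_benchmark <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$length), y = .data$auc,
                                       colour = factor(.data$order),
                                       group = factor(.data$order))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$auc - .data$bootstrap_se,
      ymax = .data$auc + .data$bootstrap_se
    )) +
    ggplot2::labs(x = "Fragment length (bp)", y = "AUROC",
                  colour = "Markov order")
}
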