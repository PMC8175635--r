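#' GC-quantile bin assignment
#'
#' Partitions genomes into `bins` groups using the empirical quantiles of
#' their GC fractions: interior edges sit at the `j/bins` quantiles
#' (`j = 1, ..., bins - 1`), and the outer edges are widened to 0 and 1. A
#' value falling exactly on an interior edge goes to the lower bin
#' (deterministic tie rule).
#'
#' @param gc Numeric vector of GC fractions in `[0, 1]`, one per genome.
#' @param bins Number of bins `M >= 1`.
#' @return Integer vector of bin assignments (1-based) with attribute
#'   `edges`, the `bins + 1` bin boundaries.
#' @examples
#' assign_gc_bins(c(0.30, 0.40, 0.50, 0.60), bins = 2)
#' @export
assign_gc_bins <- function(gc, bins) {
  if (length(bins) != 1L || bins < 1 || bins != as.integer(bins)) {
    abort("`bins` must be a single integer >= 1")
  }
  bins <- as.integer(bins)
  if (length(gc) < bins) abort("need at least as many genomes as bins")
  if (any(is.na(gc)) || any(gc < 0 | gc > 1)) abort("`gc` must lie in [0, 1]")
  if (length(unique(gc)) < bins) {
    abort(sprintf(
      "only %d distinct GC values for %d bins; use a smaller `bins`",
      length(unique(gc)), bins
    ))
  }
  interior <- if (bins > 1L) {
    unname(quantile(gc, probs = seq_len(bins - 1L) / bins))
  } else {
    numeric(0)
  }
  edges <- c(0, interior, 1)
  # exact-edge values fall to the lower bin: intervals (e_j, e_{j+1}]
  assignment <- findInterval(gc, interior, left.open = TRUE) + 1L
  occ <- tabulate(assignment, nbins = bins)
  if (any(occ == 0L)) {
    abort(sprintf(
      "bin(s) %s are empty after quantile assignment (heavily tied GC values); use a smaller `bins`",
      paste(which(occ == 0L), collapse = ", ")
    ))
  }
  structure(assignment, edges = edges)
}

# coerce genome input (tibble with genome_id/sequence, named or unnamed
# character vector) to a tibble(genome_id, sequence); multi-record genomes
# are rows sharing a genome_id.
as_genome_tbl <- function(x, arg = "genomes") {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("genome_", seq_along(x))
    return(tibble(genome_id = ids, sequence = unname(x)))
  }
  if (is.data.frame(x)) {
    if (!all(c("genome_id", "sequence") %in% names(x))) {
      abort(sprintf("`%s` must have columns `genome_id` and `sequence`", arg))
    }
    return(as_tibble(x)[, c("genome_id", "sequence")])
  }
  abort(sprintf("`%s` must be a data frame or character vector", arg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a GC-binned ensemble of Markov models for one sequence class
#'
#' Computes one GC fraction per genome (over the concatenation of its
#' records), assigns genomes to GC-quantile bins, and trains one Markov model
#' per bin on the pooled records of that bin's genomes. Counting respects
#' record boundaries: no window spans two records.
#'
#' @param genomes A tibble with columns `genome_id` and `sequence` (multiple
#'   rows with the same `genome_id` form a multi-record genome), or a
#'   (optionally named) character vector of sequences.
#' @param k Markov order.
#' @param bins Number of GC-quantile bins `M`.
#' @param pseudocount,mode Passed to [estimate_transitions()].
#' @param class_label Label recorded on the ensemble (e.g. `"virus"`).
#' @return An object of class `model_ensemble`: `class_label`, `models`
#'   (list of `bins` [estimate_transitions()] models), `bin_edges`, `bins`,
#'   `k`, and `genome_bins` (tibble of per-genome GC and bin).
#' @export
train_ensemble <- function(genomes, k, bins = 4, pseudocount = 1,
                           mode = c("row", "prefix"),
                           class_label = "class") {
  mode <- match.arg(mode)
  tbl <- as_genome_tbl(genomes)
  per_genome <- tbl |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      gc = gc_content(paste0(.data$sequence, collapse = "")),
      .groups = "drop"
    )
  assignment <- assign_gc_bins(per_genome$gc, bins)
  edges <- attr(assignment, "edges")
  per_genome$bin <- as.integer(assignment)
  tbl <- dplyr::left_join(tbl, per_genome, by = "genome_id")
  models <- lapply(seq_len(as.integer(bins)), function(b) {
    seqs <- tbl$sequence[tbl$bin == b]
    estimate_transitions(
      count_kmers(seqs, k),
      pseudocount = pseudocount, mode = mode,
      gc_bin = c(edges[b], edges[b + 1L]),
      label = sprintf("%s/bin%d", class_label, b)
    )
  })
  structure(
    list(
      class_label = class_label,
      models = models,
      bin_edges = edges,
      bins = as.integer(bins),
      k = as.integer(k),
      genome_bins = per_genome
    ),
    class = "model_ensemble"
  )
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf(
    "<model_ensemble> %s: %d GC bin(s), order k = %d, %d genome(s)\n",
    x$class_label, x$bins, x$k, nrow(x$genome_bins)
  ))
  invisible(x)
}
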