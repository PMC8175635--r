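CLASSIFIER_FORMAT_VERSION <- "1.0"

#' Build a viral-vs-host Markov chain classifier
#'
#' Trains one GC-quantile-binned Markov model ensemble per class (each class
#' is binned by the quantiles of its own GC distribution) and, optionally,
#' stores an empirical null distribution of lambda scores computed from
#' held-out bacterial fragments, stratified by fragment length, for p-value
#' calibration.
#'
#' The defaults `k = 9` and `bins = 4` are the operating point used for
#' classification of real metagenomic contigs; smaller orders train reliably
#' on small corpora and are appropriate for the synthetic benchmarks.
#'
#' @param virus,host Training genomes per class: a tibble with `genome_id`
#'   and `sequence` columns, or a character vector of sequences.
#' @param k Markov order (default 9).
#' @param bins Number of GC-quantile bins per class (default 4).
#' @param pseudocount,mode Passed to [estimate_transitions()].
#' @param orientation `"decision"` (default) scores lambda as
#'   `ll_host / ll_virus`, so that `lambda > 1` exactly when the viral mean
#'   log-likelihood exceeds the host one (both are negative); `"literal"`
#'   scores the raw ratio `ll_virus / ll_host`, which inverts the decision
#'   rule on negative values. See the package vignette.
#' @param null_fragments Optional held-out bacterial fragments (tibble with
#'   `id`/`sequence`, or character vector) whose lambda scores form the
#'   empirical null.
#' @param null_stratify `"length"` (default) stores the null per
#'   powers-of-two length stratum, a query using its own stratum (nearest
#'   populated stratum as fallback); `"pooled"` stores a single pooled null.
#' @return An object of class `markov_classifier`.
#' @seealso [score_sequences()], [write_classifier()]
#' @export
build_classifier <- function(virus, host, k = 9, bins = 4, pseudocount = 1,
                             mode = c("row", "prefix"),
                             orientation = c("decision", "literal"),
                             null_fragments = NULL,
                             null_stratify = c("length", "pooled")) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  null_stratify <- match.arg(null_stratify)
  obj <- structure(
    list(
      virus = train_ensemble(virus, k = k, bins = bins,
                             pseudocount = pseudocount, mode = mode,
                             class_label = "virus"),
      host = train_ensemble(host, k = k, bins = bins,
                            pseudocount = pseudocount, mode = mode,
                            class_label = "host"),
      null_scores = NULL,
      k = as.integer(k),
      bins = as.integer(bins),
      pseudocount = pseudocount,
      mode = mode,
      orientation = orientation,
      format_version = CLASSIFIER_FORMAT_VERSION
    ),
    class = "markov_classifier"
  )
  if (!is.null(null_fragments)) {
    frags <- as_fragment_input(null_fragments)
    sc <- score_sequences(frags, obj)
    sc <- sc[sc$call != "unscoreable", ]
    if (nrow(sc) == 0L) abort("no scoreable null fragment")
    strata <- split(sc$lambda, floor(log2(sc$length)))
    obj$null_scores <- list(
      stratify = null_stratify,
      strata = lapply(strata, sort),
      pooled = sort(sc$lambda)
    )
  }
  obj
}

# coerce contig/fragment input to tibble(id, sequence)
as_fragment_input <- function(x, arg = "x") {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq_", seq_along(x))
    return(tibble(id = ids, sequence = unname(x)))
  }
  if (is.data.frame(x)) {
    nm <- names(x)
    id_col <- intersect(c("id", "fragment_id", "pair_id"), nm)[1]
    if (is.na(id_col) || !("sequence" %in% nm)) {
      abort(sprintf("`%s` must have an id column and a `sequence` column", arg))
    }
    return(tibble(id = as.character(x[[id_col]]), sequence = x$sequence))
  }
  abort(sprintf("`%s` must be a data frame or character vector", arg))
}

# null vector appropriate for a query length (NULL if no null stored)
null_for_length <- function(classifier, len) {
  ns <- classifier$null_scores
  if (is.null(ns)) return(NULL)
  if (ns$stratify == "pooled") return(ns$pooled)
  keys <- as.numeric(names(ns$strata))
  ns$strata[[which.min(abs(keys - floor(log2(len))))]]
}

#' Save / load a classifier
#'
#' The classifier is stored as a single versioned RDS container (config, bin
#' edges, dense log-probability arrays per model, null score vectors). A
#' reload reproduces scores exactly and the same inputs always produce a
#' byte-identical file.
#'
#' @param classifier A [build_classifier()] object.
#' @param path File path.
#' @return `write_classifier()` returns `path` invisibly; `read_classifier()`
#'   returns the classifier.
#' @export
write_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "markov_classifier"))
  saveRDS(classifier, path, version = 3L)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "markov_classifier")) {
    abort("file does not contain a markov_classifier model")
  }
  if (!identical(obj$format_version, CLASSIFIER_FORMAT_VERSION)) {
    abort(sprintf(
      "model format version %s not supported by this library version (expected %s); re-train the model",
      obj$format_version, CLASSIFIER_FORMAT_VERSION
    ))
  }
  obj
}

#' @export
print.markov_classifier <- function(x, ...) {
  cat(sprintf(
    "<markov_classifier> order k = %d, %d GC bin(s) per class, %s normalisation\n",
    x$k, x$bins, x$mode
  ))
  cat(sprintf("  virus: %d genome(s); host: %d genome(s)\n",
              nrow(x$virus$genome_bins), nrow(x$host$genome_bins)))
  if (is.null(x$null_scores)) {
    cat("  no null distribution (p-values unavailable)\n")
  } else {
    cat(sprintf("  null: %d fragment score(s), %s stratification\n",
                length(x$null_scores$pooled), x$null_scores$stratify))
  }
  invisible(x)
}

#' Glance at a classifier's configuration
#'
#' @param x A `markov_classifier`.
#' @param ... Unused.
#' @return One-row tibble of configuration and training-size metadata.
#' @export
glance.markov_classifier <- function(x, ...) {
  tibble(
    k = x$k,
    bins = x$bins,
    pseudocount = x$pseudocount,
    mode = x$mode,
    orientation = x$orientation,
    n_virus_genomes = nrow(x$virus$genome_bins),
    n_host_genomes = nrow(x$host$genome_bins),
    n_null_scores = if (is.null(x$null_scores)) 0L else length(x$null_scores$pooled),
    format_version = x$format_version
  )
}

#' Tidy a classifier into one row per GC bin and class
#'
#' @param x A `markov_classifier`.
#' @param ... Unused.
#' @return Tibble with `class`, `bin`, `gc_low`, `gc_high`, `n_genomes`.
#' @export
tidy.markov_classifier <- function(x, ...) {
  one <- function(ens) {
    tibble(
      class = ens$class_label,
      bin = seq_len(ens$bins),
      gc_low = ens$bin_edges[-length(ens$bin_edges)],
      gc_high = ens$bin_edges[-1],
      n_genomes = as.integer(tabulate(ens$genome_bins$bin, nbins = ens$bins))
    )
  }
  dplyr::bind_rows(one(x$virus), one(x$host))
}
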