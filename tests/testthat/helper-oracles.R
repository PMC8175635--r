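# Independent oracles and fixture builders used across the suite.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# character-by-character reverse complement, independent of the package path
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(s), "")[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

# naive mean log-likelihood: explicit per-position window loop, own indexing
oracle_ll <- function(seq, model) {
  k <- model$k
  s <- toupper(seq)
  n <- nchar(s)
  terms <- numeric(0)
  if (n >= k + 1) {
    for (i in seq_len(n - k)) {
      word <- strsplit(substr(s, i, i + k), "")[[1]]
      codes <- match(word, c("A", "C", "G", "T")) - 1L
      if (anyNA(codes)) next
      idx <- 0L
      for (c in codes) idx <- idx * 4L + c
      terms <- c(terms, model$log_transition[idx + 1L])
    }
  }
  if (length(terms) == 0L) NA_real_ else mean(terms)
}

# small two-chain classifier fixture: viral-like (low GC) vs host-like chain
make_test_classifier <- function(k = 2, bins = 2, genome_bp = 20000,
                                 n_genomes = 4, gc = c(0.35, 0.65),
                                 seed = 42, ...) {
  gen_v <- markov_generator(2, gc = gc[1], seed = seed)
  gen_h <- markov_generator(2, gc = gc[2], seed = seed + 1L)
  vir <- tibble::tibble(
    genome_id = paste0("v", seq_len(n_genomes)),
    sequence = vapply(seq_len(n_genomes), function(i) {
      synthesize_genome(gen_v, genome_bp, seed = seed + 10L + i)
    }, character(1))
  )
  hos <- tibble::tibble(
    genome_id = paste0("h", seq_len(n_genomes)),
    sequence = vapply(seq_len(n_genomes), function(i) {
      synthesize_genome(gen_h, genome_bp, seed = seed + 20L + i)
    }, character(1))
  )
  list(
    classifier = build_classifier(vir, hos, k = k, bins = bins, ...),
    gen_v = gen_v, gen_h = gen_h, virus = vir, host = hos
  )
}

# closed-form AUROC standard error (Hanley & McNeil 1982)
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}
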