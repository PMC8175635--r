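#' Strand-symmetric k-mer counting
#'
#' Counts every overlapping `(k+1)`-mer and `k`-mer window over a set of
#' sequences, adding each occurrence to both the word and its reverse
#' complement, so that `N(w) == N(revcomp(w))` by construction (a palindromic
#' word is therefore incremented twice per occurrence). Windows containing any
#' non-ACGT character are skipped and tallied. Windows never span sequence
#' (record) boundaries.
#'
#' @param sequences Character vector of DNA sequences (case-insensitive).
#' @param k Markov order (integer >= 0): transition words have length `k + 1`,
#'   context words length `k`.
#' @return An object of class `kmer_counts`: a list with `k`, `counts`
#'   (numeric vector of length `4^(k+1)` in lexicographic word order),
#'   `context_counts` (length `4^k`; for `k = 0` a single total),
#'   `n_sequences`, and `n_skipped_windows` (ambiguous `(k+1)`-windows).
#' @seealso [kmer_count()] to look counts up by word, [estimate_transitions()].
#' @examples
#' ct <- count_kmers("ACGT", k = 1)
#' kmer_count(ct, c("AC", "CG", "GT"))
#' @export
count_kmers <- function(sequences, k) {
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) abort("`sequences` is empty")
  if (length(k) != 1L || is.na(k) || k < 0 || k != as.integer(k)) {
    abort("`k` must be a single non-negative integer")
  }
  k <- as.integer(k)
  seqs <- toupper(sequences)
  lens <- nchar(seqs)
  n_windows <- sum(pmax(lens - k, 0L))
  if (n_windows == 0L) {
    abort("no trainable windows: all sequences are shorter than k + 1")
  }
  dss <- Biostrings::DNAStringSet(seqs)
  raw <- Biostrings::oligonucleotideFrequency(dss, width = k + 1L,
                                              simplify.as = "collapsed")
  raw <- as.numeric(raw)
  counts <- raw + raw[revcomp_perm(k + 1L)]
  if (k == 0L) {
    context_counts <- sum(counts)
  } else {
    ctx_raw <- as.numeric(Biostrings::oligonucleotideFrequency(
      dss, width = k, simplify.as = "collapsed"))
    context_counts <- ctx_raw + ctx_raw[revcomp_perm(k)]
  }
  structure(
    list(
      k = k,
      counts = counts,
      context_counts = context_counts,
      n_sequences = length(seqs),
      n_skipped_windows = as.integer(n_windows - sum(raw))
    ),
    class = "kmer_counts"
  )
}

#' Look up strand-symmetric counts by word
#'
#' @param x A [count_kmers()] result.
#' @param words Character vector of words of length `k + 1` (transition words)
#'   or `k` (context words).
#' @return Named numeric vector of counts.
#' @export
kmer_count <- function(x, words) {
  stopifnot(inherits(x, "kmer_counts"))
  len <- unique(nchar(words))
  if (length(len) != 1L) abort("all `words` must have the same length")
  vec <- if (len == x$k + 1L) {
    x$counts
  } else if (len == x$k) {
    x$context_counts
  } else {
    abort(sprintf("words must have length %d or %d", x$k, x$k + 1L))
  }
  setNames(vec[kmer_index(toupper(words))], words)
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf(
    "<kmer_counts> order k = %d: %s distinct (k+1)-mers, %d sequence(s), %d ambiguous window(s) skipped\n",
    x$k, format(sum(x$counts > 0)), x$n_sequences, x$n_skipped_windows
  ))
  invisible(x)
}
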