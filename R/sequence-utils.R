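#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complementation over character vectors. In strict mode
#' (the default) any character outside `A/C/G/T` (either case) is an error;
#' in lenient mode the IUPAC ambiguity codes (`RYSWKMBDHVN`) are mapped to `N`
#' before complementing, and anything else is still rejected.
#'
#' @param x Character vector of DNA sequences.
#' @param strict If `TRUE`, reject any non-ACGT character; if `FALSE`, map
#'   IUPAC ambiguity codes to `N`.
#' @return Character vector of uppercase reverse complements. Applying the
#'   function twice returns `toupper(x)`.
#' @examples
#' reverse_complement(c("ACGT", "AAAC"))
#' @export
reverse_complement <- function(x, strict = TRUE) {
  if (!is.character(x)) abort("`x` must be a character vector")
  up <- toupper(x)
  if (strict) {
    bad <- grepl("[^ACGT]", up)
    if (any(bad)) {
      abort(sprintf(
        "non-ACGT character in sequence %d; use `strict = FALSE` to map IUPAC ambiguity codes to N",
        which(bad)[1]
      ))
    }
  } else {
    up <- chartr("RYSWKMBDHV", "NNNNNNNNNN", up)
    bad <- grepl("[^ACGTN]", up)
    if (any(bad)) {
      abort(sprintf("character outside the IUPAC DNA alphabet in sequence %d", which(bad)[1]))
    }
  }
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(comp, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of DNA sequences
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T), ignoring any other characters
#' (ambiguity codes do not enter the denominator).
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gc_content(c("GCGC", "ACGT", "AANT"))
#' @export
gc_content <- function(x) {
  if (!is.character(x)) abort("`x` must be a character vector")
  up <- toupper(x)
  n_gc <- nchar(gsub("[^GC]", "", up))
  n_at <- nchar(gsub("[^AT]", "", up))
  denom <- n_gc + n_at
  if (any(denom == 0L)) {
    abort(sprintf("sequence %d has no A/C/G/T characters", which(denom == 0L)[1]))
  }
  n_gc / denom
}
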