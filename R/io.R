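#' Read and write FASTA files
#'
#' Reading accepts plain or gzip-compressed, single- or multi-line FASTA
#' (compression is detected from the file content, not the extension) and
#' returns a tibble; the id is the first whitespace-delimited token of the
#' header. Writing compresses when the path ends in `.gz`.
#'
#' @param path File path.
#' @return `read_fasta()`: tibble with `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  dss <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(dss)),
         sequence = unname(as.character(dss)))
}

#' @rdname read_fasta
#' @param x Tibble with an id column (`id`, `fragment_id`, or `genome_id`)
#'   and `sequence`.
#' @export
write_fasta <- function(x, path) {
  id_col <- intersect(c("id", "fragment_id", "genome_id"), names(x))[1]
  if (is.na(id_col) || !"sequence" %in% names(x)) {
    abort("`x` must have an id column and a `sequence` column")
  }
  dss <- Biostrings::DNAStringSet(setNames(x$sequence, x[[id_col]]))
  Biostrings::writeXStringSet(dss, path, compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read and write FASTQ files
#'
#' Strict 4-line-per-record FASTQ, plain or gzipped (reading auto-detects
#' compression; writing compresses for `.gz` paths). Missing qualities on
#' write are filled with `I` (Phred 40).
#'
#' @param path File path.
#' @return `read_fastq()`: tibble with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  # Biostrings warns about dropping its own metadata columns here; benign
  q <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    id = sub("\\s.*$", "", names(q)),
    sequence = unname(as.character(q)),
    quality = unname(as.character(Biostrings::quality(q)))
  )
}

#' @rdname read_fastq
#' @param x Tibble with `id` and `sequence` (and optionally `quality`).
#' @export
write_fastq <- function(x, path) {
  if (!all(c("id", "sequence") %in% names(x))) {
    abort("`x` must have `id` and `sequence` columns")
  }
  qual <- if ("quality" %in% names(x)) {
    x$quality
  } else {
    strrep("I", nchar(x$sequence))
  }
  lines <- as.vector(rbind(paste0("@", x$id), x$sequence, "+", qual))
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read synchronized paired-end FASTQ files
#'
#' Mate files must list the same read ids in the same order (a trailing
#' `/1` / `/2` or ` 1:...` / ` 2:...` suffix is stripped before comparison);
#' the first desynchronized record is reported by name.
#'
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return Tibble with `pair_id`, `mate1`, `mate2`, `quality1`, `quality2`.
#' @export
read_paired_fastq <- function(r1, r2) {
  a <- read_fastq(r1)
  b <- read_fastq(r2)
  if (nrow(a) != nrow(b)) {
    abort(sprintf("mate files differ in record count (%d vs %d)", nrow(a), nrow(b)))
  }
  ida <- sub("/[12]$", "", a$id)
  idb <- sub("/[12]$", "", b$id)
  bad <- which(ida != idb)
  if (length(bad) > 0L) {
    abort(sprintf("desynchronized mates at record %d: %s vs %s",
                  bad[1], a$id[bad[1]], b$id[bad[1]]))
  }
  tibble(pair_id = ida, mate1 = a$sequence, mate2 = b$sequence,
         quality1 = a$quality, quality2 = b$quality)
}

#' @rdname read_paired_fastq
#' @param pairs Tibble with `pair_id`, `mate1`, `mate2` (and optionally
#'   `quality1`, `quality2`).
#' @export
write_paired_fastq <- function(pairs, r1, r2) {
  q1 <- if ("quality1" %in% names(pairs)) pairs$quality1 else NULL
  q2 <- if ("quality2" %in% names(pairs)) pairs$quality2 else NULL
  m1 <- tibble(id = paste0(pairs$pair_id, "/1"), sequence = pairs$mate1)
  m2 <- tibble(id = paste0(pairs$pair_id, "/2"), sequence = pairs$mate2)
  if (!is.null(q1)) m1$quality <- q1
  if (!is.null(q2)) m2$quality <- q2
  write_fastq(m1, r1)
  write_fastq(m2, r2)
  invisible(c(r1, r2))
}
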