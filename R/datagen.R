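#' Split genome records into non-overlapping fixed-length fragments
#'
#' Each record is cut into consecutive, non-overlapping windows of exactly
#' `fragment_length` bp; the trailing remainder is discarded (a record
#' shorter than `fragment_length` yields no fragment). Fragment ids encode
#' the source record and the 0-based, half-open coordinate of the window.
#'
#' @param genomes Tibble with columns `genome_id`, `sequence`, and optionally
#'   `label` (carried onto fragments), or a named character vector.
#' @param fragment_length Fragment length `L` in bp (>= 1).
#' @param label Default label when `genomes` has no `label` column.
#' @return A tibble with `fragment_id`, `sequence`, `label`, `source_genome`,
#'   `offset` (0-based), plus attribute `discarded_bp` (total trailing bases
#'   dropped).
#' @examples
#' fragment_genomes(c(g = strrep("ACGT", 300)), fragment_length = 200)
#' @export
fragment_genomes <- function(genomes, fragment_length, label = NA_character_) {
  if (fragment_length < 1) abort("`fragment_length` must be >= 1")
  L <- as.integer(fragment_length)
  tbl <- if (is.data.frame(genomes)) {
    as_tibble(genomes)
  } else {
    as_genome_tbl(genomes)
  }
  if (!"label" %in% names(tbl)) tbl$label <- label
  discarded <- 0L
  out <- purrr::pmap(
    list(tbl$genome_id, tbl$sequence, tbl$label),
    function(id, seq, lab) {
      n <- nchar(seq) %/% L
      discarded <<- discarded + (nchar(seq) - n * L)
      if (n == 0L) return(NULL)
      starts <- (seq_len(n) - 1L) * L + 1L
      tibble(
        fragment_id = sprintf("%s:%d-%d", id, starts - 1L, starts - 1L + L),
        sequence = substring(seq, starts, starts + L - 1L),
        label = lab,
        source_genome = id,
        offset = starts - 1L
      )
    }
  )
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(fragment_id = character(), sequence = character(),
                  label = character(), source_genome = character(),
                  offset = integer())
  }
  attr(res, "discarded_bp") <- discarded
  res
}

#' Number of host fragments needed for a target viral fraction
#'
#' Given `V` viral fragments and a target viral fraction `f`, the host draw
#' is `ceiling(V * (1 - f) / f)`: nine times more host fragments for a 10%
#' viral mixture, equal numbers at 50%, and `ceiling(V / 9)` at 90%.
#'
#' @param n_viral Number of viral fragments `V`.
#' @param viral_fraction Target viral fraction in `(0, 1)`.
#' @return Integer host fragment count.
#' @examples
#' mixture_host_count(266204, 0.10) # 9 * V
#' mixture_host_count(17345, 0.90)  # ceiling(V / 9)
#' @export
mixture_host_count <- function(n_viral, viral_fraction) {
  if (any(viral_fraction <= 0 | viral_fraction >= 1)) {
    abort("`viral_fraction` must lie in (0, 1)")
  }
  # 1e-6 guard: float error in the exact-ratio cases (9V, V, V/9) is < 1e-8
  # here, while true fractional parts are multiples of 1/9 and cannot be
  # flipped by it
  as.integer(ceiling(n_viral * (1 - viral_fraction) / viral_fraction - 1e-6))
}

#' Mix viral fragments with subsampled host fragments
#'
#' Keeps all viral fragments and draws host fragments uniformly without
#' replacement so that the viral fraction of the result matches
#' `viral_fraction` to within one fragment (ceiling rule, see
#' [mixture_host_count()]). Deterministic given `seed`.
#'
#' @param viral,host_pool Fragment tibbles as from [fragment_genomes()].
#' @param viral_fraction Target viral fraction in `(0, 1)`.
#' @param seed Optional integer seed for the host subsample.
#' @return A fragment tibble (viral rows first, then the host draw).
#' @export
build_mixture <- function(viral, host_pool, viral_fraction, seed = NULL) {
  n_host <- mixture_host_count(nrow(viral), viral_fraction)
  if (nrow(host_pool) < n_host) {
    abort(sprintf(
      "host pool too small: need %d host fragments for viral_fraction = %g but only %d available",
      n_host, viral_fraction, nrow(host_pool)
    ))
  }
  idx <- with_seed(seed, sample.int(nrow(host_pool), n_host))
  dplyr::bind_rows(as_tibble(viral), as_tibble(host_pool)[idx, ])
}

#' Markov genome generator specification
#'
#' `generator_spec()` wraps an explicit `4^order x 4` transition matrix (rows
#' must sum to 1) and an initial context distribution. `markov_generator()`
#' builds a randomized spec with a target GC content: each context's
#' transition row starts from the base composition implied by `gc` and is
#' perturbed by independent log-normal noise of scale `wobble`, giving the
#' chain context-specific structure (distinct rows) around the requested GC.
#'
#' @param transition Numeric `4^order x 4` matrix of transition
#'   probabilities; rows must sum to 1 within 1e-12.
#' @param order Markov order of the generator.
#' @param initial Initial distribution over the `4^order` starting contexts
#'   (default uniform).
#' @return An object of class `generator_spec` (`order`, `transition`,
#'   `initial`, `target_gc`).
#' @export
generator_spec <- function(transition, order = NULL, initial = NULL) {
  transition <- as.matrix(transition)
  if (ncol(transition) != 4L) abort("`transition` must have 4 columns")
  k <- round(log(nrow(transition), 4))
  if (4^k != nrow(transition)) abort("`transition` must have 4^order rows")
  if (!is.null(order) && order != k) {
    abort("`order` does not match the number of transition rows")
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12)) {
    abort("transition rows must be non-negative and sum to 1 (within 1e-12)")
  }
  initial <- initial %||% rep(1 / nrow(transition), nrow(transition))
  if (length(initial) != nrow(transition) || abs(sum(initial) - 1) > 1e-9) {
    abort("`initial` must be a probability vector over the 4^order contexts")
  }
  structure(
    list(order = as.integer(k), transition = unname(transition),
         initial = as.numeric(initial),
         target_gc = sum(colMeans(transition)[c(2, 3)])),
    class = "generator_spec"
  )
}

#' @rdname generator_spec
#' @param gc Target GC fraction of the generated chain.
#' @param wobble Log-normal perturbation scale for per-context rows
#'   (0 = every context identical, i.e. an i.i.d. base model).
#' @param seed Optional seed making the spec reproducible.
#' @export
markov_generator <- function(order = 2, gc = 0.5, wobble = 0.15, seed = NULL) {
  base <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  n <- 4^order
  trans <- with_seed(seed, {
    noise <- matrix(exp(rnorm(4L * n, sd = wobble)), nrow = n)
    m <- sweep(noise, 2L, base, `*`)
    m / rowSums(m)
  })
  generator_spec(trans, order = order)
}

#' Synthesize a genome from a Markov generator
#'
#' Draws the initial context from the spec's initial distribution and then
#' successive bases from the transition rows. Reproducible under `seed`.
#'
#' @param spec A [generator_spec()] / [markov_generator()] object.
#' @param length Sequence length in bp (>= `order + 1`).
#' @param seed Optional integer seed.
#' @return A DNA string of the requested length.
#' @export
synthesize_genome <- function(spec, length, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (length < spec$order + 1) abort("`length` must be at least order + 1")
  cum <- t(apply(spec$transition, 1L, cumsum))
  cum <- matrix(cum, nrow = nrow(spec$transition)) # order-0: keep matrix shape
  codes <- with_seed(seed, {
    cpp_simulate_markov(as.integer(length), spec$order, cum,
                        cumsum(spec$initial))
  })
  codes_to_seq(codes)
}

#' Simulate error-free paired-end reads from labelled genomes
#'
#' Fragments of `insert_size` bp are drawn uniformly over the pooled genome
#' positions; mate 1 is the leading-strand prefix of the fragment and mate 2
#' the reverse complement of its suffix. The truth label travels in the
#' output table (and into read ids when written as FASTQ). An optional
#' uniform substitution rate can inject sequencing errors.
#'
#' @param genomes Tibble with `genome_id`, `sequence`, and optionally
#'   `label`, or a named character vector.
#' @param n_pairs Number of read pairs.
#' @param read_length Mate length in bp (default 150).
#' @param insert_size Outer fragment length in bp (default 300); every
#'   genome must satisfy `length >= insert_size >= 2 * read_length`.
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Optional integer seed.
#' @return Tibble with `pair_id`, `mate1`, `mate2`, `label`,
#'   `source_genome`, `offset` (0-based fragment start).
#' @export
simulate_read_pairs <- function(genomes, n_pairs, read_length = 150,
                                insert_size = 300, error_rate = 0,
                                seed = NULL) {
  tbl <- if (is.data.frame(genomes)) as_tibble(genomes) else as_genome_tbl(genomes)
  if (!"label" %in% names(tbl)) tbl$label <- NA_character_
  glen <- nchar(tbl$sequence)
  if (insert_size < 2 * read_length) {
    abort("`insert_size` must be at least 2 * read_length")
  }
  if (any(glen < insert_size)) {
    abort("every genome must be at least `insert_size` long")
  }
  with_seed(seed, {
    npos <- glen - insert_size + 1L
    g <- sample.int(nrow(tbl), n_pairs, replace = TRUE, prob = npos)
    pos <- floor(runif(n_pairs) * npos[g]) + 1L
    frag_seq <- substring(tbl$sequence[g], pos, pos + insert_size - 1L)
    mate1 <- substring(frag_seq, 1L, read_length)
    mate2 <- reverse_complement(
      substring(frag_seq, insert_size - read_length + 1L, insert_size),
      strict = FALSE
    )
    if (error_rate > 0) {
      mate1 <- add_substitutions(mate1, error_rate)
      mate2 <- add_substitutions(mate2, error_rate)
    }
    tibble(
      pair_id = sprintf("pair%06d|%s|%s:%d", seq_len(n_pairs),
                        ifelse(is.na(tbl$label[g]), "unlabelled", tbl$label[g]),
                        tbl$genome_id[g], pos - 1L),
      mate1 = mate1,
      mate2 = mate2,
      label = tbl$label[g],
      source_genome = tbl$genome_id[g],
      offset = pos - 1L
    )
  })
}

add_substitutions <- function(reads, rate) {
  vapply(reads, function(s) {
    codes <- seq_codes(s)
    hit <- which(runif(length(codes)) < rate & !is.na(codes))
    if (length(hit) > 0L) {
      codes[hit] <- (codes[hit] + sample(1:3, length(hit), replace = TRUE)) %% 4L
    }
    out <- codes_to_seq(codes[!is.na(codes)])
    if (anyNA(codes)) s else out # leave reads with ambiguity codes untouched
  }, character(1), USE.NAMES = FALSE)
}
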