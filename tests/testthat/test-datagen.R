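test_that("fragmentation yields non-overlapping L-bp windows, remainder dropped", {
  g <- tibble::tibble(genome_id = "g1", sequence = rand_dna(1050),
                      label = "virus")
  fr <- fragment_genomes(g, fragment_length = 200)
  expect_equal(nrow(fr), 5L)
  expect_equal(fr$offset, seq(0L, 800L, by = 200L))
  expect_true(all(nchar(fr$sequence) == 200L))
  expect_equal(attr(fr, "discarded_bp"), 50L)
  # concatenating the fragments reproduces a prefix of the source
  expect_equal(paste(fr$sequence, collapse = ""), substr(g$sequence, 1, 1000))

  short <- fragment_genomes(tibble::tibble(genome_id = "s", sequence = rand_dna(199)), 200)
  expect_equal(nrow(short), 0L)

  set.seed(14)
  lens <- sample(50:900, 6)
  multi <- tibble::tibble(genome_id = paste0("g", 1:6),
                          sequence = vapply(lens, rand_dna, character(1)))
  fr2 <- fragment_genomes(multi, 100)
  expect_equal(nrow(fr2), sum(lens %/% 100))
})

test_that("mixture host counts follow the ceiling rule at every fraction", {
  expect_equal(mixture_host_count(10, 0.50), 10L)
  expect_equal(mixture_host_count(100, 0.10), 900L)
  expect_equal(mixture_host_count(100, 0.90), 12L) # ceiling(100/9)
  set.seed(2)
  for (i in 1:50) {
    v <- sample(1:5000, 1)
    f <- runif(1, 0.05, 0.95)
    h <- mixture_host_count(v, f)
    # realized fraction within one fragment of the request: the draw never
    # over-represents virus, and one host fragment fewer would
    expect_lte(v / (v + h), f + 1e-12)
    expect_gt(v / (v + h - 1), f - 1e-12)
  }
})

test_that("build_mixture keeps all viral fragments and subsamples hosts", {
  set.seed(6)
  viral <- fragment_genomes(tibble::tibble(genome_id = "v", sequence = rand_dna(2000),
                                           label = "virus"), 100)
  host <- fragment_genomes(tibble::tibble(genome_id = "h", sequence = rand_dna(25000),
                                          label = "host"), 100)
  mix <- build_mixture(viral, host, viral_fraction = 0.10, seed = 1)
  expect_equal(sum(mix$label == "virus"), nrow(viral))
  expect_equal(sum(mix$label == "host"), 9L * nrow(viral))
  expect_false(any(duplicated(mix$fragment_id))) # without replacement

  mix2 <- build_mixture(viral, host, viral_fraction = 0.10, seed = 1)
  expect_identical(mix, mix2) # seed-deterministic
  mix3 <- build_mixture(viral, host, viral_fraction = 0.10, seed = 2)
  expect_false(identical(mix$fragment_id, mix3$fragment_id))

  expect_error(build_mixture(viral, host[1:10, ], 0.10), "host pool too small")
})

test_that("synthesized genomes are seed-deterministic with the requested composition", {
  spec <- markov_generator(2, gc = 0.5, seed = 1)
  expect_identical(synthesize_genome(spec, 500, seed = 9),
                   synthesize_genome(spec, 500, seed = 9))
  expect_false(identical(synthesize_genome(spec, 500, seed = 9),
                         synthesize_genome(spec, 500, seed = 10)))

  # order-0 chain emitting only G/C
  gc_only <- generator_spec(matrix(c(0, 0.5, 0.5, 0), nrow = 1))
  expect_equal(gc_content(synthesize_genome(gc_only, 10000, seed = 3)), 1.0)

  # order-0 with GC 0.6: binomial concentration at length 10000 (+/- 3 sigma)
  soft <- generator_spec(matrix(c(0.2, 0.3, 0.3, 0.2), nrow = 1))
  gc <- gc_content(synthesize_genome(soft, 10000, seed = 4))
  expect_lt(abs(gc - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))

  expect_error(generator_spec(matrix(c(0.5, 0.5, 0.1, 0), nrow = 1)), "sum to 1")
})

test_that("empirical transition frequencies of a long sample match the generator", {
  spec <- markov_generator(2, gc = 0.45, wobble = 0.2, seed = 21)
  g <- synthesize_genome(spec, 1e6, seed = 22)
  # brute-force frequency count, unsymmetrized, via Biostrings
  f3 <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(g), width = 3)
  emp <- matrix(f3, ncol = 4, byrow = TRUE)
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - spec$transition)), 0.01)
})

test_that("simulated read pairs follow the insert geometry exactly", {
  g <- tibble::tibble(genome_id = "g", sequence = rand_dna(3000), label = "x")
  pairs <- simulate_read_pairs(g, 100, read_length = 150, insert_size = 300,
                               seed = 5)
  expect_equal(nrow(pairs), 100L)
  expect_true(all(pairs$label == "x"))
  for (i in c(1, 50, 100)) {
    frag <- substr(g$sequence, pairs$offset[i] + 1, pairs$offset[i] + 300)
    expect_equal(pairs$mate1[i], substr(frag, 1, 150))
    expect_equal(pairs$mate2[i], reverse_complement(substr(frag, 151, 300)))
  }
  # error-free mates are recovered at their recorded positions by exact search
  hit <- vapply(1:20, function(i) {
    as.integer(regexpr(pairs$mate1[i], g$sequence, fixed = TRUE))
  }, integer(1))
  expect_true(all(hit <= pairs$offset[1:20] + 1)) # first exact hit is at/before truth
  expect_true(all(vapply(1:20, function(i) {
    grepl(pairs$mate1[i], substr(g$sequence, pairs$offset[i] + 1,
                                 pairs$offset[i] + 150), fixed = TRUE)
  }, logical(1))))

  expect_error(simulate_read_pairs(g, 10, read_length = 150, insert_size = 250),
               "insert_size")
  expect_error(
    simulate_read_pairs(tibble::tibble(genome_id = "s", sequence = rand_dna(200)),
                        10, read_length = 100, insert_size = 250),
    "at least"
  )
  # substitution errors change bases at roughly the requested rate
  noisy <- simulate_read_pairs(g, 50, read_length = 150, insert_size = 300,
                               error_rate = 0.1, seed = 6)
  clean <- simulate_read_pairs(g, 50, read_length = 150, insert_size = 300,
                               seed = 6)
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, noisy$mate1, clean$mate1)
  expect_gt(mean(mism) / 150, 0.05)
  expect_lt(mean(mism) / 150, 0.15)
})
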