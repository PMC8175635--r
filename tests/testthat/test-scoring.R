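test_that("lambda is oriented so that lambda > 1 means viral-leaning", {
  # arithmetic under the documented orientation on negative mean LLs
  expect_equal(markovir:::lambda_from_ll(-1.30, -1.43, "decision"), 1.43 / 1.30)
  expect_gt(markovir:::lambda_from_ll(-1.30, -1.43, "decision"), 1)
  # the literal ratio inverts the rule on negative values
  expect_lt(markovir:::lambda_from_ll(-1.30, -1.43, "literal"), 1)
})

test_that("lambda is invariant to the logarithm base", {
  fx <- make_test_classifier(k = 2, bins = 2, genome_bp = 8000)
  clf <- fx$classifier
  clf2 <- clf
  for (cl in c("virus", "host")) {
    clf2[[cl]]$models <- lapply(clf2[[cl]]$models, function(m) {
      m$log_transition <- m$log_transition / log(2) # base-2 logs throughout
      m
    })
  }
  set.seed(8)
  contigs <- replicate(30, rand_dna(200))
  expect_equal(score_sequences(contigs, clf)$lambda,
               score_sequences(contigs, clf2)$lambda, tolerance = 1e-12)
})

test_that("viral-chain sequences score higher lambda than host-chain sequences", {
  fx <- make_test_classifier(k = 2, bins = 2, genome_bp = 20000)
  vir_frag <- vapply(1:80, function(i) synthesize_genome(fx$gen_v, 300, seed = 500 + i),
                     character(1))
  hos_frag <- vapply(1:80, function(i) synthesize_genome(fx$gen_h, 300, seed = 900 + i),
                     character(1))
  sv <- score_sequences(vir_frag, fx$classifier)
  sh <- score_sequences(hos_frag, fx$classifier)
  expect_gt(median(sv$lambda), median(sh$lambda))
  expect_gt(median(sv$lambda), 1)
  expect_lt(median(sh$lambda), 1)
})

test_that("empirical p-values count strictly greater null scores", {
  null <- c(0.9, 1.0, 1.1)
  expect_equal(empirical_pvalue(1.2, null), 0)
  expect_equal(empirical_pvalue(0.95, null), 2 / 3)
  expect_equal(empirical_pvalue(1.0, null), 1 / 3) # ties are not greater
  expect_equal(empirical_pvalue(0.95, null, smoothing = TRUE), 3 / 4)
  expect_error(empirical_pvalue(1, numeric(0)), "without null fragments")
})

test_that("p-values are monotone non-increasing in lambda within a stratum", {
  set.seed(12)
  null <- sort(rnorm(500, 1, 0.05))
  lam <- sort(runif(100, 0.8, 1.2))
  p <- empirical_pvalue(lam, null)
  expect_true(all(diff(p) <= 0))
})

test_that("q-values implement Benjamini-Hochberg with monotonicity", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(qvalues(rep(0.2, 5)), rep(0.2, 5))
  set.seed(4)
  p <- sort(runif(50))
  expect_true(all(diff(qvalues(p)) >= 0))
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_true(all(qvalues(p, method = "storey") <= qvalues(p)))
})

test_that("paired reads are scored over the union of both mates' windows", {
  fx <- make_test_classifier(k = 2, bins = 2, genome_bp = 8000)
  clf <- fx$classifier
  set.seed(19)
  m1 <- replicate(20, rand_dna(120))

  # duplicating one mate leaves the mean unchanged
  dup <- tibble::tibble(pair_id = paste0("p", 1:20), mate1 = m1, mate2 = m1)
  single <- score_sequences(m1, clf)
  expect_equal(score_read_pairs(dup, clf)$lambda, single$lambda)

  # an all-N mate contributes nothing
  degen <- tibble::tibble(pair_id = paste0("p", 1:20), mate1 = m1,
                          mate2 = strrep("N", 120))
  expect_equal(score_read_pairs(degen, clf)$lambda, single$lambda)

  # pooled-window oracle: concatenate the per-mate window term lists
  m2 <- replicate(20, rand_dna(80))
  pairs <- tibble::tibble(pair_id = paste0("p", 1:20), mate1 = m1, mate2 = m2)
  got <- score_read_pairs(pairs, clf)
  models <- c(clf$virus$models, clf$host$models)
  oracle <- vapply(1:20, function(i) {
    ll <- vapply(models, function(mdl) {
      n1 <- nchar(m1[i]) - mdl$k
      n2 <- nchar(m2[i]) - mdl$k
      (oracle_ll(m1[i], mdl) * n1 + oracle_ll(m2[i], mdl) * n2) / (n1 + n2)
    }, numeric(1))
    max(ll[3:4]) / max(ll[1:2])
  }, numeric(1))
  expect_equal(got$lambda, oracle, tolerance = 1e-12)

  both_bad <- tibble::tibble(pair_id = "x", mate1 = "NNNN", mate2 = "NN")
  expect_equal(score_read_pairs(both_bad, clf)$call, "unscoreable")
})

test_that("filtering partitions conserve records under both rules", {
  fx <- make_test_classifier(k = 2, bins = 2, genome_bp = 8000)
  clf <- fx$classifier
  gv <- synthesize_genome(fx$gen_v, 4000, seed = 71)
  gh <- synthesize_genome(fx$gen_h, 4000, seed = 72)
  pairs <- simulate_read_pairs(
    tibble::tibble(genome_id = c("v", "h"), sequence = c(gv, gh),
                   label = c("virus", "host")),
    n_pairs = 200, read_length = 100, insert_size = 200, seed = 73
  )
  pairs$mate1[1] <- strrep("N", 100) # force one unscoreable pair
  pairs$mate2[1] <- strrep("N", 100)

  all_kept <- filter_read_pairs(pairs, clf, lambda_min = -Inf)
  expect_equal(all_kept$summary$n_kept, 199L)
  expect_equal(all_kept$summary$n_unscoreable, 1L)

  top <- filter_read_pairs(pairs, clf, top_fraction = 0.10)
  expect_equal(nrow(top$kept), floor(0.10 * 199))
  expect_equal(nrow(top$kept) + nrow(top$discarded) + nrow(top$unscoreable),
               nrow(pairs))
  expect_equal(top$summary$cutoff, min(top$kept$lambda))
  expect_true(all(top$kept$lambda >= top$summary$cutoff))

  expect_error(filter_read_pairs(pairs, clf), "exactly one")
  expect_error(filter_read_pairs(pairs, clf, lambda_min = 1, top_fraction = 0.1),
               "exactly one")
})

test_that("threshold filtering at lambda = 1 separates the two read sources", {
  fx <- make_test_classifier(k = 2, bins = 2, genome_bp = 20000)
  gv <- synthesize_genome(fx$gen_v, 60000, seed = 81)
  gh <- synthesize_genome(fx$gen_h, 60000, seed = 82)
  pairs <- simulate_read_pairs(
    tibble::tibble(genome_id = c("v", "h"), sequence = c(gv, gh),
                   label = c("virus", "host")),
    n_pairs = 400, read_length = 150, insert_size = 300, seed = 83
  )
  res <- filter_read_pairs(pairs, fx$classifier, lambda_min = 1)
  recall <- mean(pairs$label == "virus" & pairs$pair_id %in% res$kept$pair_id) /
    mean(pairs$label == "virus")
  rejection <- mean(pairs$label == "host" & pairs$pair_id %in% res$discarded$pair_id) /
    mean(pairs$label == "host")
  expect_gt(recall, 0.5)
  expect_gt(rejection, 0.5)
})

test_that("scoring is chunk-invariant (streaming-safe)", {
  fx <- make_test_classifier(k = 2, bins = 2, genome_bp = 8000,
                             seed = 50)
  set.seed(51)
  contigs <- tibble::tibble(id = paste0("c", 1:40),
                            sequence = replicate(40, rand_dna(150)))
  whole <- score_sequences(contigs, fx$classifier)
  parts <- dplyr::bind_rows(
    score_sequences(contigs[1:13, ], fx$classifier),
    score_sequences(contigs[14:40, ], fx$classifier)
  )
  # per-record quantities do not depend on the batch (q-values are
  # set-level by definition and are excluded)
  expect_equal(parts$lambda, whole$lambda)
  expect_equal(parts$ll_virus, whole$ll_virus)
  expect_equal(parts$call, whole$call)
})
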