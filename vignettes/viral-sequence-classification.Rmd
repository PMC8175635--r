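---
title: "Identifying viral sequences with GC-binned Markov chain likelihood ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying viral sequences with GC-binned Markov chain likelihood ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovir)
library(dplyr)
```

## The model

Metagenomic sequencing samples a mixture of viral, bacterial and (often)
eukaryotic DNA. Most assembled contigs are short and carry few or no
recognisable genes, so alignment- and gene-based virus detection fails on
exactly the sequences that dominate real samples. markovir instead models
*composition*: viruses and their prokaryotic hosts have been shaped by
different evolutionary pressures, so their genomes can be described by
different Markov chains over the DNA alphabet.

A $k$-th order Markov chain assigns each base a probability conditional on
the preceding $k$ bases. From a training corpus we count every $(k{+}1)$-mer
$w$ *together with its reverse complement* $\bar w$, so that counts — and
every downstream score — are identical for a sequence and its reverse
complement; sequencing has no strand information, and the classifier should
not either. Transition probabilities are estimated as

$$P(x \mid u) = \frac{N(ux) + c}{\sum_{x'} N(ux') + 4c},$$

with context $u$ a $k$-mer, next base $x$, and pseudocount $c$ (default 1).
A query $y = y_1 \dots y_N$ is scored by its length-normalised
log-likelihood

$$LL(y \mid M) = \frac{1}{N-k} \sum_{i=1}^{N-k}
  \log P_M(y_{i+k} \mid y_i \dots y_{i+k-1}),$$

which is comparable across sequence lengths. Windows containing a non-ACGT
character are skipped in both counting and scoring; a sequence with no
scoreable window is reported as *unscoreable*, never silently given a score.

Bacterial genomes span a wide GC range, and a single average chain blurs
that structure. Training genomes of each class are therefore partitioned
into $M$ bins by the quantiles of their GC fractions (each class by the
quantiles of its *own* GC distribution), and one chain is trained per bin.
A query is scored against all $M$ chains of a class and takes the best
(maximum) $LL$, i.e. the best-matching compositional neighbourhood.

The decision statistic compares the two classes:

$$\lambda(y) = \frac{\max_m LL(y \mid M^{m}_{\mathrm{host}})}
                  {\max_m LL(y \mid M^{m}_{\mathrm{virus}})},$$

oriented so that $\lambda > 1$ exactly when the viral likelihood exceeds the
host likelihood. Mean log-likelihoods are negative, so the ratio with the
*host* term in the numerator satisfies the rule "$\lambda > 1$ means viral";
the naive ratio with the viral term on top inverts that rule on negative
values and is available as `orientation = "literal"` for comparison only.
Because $\lambda$ is a ratio of mean log-likelihoods, it is invariant to the
base of the logarithm.

## Calibration: p-values and q-values

$\lambda$ values of short and long contigs are not directly comparable —
short fragments are noisier. The classifier therefore stores an empirical
null distribution: $\lambda$ scores of held-out *bacterial* fragments. A
query's p-value is the fraction of null fragments scoring strictly above it.
By default the null is stratified into powers-of-two length strata and a
query is compared against its own stratum (falling back to the nearest
populated one); a pooled null is available via `null_stratify = "pooled"`.
Whether length-matching the null is necessary depends on the length mix of
the queries; stratification is the safer default and the pooled option
preserves the simpler behaviour. Across a set of calls, Benjamini–Hochberg
q-values control the false discovery rate; a Storey-type $\pi_0$ correction
is optional.

## Defaults and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 9 | Markov order (context length, bases). Discrimination improves with `k` until the corpus can no longer populate the $4^{k+1}$ table; order 9 with 4 bins is the operating point for real genome corpora. Synthetic benchmarks in this package use small orders (2–4), which train reliably on megabase-scale corpora. |
| `bins` | 4 | GC-quantile bins per class. |
| `pseudocount` | 1 | Additive smoothing per (context, base) cell; keeps unseen transitions finite at high orders. |
| `mode` | `"row"` | Row normalisation guarantees each context is a proper distribution. `"prefix"` uses the context k-mer count as denominator, the textbook estimator; it differs only through sequence-boundary effects and satisfies an exact strand-symmetry identity used in the tests. |
| `orientation` | `"decision"` | See above. |
| `call_threshold` | 1 | The natural likelihood-ratio decision point; raise it to trade recall for precision. |

## Paired-end reads and pre-assembly filtering

Classifying *reads* before assembly, rather than contigs after it, avoids
chimeric viral/bacterial contigs. A read pair is scored as one unit: each
model's mean is taken over the union of both mates' windows (no window spans
the mate junction), so a pair behaves like one sequence of the summed mate
length. `filter_read_pairs()` partitions a read set by a fixed $\lambda$
cutoff or by keeping the top fraction $f$ of scoreable pairs (the cut at the
empirical $1-f$ quantile, ties broken deterministically by read id). The
kept/discarded/unscoreable partitions always add up to the input; unscoreable
pairs are excluded from the kept set by default, which is the conservative
choice when the kept reads feed a viral assembly.

## The synthetic benchmark harness

No genome downloads are needed to exercise the pipeline: the package
synthesises its own corpora.

* `markov_generator(order, gc, wobble)` builds a generating chain whose
  transition rows are a GC-targeted base composition perturbed per context
  by log-normal noise — giving the chain genuine context structure, not just
  a GC bias. `synthesize_genome()` simulates from it (C-level inner loop,
  seeded through R's RNG).
* `fragment_genomes()` cuts genomes into non-overlapping fragments of exact
  length $L$ (trailing remainder discarded), the standard contig surrogate.
* `build_mixture()` mixes all viral fragments with
  $\lceil V(1-f)/f \rceil$ subsampled host fragments for a target viral
  fraction $f$ — ninefold more hosts at 10% viral, equal numbers at 50%,
  $\lceil V/9 \rceil$ at 90%. Host subsampling is uniform without
  replacement (drawing the same fragment twice would make the mixture's
  effective size ambiguous).
* `simulate_read_pairs()` draws error-free 150 bp paired reads from a fixed
  insert (mate 2 is the reverse complement of the insert suffix), with an
  optional uniform substitution rate.

What the generator does *not* emulate: repeat structure, horizontal
transfer, coverage biases, real error profiles, and the long-range
correlation structure of real genomes. Passing benchmarks on these corpora
demonstrates that the estimator, scoring, calibration and filtering
machinery are correct and that compositional signal is recovered when
present — not that any particular AUROC will be attained on real
metagenomes, where the viral/bacterial compositional gap is far subtler than
between two synthetic chains.

## Numerical and design choices

* **Logarithms** are natural throughout; $\lambda$ is base-invariant, so
  this is purely a convention.
* **Palindromic words** are counted twice per occurrence (once per strand).
  The convention is applied identically in training and scoring, so scores
  are insensitive to it.
* **GC quantiles** use R's default (type 7) sample quantiles; a genome
  falling exactly on an interior bin edge goes to the lower bin. Heavily
  tied GC values can empty a bin, which is reported as an error suggesting
  fewer bins. A multi-record genome gets one GC value over its concatenated
  records, but k-mer windows never span record boundaries.
* **Empirical p-values** count strictly greater null scores (so a query
  equal to the null maximum gets $p = 0$ only if it strictly exceeds all of
  it); add-one smoothing is available when exact zeros are unwanted.
* **Ties in ROC curves** receive half credit (midrank convention), making
  the AUROC exactly the scaled Mann–Whitney statistic; the bootstrap SE
  resamples within class (30 replicates by default) so every replicate keeps
  both classes. Bootstrap resampling is over fragments, the unit the
  validation sets are built from.
* **Degenerate inputs**: sequences shorter than $k+1$, all-ambiguous
  sequences, and read pairs with two unscoreable mates are carried through
  every interface with an explicit `unscoreable` status.
* **Determinism**: training has no hidden randomness; all simulation and
  subsampling accept explicit seeds; a model file written twice from the
  same inputs is byte-identical.

## Problem sizes used in the checks

The package's own verification uses synthetic corpora sized to exercise the
statistics without waste: two order-2 chains at GC 0.35 / 0.65 with 1 Mb of
training per class; 2,000 test fragments per class at each length in
{200, 500, 1,000, 3,000} bp for the length sweep; a stored null of 100,000
bacterial fragments against 10,000 held-out queries for the calibration
check (a null much larger than the query set keeps the shared-null
correlation from distorting the uniformity test); and 1,000 simulated read
pairs for the filtering checks.

## A worked mini-benchmark

```{r benchmark}
bench <- benchmark_grid(
  orders = c(2, 4), lengths = c(200, 500, 1000),
  bins = 2, gc = c(0.4, 0.6), train_bp = 1e5, n_test = 300, seed = 1
)
bench
```

```{r benchmark-plot, fig.width = 5, fig.height = 3.5}
autoplot(bench)
```

AUROC grows with fragment length at fixed order — longer fragments average
more windows, shrinking the variance of $LL$ — mirroring the behaviour of
composition classifiers on real contigs.

## Known limitations

* The dense $4^{k+1}$ transition table costs $8 \cdot 4^{k+1}$ bytes per
  model (8 MB at $k = 9$); orders beyond ~10 need a sparse representation
  this package does not provide.
* Empirical p-values are granular at $1/n_{\mathrm{null}}$; very small
  p-values require a correspondingly large stored null.
* The classifier is two-class. Eukaryotic contamination can be *measured*
  (`contaminant_fpr()`) but a dedicated eukaryote model is not trained;
  fragments of a third class are forced into the viral/host dichotomy.
* q-values are a property of the scored *set*: scoring the same record in
  different batches changes its q-value (not its $\lambda$ or p-value).
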