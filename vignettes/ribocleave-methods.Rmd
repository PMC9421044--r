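---
title: "Methods: ribozyme fitness landscapes from cleavage sequencing"
author: "ribocleave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ribozyme fitness landscapes from cleavage sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocleave)
```

# The measurement model

A self-cleaving ribozyme transcribed in vitro either cuts its own backbone
before the reaction is stopped or it does not. After reverse transcription
and sequencing, each read belongs to one variant (genotype) of the
reference ribozyme and is either *cleaved* (the 5' upstream segment is
gone) or *uncleaved* (the segment is still attached). The per-variant
activity estimate is

$$\widehat{W}_g = \frac{c_g}{c_g + u_g},$$

the *fraction cleaved*, where $c_g$ and $u_g$ are the cleaved and
uncleaved read counts of genotype $g$. Given the true per-molecule
cleavage probability $W_g$, the counts are binomial, so
$\mathrm{SE}(\widehat W_g) = \sqrt{W_g (1 - W_g) / n_g}$ with $n_g = c_g +
u_g$; the package's consistency tests lean on exactly this error model.
Rows with fewer than `min_reads` total reads (default 1, i.e. nothing is
discarded silently) carry `NA`, never a fabricated zero.

Genotypes are substitution-only variants of a reference sequence, written
`"G1A;U20C"` (1-based positions, `"WT"` for the reference itself); the
*order* of a genotype is its Hamming distance from the wild-type.
Insertions and deletions are out of scope.

## Read classification

`classifyReads()` anchors every read at the reverse-transcription primer
binding site, located by **exact** substring match: the rejection
rules (any unexpected mutation in the primer site, the upstream portion,
or the ribozyme discards the read) imply exact matching, and exactness
keeps the classifier deterministic and fast. A read is cleaved
iff nothing precedes the ribozyme portion, uncleaved iff exactly the
upstream segment precedes it; anything else is rejected with a reason
code. Two matching modes mirror the two library designs:

* `match_list` — the ribozyme portion must equal one of the expected
  variant sequences (e.g. all mutants up to order 2);
* `variable_positions` — every base outside a declared set of variable
  positions must equal the reference, and variable positions must carry an
  allowed base.

Counts from multiple FASTQ files are pooled (the original triplicate
handling is undocumented; pooling counts is the default and the provenance
records the inputs). `cleaved + uncleaved + rejected = total` is asserted
on every run.

# Pairwise epistasis

For a double mutant $AB$ with constituent singles $A$, $B$:

$$\varepsilon = \log_{10}\frac{W_{AB}\,W_{wt}}{W_A\,W_B},$$

negative when the combination is worse than the multiplicative
expectation. $\varepsilon$ is computed on raw fractions cleaved (the
$W_{wt}$ factor already normalizes); it is symmetric in $A, B$ and
invariant under rescaling all four activities, and both properties are
tested. Quadruples containing a non-positive or missing activity are
excluded and counted per reason rather than patched with a pseudocount —
inventing magnitudes for unobserved activities would bias the
distribution's tails. An optional `min_reads` threshold in
the upstream table is the only filter.

# The genotype network and quintiles

`buildGenotypeNetwork()` joins genotypes at Hamming distance 1. Neighbor
search indexes each sequence $L$ times with one position wildcarded
(linear in $nL$) instead of comparing all pairs, and is verified against
the brute-force all-pairs oracle in the tests. Activity quintiles default
to five equal-width bins over $[0, 1]$ (right-closed; the "quintiles of
ribozyme activity" phrasing reads most naturally as value ranges), with a
rank-based equal-count option labelled in the output since the convention
is ambiguous.

# Predictors

* **Random forest** on flattened one-hot features (the $L \times 4$
  indicator matrix, column order A, C, G, U — fixed here because no
  convention is stated — flattened position-major). Hyperparameters are
  the ranger library defaults (500 trees, default `mtry`), recorded
  verbatim in the bundle; training is single-threaded and seeded so
  predictions are bitwise reproducible.
* **LSTM-feature hybrid.** A single-layer LSTM (32 hidden units, dropout
  0.2, nucleotide embedding of size 4, batches of 64, 25 epochs, Adam,
  MSE loss) is trained against fraction cleaved; the final hidden state
  $h_n$ of each sequence is then the feature vector for a random-forest
  regressor. The recurrence, backpropagation through time and Adam are
  implemented directly in vectorized R and validated against numerical
  gradients in the test suite.
* **Baselines**: ordinary least squares (rank-deficient designs fall back
  to ridge with $\lambda = 10^{-6}$, recorded in the bundle) and a small
  nnet multilayer perceptron (16 hidden units, decay $10^{-4}$).

Three architecture details were genuinely open and are fixed here as
design choices:

* *Embedding.* A learned embedding of dimension 4 initialized at the
  one-hot basis, so the one-hot representation is the starting point that
  training can refine.
* *Dropout placement.* A single-layer LSTM has no between-layer
  connections, so a layer-dropout parameter would be inert; dropout is
  applied to $h_n$ before the training head, in training mode only.
* *Learning rate.* The default is $10^{-2}$. With the
  fixed 25-epoch schedule, no early stopping, and the modest training-set
  sizes this package targets (hundreds to a few thousand sequences, i.e.
  tens of Adam steps per epoch), the conventional $10^{-3}$ leaves the
  training loss visibly unconverged (0.064 vs 0.004 final MSE on the
  package's L = 20 reference fixture) and the extracted features carry
  little signal. The rate is a config field; users fitting much larger
  data sets may prefer a smaller value.

Predictions are reported raw (regression output may fall slightly outside
$[0,1]$; clipping is an opt-in flag recorded with the output), matching
the practice of plotting model output directly against observation.

**Feature importance** is the impurity-based measure mapped back to
(position, base) labels and normalized to sum 1, with a per-position
aggregate. It is defined only for the one-hot random forest: the hybrid's
latent features have no positional mapping. Forests with no impurity
signal (constant targets) are flagged `degenerate` rather than silently
returning noise.

# Experiment harness

`splitByOrder()` bins genotypes by mutational order; orders 0–2 go
entirely to training (the comprehensive single/double data is always
training material), and each higher-order bin contributes a random 20% to
the test side. The per-bin test size is round-half-up of
$f \cdot n$ — with $f = 0.2$ and $n = 518$ this gives a 414/104 split
(103.6 rounds up), the convention the accounting tests pin down. Sampling happens on the sorted genotype list, so the split
depends only on the genotype set and the seed, not on row order; the split
object is built once per experiment and reused for every model, making
test sets byte-identical across model kinds.

Cumulative training sets take all training portions up to a maximal order
(plus the wild-type; it is never test data). Subsampling draws
round-half-up $f \cdot n$ rows without replacement. `computeMetrics()`
reports Pearson $r$, $R^2$ and MSE; both $R^2$ conventions are in
circulation, so the default is $R^2 = r^2$ with the coefficient of
determination available as an option. One base seed
derives the split seed and every model/replicate seed through a fixed
counter scheme, so a single integer reproduces a whole factorial run.

# The synthetic-data generator

All distributions below are generator fixtures, chosen once as plausible
desk-scale stand-ins so that every downstream stage has a known ground
truth. They are not estimates from data.

* **Landscape.** Latent score $=$ baseline $+ \sum$ additive $+ \sum$
  pairwise $(+ \sum$ three-way$)$, mapped to $[0,1]$ by a link. Additive
  effects per single mutation are a mixture of near-neutral
  ($N(0, 0.15)$, weight 0.35) and deleterious ($-|N(2.5, 1)|$, weight
  0.65) — most point mutations in a structured RNA hurt, some are
  tolerated. Compensatory base pairs get single-break effects of $-4$
  latent units and a pairwise rescue of $+6$, which guarantees the double
  sits above both singles after the link. Background pairwise terms are
  sparse with negative mean (RNA fitness landscapes are dominated by
  negative epistasis). Optional sparse three-way terms plant genuinely
  higher-order structure that no amount of double-mutant data reveals;
  they exist for the cumulative-training experiments.
* **Links.** `logistic` (default; wild-type activity $\approx 0.8$)
  because fraction cleaved is bounded and spans the full range.
  `exp` ($W = e^{\text{latent}}$, clamped at 1) makes additive latent
  effects exactly multiplicative in activity, so the epistasis null
  ($\varepsilon = 0$ for a purely additive landscape) holds exactly;
  under the logistic link the null is only approximate — link curvature
  alone produces $|\bar\varepsilon| \lesssim 0.15$ on the additive
  test fixture, and tests use that documented tolerance.
* **Doped library.** Each position mutates independently with probability
  0.03 (97% wild-type, 1% each alternative), matching doped-phosphoramidite
  synthesis; the mean order is $L \times$ rate.
* **Reads.** Depth per genotype is negative binomial (dispersion 0.2 by
  default; the real data show a ~100-fold spread between single- and
  double-mutant coverage), each read cleaved with probability equal to
  the true activity, sequencing errors off by default (a nonzero rate
  exercises the rejection rules). Reads are written as DNA FASTQ with
  constant quality; base qualities are never used by the logic.

What the generator does **not** emulate: paired-end structure, PCR
amplification bias, replicate index structure, position-dependent error
profiles, or any secondary-structure-informed effect distribution.
Passing tests therefore demonstrate correctness of the estimators and
harness under a known truth — not that the predictors will reach any
particular accuracy on real cleavage data.

# Numerical choices and degenerate inputs

* Alphabet is normalized to RNA (T → U) on every input path; one
  canonical form prevents duplicate genotype keys.
* Genotype identity is the position-sorted token string; all tables key
  on it.
* Zero-variance targets: Pearson $r$ is `NA` and flagged, never 0.
* Empty prediction input returns an empty vector; bins smaller than 2
  fall back to training with a warning rather than erroring a whole run.
* The LSTM forget-gate bias starts at 1 (standard practice so long-range
  information survives early training); weights are Glorot-uniform;
  gradient correctness is asserted to $10^{-7}$ against central
  differences.

# Problem sizes used by the test suite

The suite and the acceptance script work on a 20-nt reference (60
singles, 1,710 doubles, 200 held-out triples), 500-genotype read
simulations at depths 100/1,000/10,000, and a 13-position biallelic
combinatorial landscape (8,192 variants) for the cumulative-training
trend. These sizes were chosen so the full pipeline — including LSTM
training from scratch — exercises every code path in a few minutes on a
single CPU while keeping binomial standard errors small enough for the
stated tolerances.

# Known limitations

* The LSTM runs on the CPU in plain R; it is entirely adequate at the
  package's target scale (up to a few tens of thousands of sequences) but
  not a platform for large-scale architecture search.
* Exact primer matching means a primer-site sequencing error always costs
  the read (by design); there is no mismatch-tolerant rescue.
* Only pairwise epistasis is quantified; the generator can *plant*
  three-way terms, but the statistic module does not decompose them.
* Replicate handling is pooled counts; per-replicate fraction averaging
  is not implemented because the original choice is undocumented.
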