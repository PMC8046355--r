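---
title: "Models and design choices for scoring yeast two-hybrid deep-sequencing screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices for scoring yeast two-hybrid deep-sequencing screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(y2hngis)
```

## The problem

Batch yeast two-hybrid screens with next-generation sequencing readout
(Y2H-NGIS) mate a bait protein against a pooled prey library, split the
diploid culture into a *non-selected* arm (plasmid maintenance only) and a
*selected* arm (reporter activation required for growth), grow both to
saturation, and sequence the prey inserts. Preys that interact with the bait
multiply under selection; everything else is diluted. Three confounders make
naive read-count ranking unreliable:

* **auto-active preys** activate the reporter with no bait at all;
* **non-specific ("sticky") preys** interact promiscuously with many baits;
* cDNA libraries are cloned in three reading frames, so only about one third
  of inserts are translated in frame with the activation domain, and random
  out-of-frame survivors add background.

This package ranks candidate (bait, prey) interactions with three
complementary [0, 1] scores and their Borda ensemble, and ships a generative
simulator of the whole experiment so the ranking can be validated against
known truth.

## Count model and the two negative controls

Raw prey counts are modelled per prey with a negative binomial (NB)
log-linear model, mean `mu = sf * exp(beta_group)` and variance
`mu + phi * mu^2`. Two contrasts are fit with `fit_enrichment()` and
`fit_specificity_pairs()`:

* *enrichment*: selected vs. non-selected samples of the same bait — the
  non-selected arm is the negative control for selection;
* *specificity*: selected samples of bait i vs. selected samples of bait j,
  for every ordered bait pair — other baits are the negative control for
  promiscuity.

Counts always enter raw, with per-sample size factors (library size by
default, median-of-ratios optionally) as offsets. The design within one
contrast is a single two-level factor, so the two group coefficients
decouple and each prey's fit is a one-dimensional Newton iteration,
vectorized across all preys; this is what keeps a 10-bait, 20,000-prey
screen (one enrichment fit per bait plus 45 pairwise fits) in the
one-minute range on a single core.

Dispersion is estimated gene-wise by method of moments on
size-factor-normalized counts (bias-corrected by `n/(n - p)`), then shrunk
on the log scale toward a parametric `a0 + a1/mu` trend fitted across
preys, with prior weight 4 pseudo-degrees-of-freedom against the residual
degrees of freedom, floored at `1e-8`. The floor is what a pair of
duplicated pseudo-replicates collapses to, by construction. Wald statistics
use a t reference with *moderated* degrees of freedom (residual + prior):
with three replicates per condition a plain normal reference is visibly
anti-conservative (empirical type-I about 0.10 at nominal 0.05 in our
calibration simulations), while the moderated t brings it to about 0.05 and
keeps the null p-value distribution uniform to Kolmogorov-Smirnov distance
below 0.05. Preys with zero counts everywhere report `log2fc = 0` and a
missing p-value, which the scores treat as p = 1. A group with all-zero
counts is represented by a half-count at the group level, keeping fold
changes finite while its tiny Fisher information widens the interval
appropriately.

An established NB differential-abundance engine of the same family serves
as an independent cross-check in the test suite (fold-change correlation
and call overlap on a planted-signal fixture), never as the implementation.

One practical caution the test fixtures encode: with library-size offsets,
a planted enrichment of a subset of preys shifts the selected totals and
therefore depresses the apparent fold change of every other prey
(composition bias). In a real screen that is the intended semantics —
enrichment is change in *relative* abundance — but calibration of the
engine itself is judged with offsets fixed to truth.

## Fusion reads and the in-frame test

For each (bait, prey) and condition, fusion reads spanning the prey-vector
junction are aggregated across replicates (the model indexes them by
condition, not replicate) into `y` in-frame reads out of `f` fusion reads,
`y ~ Bin(f, pi)`. Under random three-frame cloning `pi` is about 1/3 in
non-selection; selection of a genuine interactor pushes it up. The pooled
two-proportion z statistic

```
rho = (pi_S - pi_N) / sqrt(pi * (1 - pi) * (1/f_S + 1/f_N))
```

tests `pi_N < pi_S`. `rho` is undefined when either condition has no fusion
reads, and the corresponding score is zero. Exactly equal proportions give
`rho = 0` even when the pooled variance degenerates. When non-selected
fusion data are missing entirely (some published designs), the default-null
variant substitutes `pi_N = 1/3` at an effective depth equal to the
selected depth; the effective depth is exposed as a tunable because it
scales the statistic, though ranks — all the downstream score consumes —
are insensitive to its broad range.

## The three scores

All three scores are rank-based, so any strictly monotone recalibration of
p-values (within windows) or of `rho` leaves them unchanged.

* **Enrichment** (`enrichment_score()`): pairs with `p <= alpha`
  (default 1) are ranked by p-value, `E(p) = (N - R(p))/N`; the set is cut
  into `b` equal p-value windows (default 10, width `alpha/b`) and within
  each window fold changes are ranked descending,
  `E(f) = (maxR - R)/maxR`; the combined score adds `E(f)` weighted by the
  window's `E(p)` spread over its size — so fold change only breaks ties
  among comparably significant pairs — and is rescaled by the global
  maximum.
* **Specificity** (`specificity_score()`): the same chain applied to the
  unordered bait-pair contrasts; a directed triple is zeroed when
  `f_ijk < 0` (the prey is not enriched with bait i over bait j) or
  `p > alpha`; p-scores and windowed fold-change increments are averaged
  over a bait's `n_b - 1` comparisons, then rescaled.
* **In-frame** (`inframe_score()`): the ascending rank of `rho` over all
  (bait, prey) pairs divided by the maximum rank; undefined statistics
  score 0.
* **Borda** (`borda_ensemble()`): classic mean-rank aggregation within each
  bait, rescaled by the bait's maximum mean rank.

Three constructions were genuinely open and are fixed as follows. First,
the combined specificity formula references "the" p-value window of a
(bait, prey) pair, but its `n_b - 1` triples may fall in different windows;
we compute the windowed fold-change increment per triple and average,
which coincides with the printed form whenever the triples share a window.
Second, fold-change ranks for specificity use the magnitude of the
canonical (positive-direction) fold change, since only one direction of a
pair can survive the `f < 0` rule. Third, ties take competition (minimum)
ranks, with the prey identifier as the final deterministic tie-break in
output ordering; window membership uses `ceiling(p / w)` with `p = 0` in
window 1, so a p-value sitting exactly on a boundary belongs to the lower
window.

The published tool's flags expose fold-change thresholds for both chains
with default 0. For specificity that threshold *is* the `f < 0` rule. For
enrichment the score equations carry no fold-change rule; the package
implements `enrichment <- 0` when `f` falls below the threshold, keeps 0 as
the pipeline default (matching the published flags), and accepts `-Inf` to
disable the rule. At the default the effect is confined to depleted pairs,
which the p-rank chain already places at the bottom.

Missing p-values become 1 and missing fold changes 0 before scoring; a
window whose p-scores are all equal contributes no fold-change increment
(zero spread). If every combined score is 0 the rescale is skipped and all
scores stay 0.

## Normalization and diagnostics

Four normalizations are provided (`normalize_counts()`): library size
(counts per million; the scale constant 10^6 is conventional and cancels in
the NB offsets), TPM (length-corrected CPM), median-of-ratios within each
bait-condition replicate group (geometric means over preys positive in all
group samples), and the replicate-sample variant of RUV
(within-replicate-group centering of `log(x+1)`, first `k` singular
vectors regressed out, `k = 1` by default, selected and non-selected
corrected separately, all preys acting as controls). Zeros remain zeros
under every method. Median-of-ratios assumes most preys are not
differentially abundant — an assumption selection deliberately violates —
and is included as the cautionary control it is in practice.
`normalization_report()` collects per-prey replicate CVs (computed on
untransformed normalized counts; the log-or-not choice is not fixed by
convention and is documented rather than asserted), within-condition
pairwise Pearson correlations, and paired Wilcoxon signed-rank comparisons
of CV distributions via `stats::wilcox.test()`.

## The simulator

`simulate_experiment()` generates a labelled screen per bait, condition and
replicate:

1. **Library**: proportions `q` drawn log-normal (`sdlog = 2`),
   renormalized — spanning the orders of magnitude typical of cDNA
   libraries. A stickiness fraction (default 0.1%) of preys is flagged
   auto-active/non-specific. Each bait receives 1-20 true interactors.
2. **Fitness**: `e` is the per-generation division probability, so a prey
   multiplies by `(1 + e)` per synchronous generation. Inert preys draw
   `e ~ Beta(1, 50)` under selection (they barely divide), sticky preys
   `Beta(8, 4)` under *every* bait, and true interactors sit above the
   99.9th percentile of the pooled background draws (default), uniform up
   to 1. Non-selected fitness is 0.9 for every prey.
3. **Growth**: initial cells `Bin(M0, q)` with `M0 = 3.84e9`; binomial
   offspring per generation (exact RNG draws even at 10^9-cell scales —
   no per-cell simulation); non-selected cultures run the deterministic
   number of generations reaching 7.5e10 total cells, selected cultures
   grow until the total first reaches it, so their duration is stochastic
   and genetic drift acts most strongly on rare preys. Diploid enrichment
   and the second selection round are treated as deterministic
   pass-throughs.
4. **Sequencing**: reads `Z ~ NB(L * X, phi)` with `L = depth / total`
   cells and depth 7.5e6 reads per sample; `phi = 0` degenerates to
   Poisson. Non-selected overdispersion is log-normal (median 0.5) with a
   Gaussian-copula coupling (correlation 0.9) to library abundance —
   real screens estimate abundance and overdispersion jointly, and
   abundant preys are measured with relatively less extra-Poisson noise;
   the copula preserves the marginal. Selected overdispersion is
   log-normal with median 0.05. The high-overdispersion mode replaces both
   with uniform draws over the upper-decile ranges (2.27-13.42 and
   0.33-2).
5. **Fusion reads**: a per-prey `Beta(2, 60)` fraction (mean ~3%) of total
   reads, in-frame with probability 1/3 except true interactors (0.95) and
   sticky preys (uniform between the two) under selection.

The generator's defaults are the study conditions of the idealized screen;
smaller libraries inherit the same sequencing depth, matching how
library-size sweeps are designed experimentally. What the simulator does
*not* emulate: mating-efficiency variation, experimentally normalized
libraries (proportions are heavy-tailed by design), frame-calling errors,
and any coupling between selected-condition overdispersion and fitness.
Passing tests therefore demonstrate correctness of the inference chain
under this generative model, not performance guarantees on any particular
real library.

Two parametric stand-ins deserve emphasis because they bound what the
validation can show. With heavy-tailed proportions, low-abundance true
interactors often have *zero* non-selected fusion reads, and the in-frame
score hard-zeroes such pairs; the in-frame ROC AUC in our ideal scenario
(about 0.85) is therefore markedly below what screens built on
experimentally normalized libraries can reach, and in the low-concentration
scenario the in-frame score collapses outright — the same failure mode
reported for real screens with sparse non-selected fusion coverage. The
same heavy tail caps raw-count Pearson correlations between non-selected
samples near 0.93 even under perfect abundance-overdispersion coupling;
exchangeability holds, but the numerical correlation level is a property
of the library-shape stand-in.

## Evaluation

`roc_auc()` is the trapezoidal AUC computed through the Mann-Whitney
mid-rank identity; `pr_auc()` is the step-wise (non-interpolated)
estimator, whose ties enter as blocks and whose baseline under random
scores is the prevalence — the right behaviour at prevalences of ~0.05%
where interpolation flatters. `run_scenario()` pools all (bait, prey)
pairs of a run into one curve per score (pooling, rather than averaging
per-bait curves, was an open choice; pooling weights baits by their
interactor counts and is recorded in results as such). True-interactor
pairs are positives; auto-active/non-specific preys count as negatives for
every bait, because discarding them is the point of the exercise.

## Problem sizes used by the shipped analyses

The test suite validates the ideal scenario at a 5,000-prey library (three
seeds, identical scoring pipeline; the full-scale ordering of the three
scores is reproduced there) and the full 20,000-prey scenario for the
headline figures, with the replicate, bait and low-concentration sweeps at
full scale and three seeds each — sizes chosen so a complete validation
runs comfortably on a single core. Engine-calibration fixtures use
500-2,000 preys at 3+3 replicates.

```{r example, eval = FALSE}
cfg <- scenario_config(n_preys = 5000)
sim <- simulate_experiment(cfg, seed = 1)
scores <- score_screen(sim$counts, sim$fusion)
evaluate_scores(scores, sim$truth)
```

## Known limitations

* The Wald test's small-sample behaviour is managed by moderation, not
  exact conditioning; at two replicates per condition p-values remain
  approximate.
* Fold-change shrinkage and independent filtering are deliberately absent:
  the scores consume raw p and f with `alpha = 1` by default.
* The specificity score needs two or more baits and improves with more;
  with two baits a prey interacting with both is indistinguishable from a
  sticky prey.
* The in-frame score inherits the sparsity of fusion reads; deep
  non-selected sequencing is the experimental remedy.
* Time-series fitness estimation is out of scope; only endpoint counts are
  modelled.
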