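# y2hngis

Ranking candidate protein–protein interactions from next-generation
yeast two-hybrid interaction screens (Y2H-NGIS).

In a batch Y2H-NGIS experiment a bait protein is mated against a pooled
prey library, the diploid culture is split into a non-selected arm
(background library composition) and a selected arm (growth requires
reporter activation, i.e. a bait–prey interaction), and prey inserts are
sequenced in both. Deciding which preys are genuine interactors is
confounded by auto-active preys (activate the reporter baitlessly),
"sticky" non-specific preys (bind many baits), and the three-frame cloning
of cDNA libraries (only in-frame fusions are translated). This package is
for groups running such screens — or re-analysing published ones — who
need a ranked candidate list with those confounders accounted for.

## The scores

For each (bait, prey) pair three [0, 1] scores are computed and combined
by a Borda (mean-rank) ensemble:

* **Enrichment** E<sub>ik</sub> — per-prey negative binomial Wald contrast
  of selected vs. non-selected counts (raw counts with size-factor
  offsets; gene-wise method-of-moments dispersions shrunk toward a
  parametric mean–dispersion trend; moderated-df t reference). P-values
  are converted to ranks, E(p) = (N − R(p))/N over the set with
  p ≤ α (default α = 1), and log₂ fold-changes are ranked *within b equal
  p-value windows* (default 10), so effect size breaks ties among
  comparably significant pairs:
  E(ik) = E(p) + [spread(E(p) in window)/N(window)] · E(f), rescaled by the
  global maximum.
* **Specificity** S<sub>ik</sub> — the same rank-within-rank chain applied
  to NB contrasts of bait i vs. every other selected bait j, zeroed where
  f<sub>ijk</sub> < 0 or p > α, averaged over the n<sub>b</sub> − 1
  comparisons. Sticky and auto-active preys are enriched with *every*
  bait and score near zero.
* **In-frame** IF<sub>ik</sub> — pooled two-proportion z statistic
  ρ = (π̂_S − π̂_N) / √(π̂(1−π̂)(1/f_S + 1/f_N)) testing whether the
  in-frame fusion-read proportion rises above its non-selected level
  (≈ 1/3 under random cloning), converted to a rescaled rank. Pairs with
  no fusion reads in either condition score 0; screens without
  non-selected fusion data can assume π_N = 1/3.

A Galton–Watson branching-process simulator (`simulate_experiment()`)
generates fully labelled synthetic screens — log-normal library
proportions, per-prey selective fitness, exact binomial growth of ~10⁹–10¹⁰
cells, negative binomial sequencing noise, binomial fusion reads — so the
whole pipeline can be validated with ROC and precision–recall curves
against known truth (`run_scenario()`, `evaluate_scores()`).

## Worked example

```r
library(y2hngis)

cfg <- scenario_config(n_preys = 5000)      # 10 baits, 3 replicates each arm
sim <- simulate_experiment(cfg, seed = 1)   # counts + fusion reads + truth
scores <- score_screen(sim$counts, sim$fusion)
head(tidy(scores), 5)
#>   bait   prey      enrichment specificity inframe borda
#> 1 bait01 prey04948      0.996       0.999   0.999 1
#> 2 bait01 prey04969      1.000       0.999   0.998 1.000
#> 3 bait01 prey00038      0.964       0.999   0.999 0.999
#> 4 bait01 prey00561      0.998       0.997   0.997 0.999
#> 5 bait01 prey00062      0.872       0.998   0.999 0.999

evaluate_scores(scores, sim$truth)
#>   score       roc_auc pr_auc n_positives n_total
#> 1 enrichment    0.947  0.548          87   50000
#> 2 specificity   0.996  0.830          87   50000
#> 3 inframe       0.886  0.727          87   50000
#> 4 borda         0.983  0.810          87   50000
```

The top-ranked pairs are planted true interactors of `bait01`
(e.g. `prey00038`, selected-condition fitness 0.35 vs. ≈ 0.02 for inert
preys); with 87 true pairs among 50,000, the specificity score retrieves
them with ROC AUC 0.996 and PR AUC 0.83 while auto-active/sticky preys —
scored as negatives — are pushed down the list.

Real data enter through TSV tables: `read_counts()` (preys × samples plus
a sample metadata file), `read_fusion()` (long-format in-frame/total
fusion reads), then `score_screen()` and `write_scores()`. A thin command
line over the same functions ships in `inst/cli/y2hngis.R`
(`simulate`, `normalize`, `fit`, `inframe`, `score`, `evaluate`).

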