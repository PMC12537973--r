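---
title: "Methods: differential dependency screening and its downstream statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential dependency screening and its downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

## The screening model

The screen consumes Chronos-style gene-effect scores: one real number per
gene per cell line, scaled so that 0 means knockout has no fitness effect
in that line, −1 is the typical effect of knocking out a pan-essential
gene, and scores below −0.5 are conventionally read as complete
essentiality. The screen asks, per gene, whether a *target* entity's cell
lines depend on the gene more than the pan-cancer *background*, and it
does so on medians rather than means: Chronos scores carry heavy-tailed
per-line artifacts (screen quality, copy-number effects), and the median
difference

$$\Delta_g = \mathrm{med}_{c \in C_T}\, x_{gc} - \mathrm{med}_{c \in C_B}\, x_{gc}$$

is robust to a minority of aberrant lines. Significance, in contrast,
comes from a two-sided two-sample t test on the same per-line scores.
Using a mean-based test beside a median-based effect size is deliberate:
the effect size matches the essentiality-threshold filter downstream
(which is defined on medians), while the t test supplies a familiar,
calibrated p-value for ranking. The t test assumes approximate normality
within groups; for 26-vs-300 group sizes it is insensitive to moderate
violations, and the null-calibration tests in the suite confirm nominal
behaviour for Gaussian scores at those sizes.

The Welch (unequal-variance) form is the default, with the pooled Student
form behind `var_equal = TRUE`: nothing guarantees equal score variance
between a 26-line entity and a 1000-line background, and Welch is also
what a stock R `t.test()` does, so defaults line up with common practice.

### Selection, enrichment, filtering

`run_screen()` chains four stages and records the surviving gene count of
each:

1. `compute_gene_stats()` — statistics for every gene with at least
   `min_group_size` (default 3) non-missing scores per group. Missing
   scores are dropped per gene, never imputed: imputing a dependency score
   would fabricate evidence of essentiality. Genes below the size floor
   are reported with `NA` statistics and are ineligible downstream.
2. `select_top_candidates()` — genes with strictly negative Δ, sorted by p
   ascending, first `top_k` kept. "Significant" here means *ranked by p*;
   no α cutoff is applied at this stage, so `top_k` alone controls the
   list size. Ties on p break by more-negative Δ, then by gene symbol, so
   output is identical across platforms.
3. `ora()` — exact upper-tail hypergeometric test of the top-K list
   against each gene set, BH-adjusted across sets; `member_overlap()` then
   restricts the candidate list to genes carried by sets with adjusted
   p < α (default 0.05). The universe defaults to the genes that actually
   received statistics — the sampling frame the top-K list was drawn from —
   rather than the union of set members; using the GMT universe is
   available via `universe = "gmt"` but mixes two frames. Sets smaller
   than 3 members or larger than half the universe are excluded by
   default, the usual ORA hygiene against uninformative sets.
4. `essentiality_filter()` — keep genes with target median < −0.5 **and**
   background median > −0.5, both strict, so a gene sitting exactly at the
   threshold in either group is excluded; rank survivors by p with the
   same tie-break.

When the gene-set collection is empty the enrichment stage is skipped and
the filter applies to the top-K list directly; the stage counts make the
skip visible.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `top_k` | 200 | genes | list size carried into enrichment; should scale with the number of genes screened (see below) |
| `essential_threshold` | −0.5 | score units | conventional complete-essentiality cutoff for Chronos scores |
| `min_group_size` | 3 | cell lines | smallest group for which a variance, hence a t test, is meaningful |
| ORA α | 0.05 | — | BH-adjusted cutoff calling a set enriched |
| ORA set-size bounds | 3, N/2 | genes | standard hygiene against tiny/near-universal sets |
| DEG `pseudocount` | 1 | counts | keeps log2 finite at zero counts; at typical expressed-gene counts its distortion is negligible |
| DEG α | 0.05 | — | raw-p significance flag; a BH column is emitted but not used for the flag |
| survival `ties` | `"low"` | — | stratum receiving samples tied at the median |

`top_k = 200` is the right order for a genome-scale screen (~18k genes,
~1% selected). On scaled-down simulations the same absolute K would make
the ORA query a large fraction of the universe, where the hypergeometric
overlap test has little room to detect enrichment — with a 500-gene screen
and K = 200 the query is 40% of the frame and the planted pathway's
overlap is barely above its null expectation. The package's own
scaled-down analyses therefore use `top_k = 50` (10% of a 500-gene
screen); users should keep K a small fraction of the genes tested.

## Numerical choices and degenerate inputs

* **Medians** are the mean of the two central order statistics for even
  group sizes (R's default), both in the screen and in the median split.
* **Zero-variance groups.** `t.test()` refuses constant data; the screen's
  contract instead returns `t = 0, p = 1` when both groups are constant
  with equal means (no evidence, not an error) and `t = ±Inf, p = 0` when
  a zero standard error meets unequal means. The t statistic is computed
  from the closed Welch/pooled formulas so these cases are decided
  explicitly; the test suite cross-checks against `t.test()` on
  non-degenerate inputs.
* **p-value flooring.** Before `−log10`, p is floored at the smallest
  positive double (~4.9e−324), so volcano coordinates stay finite.
* **Hypergeometric tail** via `phyper()`, which works in log space
  internally; the suite verifies it against exhaustive enumeration of all
  draws for every universe of size ≤ 12 to 1e−12.
* **Survival conventions.** Product-limit estimation and the Mantel–Cox
  test are computed with the `survival` package; subjects censored at an
  event time count as at risk for that time. A cohort with no events (or
  no variance information) returns `chi-square = 0, p = 1` with a warning
  rather than an error. Samples tied at the median split go to the low
  stratum by default; the choice is configurable because with heavily
  duplicated expression values it visibly changes group sizes.
* **Ranking determinism.** Every ranked output uses the same three-level
  tie-break (p, then Δ, then symbol), so re-runs and platforms agree
  byte-for-byte.

## What the generators emulate — and what they do not

`gen_dependency_matrix()` draws scores from three Gaussian classes:
non-essential (mean 0), common essential (mean −1 everywhere), and planted
selective (mean −δ in target lines, 0 in background), all with SD σ.
Defaults are 26 target vs 300 background lines, δ = 0.8, σ = 0.15,
10 planted selective and 20 common essentials among 500 genes. The
26-line target matches the size of a typical leukemia panel in the public
dependency data; the background is scaled down from ~1100 lines to 300 so
end-to-end tests run in seconds (the full-size configuration remains one
argument away). δ = 0.8 puts planted target medians near −0.8 — the
dependency range printed for strong hits in public data — and σ = 0.15 is
a realistic per-class spread for Chronos scores.

`gen_gene_sets()` plants one enriched pathway containing a configurable
fraction of the planted genes plus random fillers; the remaining sets are
uniform draws. `gen_counts()` draws negative-binomial counts (dispersion
0.1, base mean 100) with planted ±log2-effects; `gen_survival()` draws a
standard-normal covariate and exponential event times with hazard
`h0·exp(β·z)` plus independent exponential censoring tuned to a target
censoring fraction.

All generators are pure functions of their seed, with per-gene streams
derived from it so individual genes reproduce under reordering.

What the generators do **not** emulate: copy-number and screen-quality
artifacts in dependency scores, correlated genes or co-essential modules,
overlapping/nested real pathway structure, library-size variation and
gene-length effects in counts, or non-proportional hazards and competing
risks in survival. Passing tests therefore demonstrate that the
*procedures* are implemented correctly and behave as designed under their
own assumptions — not that those assumptions hold in any particular real
dataset.

## Calibration test design

The null-calibration checks run at 2000+ replicates and accept deviations
up to three binomial standard errors around the nominal 5%. The DEG
calibration runs at n = 10 samples per group: the Welch test is
intrinsically conservative at n = 3 (its small-sample rejection rate sits
below 4% even for Gaussian data), so calibration is an asymptotic property
and is tested where the asymptotics plausibly hold; the n = 3 regime —
the realistic replicate count for knockdown RNA-seq — is exercised by the
planted-effect recovery tests instead, where conservatism only makes the
test harder to pass.

## Known limitations

* The DEG statistic is the simple median/t construction it is specified to
  be; it ignores count overdispersion structure that negative-binomial
  GLMs (DESeq2, edgeR) model, and with default settings applies no
  library-size normalization (a CPM flag exists). It is faithful to its
  definition, not state of the art.
* ORA results depend on the gene-set collection and universe; with a
  different annotation release the enriched-set list and the downstream
  candidate count will differ. Only the procedure, not any specific
  pathway count, is stable.
* The log-rank test compares whole survival curves; it does not estimate a
  hazard ratio and the package deliberately stops short of Cox modeling.
* Dependency scores are consumed as given; estimating them from raw sgRNA
  counts is out of scope.
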