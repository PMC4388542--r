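---
title: "raftdiff: statistical methods and design notes"
author: "raftdiff maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{raftdiff: statistical methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftdiff)
```

# Scope

`raftdiff` analyses iTRAQ 2-plex reporter-ion proteomics of lipid-raft
(detergent-resistant membrane) preparations in a two-condition,
few-replicate design: one knockout (KO) and one wild-type (WT) channel per
experiment, typically three experiments. This vignette records the
statistical model, every default parameter and why it has the value it
has, and the numerical-tolerance decisions that the test suite relies on.

# The data model

A `PSMSet` holds one row per peptide-spectrum match with mandatory columns
(`experiment`, `peptide`, `protein`, `gene`, `confidence`, `is_decoy`,
`is_contaminant`) and one intensity column per reporter channel
(`i113`, `i114`, `i117`, `i118`). A `ChannelDesign` maps
(experiment, channel) to condition and fixes which condition is the ratio
numerator (KO by default). Missing reporter peaks are `NA`, never zero:
a zero would silently produce ratios of 0 or infinity, whereas `NA`
propagates to an explicit `invalid_reason` (`missing_peak` or
`zero_intensity`) in `peptideRatios()`.

# Stage-by-stage methods

## PSM filtering and decoy FDR

`filterPSMs()` applies, in order: a strict confidence cut
(confidence **>** threshold; a PSM exactly at 95 is rejected, matching the
"greater than 95 %" phrasing of standard search-engine reports), decoy
counting and removal, and contaminant removal (flagged rows plus any
normalized gene symbol in `contaminant_genes`, by default the keratin
family). The FDR estimate is

$$\widehat{\mathrm{FDR}} = 100 \cdot D / T$$

with decoy matches $D$ and target matches $T$ among confidence-passing
PSMs. The alternative estimator $100 \cdot 2D/(T+D)$ is available via
`method = "combined"`; the simple quotient is the default because it is
the form under which the reference values 0.00 %, 1.22 % and 1.63 %
(with $T = 257, 575, 796$) are exactly reproduced with
$D = 0, 7, 13$.

## Peptide ratios and protein rollup

Reporter ratios are multiplicative, so `rollupProteins()` summarizes the
peptide ratios of a protein within one experiment by the geometric mean,
$\exp(\overline{\log r})$, with a geometric SD
$\exp(\mathrm{sd}(\log r))$ (undefined for a single peptide). The
geometric mean is the maximum-likelihood location estimate under the
lognormal error model below and is exactly label-swap equivariant: swapping
numerator and denominator inverts every rollup.

## Cross-experiment combination

`combineExperiments()` requires a protein to be quantified in
`min_experiments` experiments (default: *all* experiments present). This
is the conservative published rule: 85 of 133 identified raft proteins are
quantified in 3/3 experiments. The combined estimate is the arithmetic
mean and sample SD of the per-experiment ratios — arithmetic, not
geometric, because the downstream t-test is specified on the ratio scale
and its inputs are the printed per-protein (mean, sdev) pairs.

## Reference-anchored differential test

With $n = 3$ experiments there are too few observations for a stable
per-protein variance. The design instead anchors every protein to an
internal reference protein believed not to change — HSP7C/Hspa8, whose
combined ratio is $1.01 \pm 0.064$ — and applies a pooled two-sample
t-test (equal variances, $df = n_1 + n_2 - 2 = 4$, two-tailed):

$$t = \frac{|\bar x_{\mathrm{ref}} - \bar x_g|}{s_p\sqrt{2/3}}, \qquad
  s_p^2 = \tfrac{1}{2}(s_{\mathrm{ref}}^2 + s_g^2).$$

Significance is called at raw $p < 0.05$; the direction is the sign of
$\bar x_g - 1$. A Benjamini–Hochberg column (`p_bh`) is emitted for
inspection but does not drive the primary call, mirroring the published
analysis. Options: `var_equal = FALSE` gives Welch's test;
`test_scale = "log"` runs the test on log-ratios, which is the variant
that makes p-values exactly invariant under label swap (on the raw ratio
scale a swap transforms ratios nonlinearly, $r \mapsto 1/r$, so p-values
shift slightly). The ratio-scale pooled test is the default because it is
the computation that reproduces the printed p-values.

`selectReference()` accepts a named gene or `"AUTO"`, which picks the
quantified gene minimizing $|\bar x - 1|$, breaking ties by smaller SD and
then alphabetically — a deterministic rule so that pipelines are
reproducible without a seed.

## Enrichment and overlap

`oraTest()` computes the hypergeometric upper tail
$P(X \ge k) = $ `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`,
identical to the one-sided Fisher test used by DAVID-style tools; the
EASE variant (score on $k - 1$) is available via `ease = TRUE`. Fold
enrichment is $(k/n)/(K/N)$. Corrections are applied *per namespace*
(e.g. GO CC and GO BP corrected separately), matching how term databases
report them. Gene symbols are normalized to mouse convention (first
letter capitalized) on both the query and the gene-set database, so
case-mismatched inputs cannot silently produce empty overlaps.
`overlapStats()` reports an intersection against an external target list
with a caller-chosen denominator and messages any targets absent from the
query rather than failing: curated lists legitimately contain symbols
(e.g. septin family aliases such as *Sept4*/*Sept7*) that do not match a
given proteome table exactly, and that disagreement should be surfaced,
not papered over.

# The simulator

`simulateDataset()` draws, per protein $g$ and experiment $e$,

$$\log r_{ge} = \log \rho_g + \varepsilon_{ge}, \quad
  \varepsilon_{ge} \sim N(0, \sigma_e^2)$$

and per peptide $j$

$$\mathrm{num}_{gej} = \mathrm{den}_{gej}
  \exp(\log r_{ge} + \eta_{gej}), \quad
  \eta_{gej} \sim N(0, \sigma_p^2), \quad
  \log \mathrm{den}_{gej} \sim N(8, 1).$$

It adds channel-wise missing peaks, sub-threshold PSMs, reversed-sequence
decoys (`REV_` accessions) and keratin contaminants, and returns the PSM
set together with a truth table of true and realized ratios. Everything
is a deterministic function of `seed`.

Default parameters and rationale:

| parameter | default | rationale |
|---|---|---|
| `sigma_p` | 0.20 | spectrum-level CV of ~20 %, typical of iTRAQ reporter ratios |
| `sigma_e` | 0.10 | between-experiment SD consistent with the observed reference protein SD (0.064 on the ratio scale at mean 1 corresponds to ~0.06–0.10 in log units once peptide averaging is included) |
| `peptides_per_protein` | 3–6 | the observed median peptide support of quantified raft proteins |
| `missing_peak_prob` | 0.05 | mild channel dropout |
| `subthreshold_prob` | 0.05 | fraction of PSMs below the confidence cut |
| `decoy_frac` | 0.05 | yields single-digit decoy counts at realistic $T$, like the printed $D \in \{0, 7, 13\}$ |
| `contaminant_frac` | 0.02 | sporadic keratin background |

The simulator is intentionally simple: it does not model ratio
compression from co-isolation, intensity-dependent variance, or shared
peptides, so it supports *calibration* claims (type-I error, bias,
label-swap symmetry, power trends), not instrument realism.

# Numerical decisions and tolerances

* **Printed-value reproduction.** The five spot-checked p-values (Ly6h
  0.003 … Flot1 0.084) are reproduced within ±0.003 absolute. This
  tolerance is not arbitrary: the printed inputs are rounded (means to 2
  decimals, SDs to 3), and propagating those half-ulp input intervals
  through the t-test moves p by up to a few thousandths for these rows.
* **Whole-table consistency.** A fixed ±0.003 band is *not* valid for all
  85 rows — for rows with small SDs the rounding of the inputs can move p
  by several hundredths (up to ≈ 0.08). The suite therefore checks, for
  every row, that the printed p lies inside the interval obtained by
  evaluating the test at all 16 corners of the input-rounding box
  (mean ± 0.005, SD ± 0.0005, for both the protein and the reference),
  widened by 0.0006 for the rounding of the printed p itself. All 85 rows
  pass this interval check, and the recomputed significance partition is
  exactly the printed one: 7 of 85 significant, 3 down, 4 up.
* **Degenerate t-tests.** A pooled SD of zero yields $p = 1$ when the
  means are equal and $p = 0$ otherwise, so noiseless simulations have
  well-defined outcomes.
* **Monte-Carlo test sizes.** The suite's calibration checks use problem
  sizes chosen by this package for runtime, not mandated elsewhere:
  type-I error over 26 null datasets × 41 proteins (> 1000 null tests,
  accepted band 0.03–0.07 at α = 0.05), power at a 1.55-fold effect over
  300 replicates compared against a noncentral-t oracle within 0.1, and
  log-scale unbiasedness over 200 replicates within 4 Monte-Carlo
  standard errors. Each runs in seconds on one CPU.
* **Ratio-scale bias.** The arithmetic mean of lognormal ratio estimates
  carries a multiplicative bias of $\exp(\sigma^2/2)$; unbiasedness is
  therefore asserted on the log scale, where the geometric rollup is
  mean-unbiased.
* **TSV round-trips.** Numeric columns are written with 10 significant
  digits (`formatC`), enough for exact round-tripping of every statistic
  the pipeline reports.

# Session info

```{r}
sessionInfo()
```
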