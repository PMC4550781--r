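---
title: "Methods: MSAP methylation profiling and cross-ploidy expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSAP methylation profiling and cross-ploidy expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidymeth)
library(dplyr)
```

`ploidymeth` analyses cytosine methylation variation across a polyploid
series from MSAP (methylation-sensitive amplification polymorphism)
fingerprints, and the qRT-PCR expression arm that accompanies such
studies. This vignette documents the statistical model behind each step,
the tunable parameters, the design decisions taken where the procedures
admit more than one reasonable reading, and what the synthetic-data
generators do and do not emulate.

## MSAP band-pattern classification

MSAP digests genomic DNA in parallel with EcoRI + HpaII (the "H" lane)
and EcoRI + MspI (the "M" lane). The isoschizomers recognise the same
CCGG site but differ in methylation sensitivity, so each scoreable
fragment's presence pattern across the two lanes encodes the methylation
state of its site:

| H lane | M lane | state | interpretation |
|---|---|---|---|
| 1 | 1 | non-methylated | both enzymes cut |
| 0 | 1 | fully methylated | internal cytosine methylated (CmCGG), MspI cuts |
| 1 | 0 | hemi-methylated | external cytosine methylated on one strand (mCCGG), HpaII cuts |
| 0 | 0 | uninformative | site absent, or methylated beyond either enzyme's tolerance |

`classify_site()` implements this truth table exhaustively. Doubly
absent fragments are *excluded* from profile denominators: a published
methylation table whose three state percentages sum to exactly 100%
implies that only the three observable patterns enter the denominator,
and an absent-absent pattern is genuinely ambiguous between site absence
and dual methylation. `n_sites` in a profile therefore counts
informative sites only, and `build_profiles()` errors when a sample has
none.

Scoring conventions follow standard AFLP/MSAP practice: a fragment
identity is a (primer combination, size) pair, co-migrating fragments
are one site, and scoring is restricted to the closed 120–480 bp window
(`filter_size_range()`), where capillary sizing against the internal
standard is reliable. Replicate reactions must agree: a fragment with
any discordant replicate pair in any sample and lane is dropped from the
whole table (`filter_reproducible()`), the strict reading of "only
reproducible fragments were retained". The peak binarization threshold
of `read_peak_table()` defaults to 50 RFU; instrument exports vary in
scale, so the threshold is exposed as a parameter.

## The mid-value U statistic

Within-group homogeneity is tested per species and measure (total,
fully, hemi-methylated) with the pooled two-proportion statistic

$$p = \frac{y_1 + y_2}{n_1 + n_2},\qquad q = 1 - p,\qquad
\delta = \sqrt{pq\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)},\qquad
U = \frac{|p_1 - p_2|}{\delta},$$

the classical two-sample z statistic for proportions, reported as an
absolute value against the fixed two-sided 5% critical value 1.96. No
continuity correction and no multiple-testing adjustment are applied;
tests are reported individually, as is conventional for this
descriptive use.

Two constructions needed a decision:

* **The mid-value comparator.** For the comparison of one sample
  against its ploidy group, the comparator proportion $p_2$ is the
  unweighted arithmetic mean of member proportions with the focal
  sample *included*, at the group's typical site count
  ($n_2 = \mathrm{round}(\overline{n})$, $y_2 = \mathrm{round}(p_2
  n_2)$). Inclusion keeps the comparator identical for every member
  (leave-one-out would give each species a different reference), and a
  published table in which every member shows a nonzero U against the
  mid-value is consistent with either convention. A median mid-value is
  available via the `midvalue` argument.
* **Cross-ploidy comparisons.** Group pairs are compared through their
  mean proportions at the *per-sample* site scale, not pooled counts:
  pooling thousands of sites per member would make the statistic
  diverge at effect sizes the within-fingerprint sampling noise cannot
  support, and would render the observed cross-ploidy non-significance
  numerically impossible. The per-sample-scale convention is a
  documented choice, not asserted as the original construction.

Pearson correlation between ploidy level (2–10, as integers) and each
methylation proportion uses `stats::cor.test`, with the usual two-sided
p-value on $n-2$ degrees of freedom.

## Synthetic MSAP generation

`msap_scenario()`/`generate_msap()` emulate the statistical structure
the analysis consumes: per-species state proportions, a fixed number of
scoreable fragments (default 1000 per sample, the order of magnitude a
12-primer-combination fingerprint yields in the 120–480 bp window), two
replicate reactions and an optional replicate-discordance rate.

In exact-count mode, state counts are allocated by largest-remainder
rounding so that counts always sum to `n_sites`. The allocation is
hierarchical: the non-methylated vs methylated split is fixed first,
then the methylated count is divided between fully and hemi-methylated
states. The packaged 20-species table makes this ordering matter: in
four of its rows the printed fully + hemi percentages differ from the
printed total by 0.1 points (rounding in the source), while
non + total is exactly 100 everywhere. The hierarchical allocation
reproduces every non/total percentage exactly at $n = 1000$ and absorbs
the inconsistency in the full/hemi split, where it is at most 0.1
points. Multinomial mode draws states independently per site instead,
for sampling-noise studies.

The generators are seeded and bit-reproducible. They do not model
fragment-length distributions, PCR bias, electrophoretic mobility, or
peak-calling physics; passing tests therefore validate the scoring,
classification and testing machinery, not instrument-level artefact
handling.

## Reference-gene stability

Two complementary stability statistics rank candidate reference genes,
with technical replicates averaged first and (species, biological
replicate) as the sample unit:

* `mvalue_stability()` computes, for each candidate pair, the standard
  deviation over samples of the log2 expression ratio (at efficiency 2
  this is simply the Ct difference), and averages each gene's pairwise
  variations into a stability value $M$; low $M$ means the gene moves
  in concert with the other candidates. Shifts common to all genes of a
  sample cancel in the ratios.
* `variance_stability()` is an ANOVA-style score in the spirit of
  model-based reference-gene selection, reconstructed rather than
  copied from any published implementation: each sample's Ct vector is
  centered by its across-candidate mean (removing template and run
  effects), and the candidate's centered log2 quantity is decomposed
  into a between-ploidy-group SD and a root-mean within-group variance,
  combined as $\sqrt{\text{between}^2 + \text{within}^2}$.

`select_references()` restricts the Ct table to each requested ploidy
comparison, combines the two rankings by mean rank (ties broken by $M$,
then gene name) and returns a segment plan.

A caution established with the package's own simulations: with four
candidates at sample-level noise SDs 0.05/0.1/0.2/0.4 cycles and six
species, neither statistic can reliably separate the two most stable
genes — the top rank falls on one of the two lowest-noise genes
essentially always, but on *the* lowest-noise gene in only roughly
three quarters of runs. This is an identifiability limit of estimating
standard deviations from a handful of samples, not an implementation
artefact; a noise-free gene among clearly noisier ones is ranked first
reliably once a dozen species are available. The test-suite asserts the
separations that the simulations show to be stable.

## Chained normalization and the inter-run calibrator

When no single reference gene is stable across the whole series,
normalization is chained: each plan segment names the reference gene
for a subset of ploidy levels; within a segment the relative quantity
per biological replicate is $E^{\,Ct_\text{ref} - Ct_\text{target}}$
with amplification efficiency fixed at $E = 2$ (no efficiency
calibration is modelled); adjacent segments are linked by the geometric
mean, over shared species and replicates, of the ratio of their
quantity scales; and the chain is anchored so the calibrator species'
mean quantity is exactly 1. Fold changes between species are ratios of
anchored quantities, so they compose exactly
($FC_{A\to C} = FC_{A\to B}\,FC_{B\to C}$), and run-wide Ct shifts
cancel (reference and target of a sample share a plate).

The segment-product algebra is the package's documented convention —
the construction is validated, as in the original design, by an
inter-run calibrator: an independent single-reference normalization
over the IRC gene's ploidy levels, compared to the chained estimate via
the coefficient of variation (SD/mean) of their ratio across shared
species, accepted below 5%. At zero noise the two estimates agree to
well under 1%; at the canonical noise level (technical SD 0.1 cycles,
small gene-specific reference instability) the CV is typically 3–4%
and the chained species estimates scatter a few percent per run around
the encoded values while remaining unbiased — the mean over repeated
simulated experiments recovers the encoded fold-change ladders to
within a fraction of a percent.

The canonical Ct scenario (`ct_scenario_chrysanthemum()`) encodes the
five intensively studied species with the MET1 and DDM1 fold-change
ladders, four reference genes at their observed expression strata
(EF1a ≈ Ct 17, ACTIN ≈ 19.3, TUB ≈ 21, PP2A ≈ 25.9) with gene-specific
instability SDs of 0.02–0.06 log2 units (chosen so the canonical chain
passes its own IRC check, as the original design reports), one qPCR run
per biological replicate with SD 0.3-cycle run offsets, SD 0.2-cycle
template shifts, and 3 × 3 biological × technical replicates.

Whether the expression–DNA-content correlation should be computed on
species means ($n = 5$) or biological replicates ($n = 15$) is not
determinable from the published account; `expression_content_correlation()`
offers both (`replicate_level`), defaulting to species means.

## Flow cytometry

`dna_content_ratio()` expresses each species' mean fluorescence peak
relative to a reference species, using only replicates with CV < 5%
(strict inequality), omitting — with a warning — species left without
accepted replicates. The generator draws accepted CVs uniformly below
the threshold and, when requested, a configurable fraction above it.

## Numerical conventions and degenerate inputs

* Largest-remainder apportionment breaks ties toward earlier elements;
  exact-count allocation therefore never loses or invents a site.
* $U$ with a degenerate pooled proportion (0 or 1) is defined as 0 when
  the two proportions agree and is an error otherwise.
* Reports print percentages to one decimal, U to two decimals, and
  $r$/$r^2$ to two decimals.
* Duplicate instrument peaks keep the maximum height (with a warning);
  malformed rows fail fast with their line number.
* Profile tables, U tables and correlation results are plain tibbles;
  the chained-normalization fit is the one structured object, with
  `tidy()`, `glance()`, `fold_changes()` and `autoplot()` methods.

## Problem sizes

The packaged analyses run at the canonical scale of the emulated study:
20 species × 1000 fragments × 2 lanes × 2 replicates for the MSAP arm,
and 5 species × 6 genes × 3 × 3 replicates for the expression arm.
Simulation-based properties in the test-suite use 100–200 seeded
replicates of these scenarios.

## Worked example

```{r example}
profiles <- chrysanthemum_exact_profiles(n_sites = 1000, seed = 1)
summarize_profiles(profiles)
max(midvalue_comparisons(profiles)$u)
pearson_ploidy_correlation(profiles, "total")

ct <- generate_ct(ct_scenario_chrysanthemum(seed = 1))
fit <- chained_normalization(ct, chrysanthemum_reference_plan()$plan,
                             calibrator_species = "C. nankingense",
                             irc_gene = "PP2A", irc_ploidies = c(4, 8, 10))
glance(fit)
tidy(fit) |> filter(gene == "DDM1") |> arrange(ploidy)
```

## Known limitations

* Fragment identity is by size and primer combination only; homoplasy
  (distinct loci co-migrating) is not modelled, matching standard MSAP
  scoring.
* The U machinery treats each fingerprint as a binomial sample of
  sites; spatial or locus-level correlation between sites is ignored.
* Amplification efficiency is fixed at 2.0 for all genes; no standard
  curves or efficiency corrections are modelled.
* The variance-based stability score is a reconstruction in the spirit
  of model-based selection, not a bit-exact reimplementation of any
  published tool.
* Published per-sample fragment totals in the emulated study are
  unreported; within-group U values computed at 1000 sites per sample
  track the published ones qualitatively but are not expected to match
  them digit for digit.
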