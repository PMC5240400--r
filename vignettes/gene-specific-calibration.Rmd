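---
title: "Gene-specific calibration of variant pathogenicity thresholds"
author: "VariantCalibrator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-specific calibration of variant pathogenicity thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantCalibrator)
```

## The problem

Deleteriousness scores such as CADD rank variants genome-wide, but clinical
interpretation needs a discrete call per variant — benign, pathogenic, or a
variant of uncertain significance (VUS) — and a single genome-wide score
cutoff is known to be wrong for many genes: genes differ widely in how much
damage they tolerate. A second, subtler problem is calibration bias. Benign
variants are on average more common and of milder consequence than
pathogenic ones, so naively comparing score distributions between "all known
pathogenic" and "all population" variants in a gene overstates any score's
power: part of the separation is explained by allele frequency and variant
consequence alone.

This package implements a gene-aware answer. For every gene with labelled
training variants it first constructs a benign comparison set *matched* to
the pathogenic set in allele-frequency range and effect-impact composition,
and only then asks whether CADD separates the two groups. The result is a
per-gene rule set — an allele-frequency ceiling, impact rules, CADD bounds —
with a fixed genome-wide fallback for everything else.

## The calibration procedure

Per gene, given pathogenic variants and population candidate variants:

1. **Pathogenic MAF ceiling.** Each pathogenic variant contributes its
   population allele frequency, with absence from the population counted as
   frequency zero. The ceiling is the 95th percentile of these values under
   the Hyndman–Fan type-7 definition (`percentileR7()`), i.e. linear
   interpolation between order statistics at $h = (n-1)p + 1$. Population
   candidates above the ceiling are too common to be in the pathogenic
   frequency range and are excluded.
2. **Known-pathogenic exclusion.** Candidates identical to a known
   pathogenic variant by (chrom, pos, ref, alt) are removed first.
3. **Impact equalization (step-over).** The remaining pool is downsized to
   the pathogenic impact distribution (proportions over HIGH / MODERATE /
   LOW / MODIFIER). The published description of this step names only a
   non-random "step over" removal of interspersed variants, so the exact
   mechanics here are this package's own design: the largest achievable set
   size is $n^* = \min_c \lfloor \mathrm{count}(c) / \mathrm{target}(c)
   \rfloor$ over impact categories with positive target (categories with
   target 0 are dropped entirely); per-category keep counts are allocated
   by largest remainder; and each over-represented category removes every
   $\lceil n_{alive}/r \rceil$-th variant in genomic-position order, in
   repeated passes, until its removal count $r$ is reached. This is
   deterministic, order-stable and interspersed, and on a realistically
   sized gene reaches the target composition to well under one percentage
   point per category — the tolerance `matchBenignSet()` reports against
   (`withinTolerance`). Infeasible targets (a needed impact category with
   zero candidates) are flagged, never silently approximated.
4. **CADD statistics.** On the matched groups the package computes group
   means, the 95th-percentile *sensitivity* threshold (type-7 5th
   percentile of pathogenic scores — the value exceeded by 95% of
   pathogenic variants) and the 95th-percentile *specificity* threshold
   (type-7 95th percentile of benign scores), and a two-sided Mann–Whitney
   U test (exact for two groups of at most 8 without ties, tie-corrected
   normal approximation otherwise).

Every gene then receives exactly one of seven categories, decided in this
order: `NOT_CALIBRATED` (fewer than 2 usable variants, or no pathogenic
variants at all — with nothing labelled pathogenic there is nothing to
calibrate against); `IMPACT_PREDICTIVE` (an impact category occurs in
pathogenic variants but never in the frequency-matched pool — impact is
then a direct classifier and no CADD calibration is performed);
`MAF_ONLY` (no benign set could be formed, either because no candidate
survives the frequency filter or because a group has no CADD coverage);
`LITTLE_DATA` (fewer than `minN = 5` variants in either matched group —
CADD bounds are still recorded and used, with commensurate caution);
`ARTIFACT` (significant separation in the inverted direction, benign above
pathogenic); otherwise `CADD_PREDICTIVE` / `CADD_LESS_PREDICTIVE` by the
Mann–Whitney p value at $\alpha = 0.05$. Significance and direction are
evaluated separately, which is what makes the inverted-direction artifact
category observable. The categories partition the calibrated gene set by
construction.

The "fewer than 2 usable variants" rule is read as pathogenic plus
population candidates combined, which is the weaker (more permissive)
reading of an ambiguous criterion; genes failing it get no numbers at all.

## Classification

`classifyVariants()` applies a fixed-order cascade; order is the one design
element a rule list of this kind leaves open, and it is pinned as:

1. allele frequency above the (adjusted) gene MAF ceiling → **Benign** —
   frequency dominates CADD by construction;
2. impact-predictive genes: impact at or above the least severe
   pathogenic-unique category → **Pathogenic**; impact strictly below every
   pathogenic-observed category → **Benign**; otherwise fall through;
3. genes with CADD bounds: score at or above the pathogenic bound →
   **Pathogenic**; at or below the specificity threshold → **Benign**; in
   between → **VUS** (uncertainty is an answer, not a failure; the
   `fallbackOnVus` switch routes this zone to the fallback instead);
4. genome-wide fallback (uncalibrated genes, `MAF_ONLY` /
   `NOT_CALIBRATED` / `ARTIFACT` remainders, missing gene annotation):
   frequency above the fallback MAF threshold → **Benign**; CADD above 15 →
   **Pathogenic**; at or below 15 → **Benign** (the boundary value 15 is
   deliberately assigned to benign); no CADD → **VUS**.

The fallback MAF threshold is the mean of all gene-specific ceilings
(`genomeWideDefaults()`); the CADD fallback threshold is fixed at 15.
Absent allele frequency is treated as zero in every frequency comparison,
consistently with the calibration step; a variant with no CADD, no
qualifying frequency and no applicable impact rule — including
MODIFIER-impact variants in uncalibrated genes — is a VUS rather than a
silent benign call. Classification is total and deterministic: every input
yields exactly one verdict plus the rule code that produced it.

### The sensitivity setting

Matched calibration is symmetric in the two classes, but diagnostic
practice is not: a missed pathogenic variant costs more than a false
positive. A single non-negative `setting` (default 5) shifts the balance:
the gene MAF ceiling is multiplied by $1 + setting$ (fewer frequency-based
benign calls) and the sensitivity CADD threshold is lowered by `setting`
score points. The effective pathogenic bound used by the classifier is
$\max(\mathrm{spec95}, \mathrm{sens95} - setting)$ — floored at the
specificity threshold so the pathogenic and benign zones never cross. With
this construction the bound is non-increasing and the MAF ceiling
non-decreasing in the setting, so sensitivity is provably non-decreasing
and specificity non-increasing along the whole sweep, with `setting = 0`
the exact identity. The published account of this adjustment fixes only its
direction and the default value of 5; the multiplicative/subtractive form
here is this package's documented choice, chosen for the monotonicity
guarantee above.

## Benchmarking

Because a classifier may abstain (VUS), two-state metrics are misleading.
The three-outcome definitions used throughout count abstentions as missed:

$$\mathrm{sensitivity} = \frac{TP}{TP + FN + \mathrm{missedPos}},\qquad
  \mathrm{specificity} = \frac{TN}{TN + FP + \mathrm{missedNeg}},$$
$$\mathrm{accuracy} = \frac{TP + TN}{TP + TN + FP + FN +
  \mathrm{missedPos} + \mathrm{missedNeg}}.$$

`predictiveValues()` gives the complementary classified-only view
($PPV = TP/(TP+FP)$, $NPV = TN/(TN+FN)$), which is the fair lens for
deliberately abstaining tools. `stratifyByPanel()` splits results by
organ-system gene panels (a Clinical Genomics Database style map); a
variant joins every panel linked to any of its genes, at most once per
panel, and the `NotInCGD` panel only when none of its genes are mapped.
`bootstrapCompare()` draws seeded bootstrap replicates (sampling with
replacement, 100 benign + 100 pathogenic per replicate by default),
computes the accuracy of two classifiers on identical samples, and
compares the two accuracy distributions with a two-sided Mann–Whitney
test.

## The synthetic cohort generator

All tests run offline on generated fixtures with planted structure
(`geneScenario()`, `generateGene()`, `generateCohort()`):

* CADD scores are normal truncated at zero — the minimal model matching
  the per-group mean/sd summaries such scores are reported with. Scaled
  CADD values have no hard upper bound, so no upper truncation is applied.
* Pathogenic allele frequencies are absent (not observed in the
  population) with probability 0.9 by default — reflecting that most
  clinically reported pathogenic variants are absent from population
  panels — and otherwise log-uniform in a rare range below 5e-5, the
  scale of a well-studied cardiomyopathy gene's ceiling. Benign
  frequencies are log-uniform over [1e-6, 0.5] with a 10% point mass at
  "absent", so both the frequency filter and the zero-assignment rule are
  exercised.
* Impact categories are allocated at exactly the planted proportions
  (largest-remainder allocation in shuffled order) rather than drawn
  multinomially, so a planted mix is recoverable within $1/n$ and
  category-starvation is a designed event, not sampling noise.
* A configurable number of pathogenic variants is copied, unlabelled, into
  the population set to exercise the known-pathogenic exclusion stage.
* Positions are consecutive integers per gene on disjoint 10 kb synthetic
  intervals, making step-over removal order well defined and test-stable.

`scenarioPresets()` ships one scenario per calibration category. The two
CADD-signal presets (10-point separation vs none, sd 3, 50 pathogenic
variants, 200 candidates) use a balanced impact mix shared by both groups
and a 30% absent-from-population candidate mass, so the benign pool never
starves an impact category and the planted category is decided by the rank
test alone — a deliberate design constraint, since those presets exist to
measure detection and type-I rates.

What the generator does **not** emulate: linkage and haplotype structure,
transcript structure and overlapping genes' shared exons, realistic
coordinates, score-frequency correlation, or label noise in the training
archives. Green tests on these fixtures therefore demonstrate the
correctness of the algorithms and their stated statistical behaviour, not
the clinical performance figures obtainable on real annotation resources.

## Numerical choices and degenerate inputs

* All percentiles are type-7; ties in score vectors are handled by the
  interpolation itself, without deduplication.
* Equalization tolerance is one percentage point per impact category;
  small matched sets can be granularity-limited, which is reported via
  `withinTolerance` rather than hidden.
* An empty pathogenic set yields an absent MAF ceiling; an empty variant
  set yields an all-absent impact distribution; empty groups are errors
  only where a statistic is undefined (Mann–Whitney, percentiles).
* The step-over removal ties genomic order as chrom, then position, then
  ref, then alt — fully deterministic on any input.
* Bootstrap replicates restore the caller's RNG state; all generators take
  explicit seeds, and calibration itself contains no randomness.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely from generated data:
category-recovery rates use 500–1000 single-gene replicates (50 pathogenic
variants, 200 candidates each); the gene-specific versus genome-wide
comparison uses a 20-gene cohort whose per-gene optimal cutoffs are spread
uniformly over [10, 30] (a 5-point half-gap at sd 3) and 1000 bootstrap
replicates of 100 + 100; the sensitivity sweep uses an 8-gene cohort at
settings 0–10. These sizes give sampling error comfortably below the
margins being asserted while keeping a full run in minutes on one core.

## Known limitations

* The exact step-over mechanics and sensitivity-adjustment arithmetic of
  the original implementation are unpublished; both are pinned here by the
  documented constructions above and are configurable where they are
  choices rather than contracts.
* Calibration consumes canonical-transcript, single-gene-per-annotation
  input; no transcript selection, liftover, HGVS parsing or allele
  normalization beyond multi-allelic splitting is performed.
* Truth labels are binary at scoring time; a truth-VUS variant must be
  excluded before scoring, and `scoreJudgments()` enforces this loudly.
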