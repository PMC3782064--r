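---
title: "Rare CNV burden and region association: models and design"
author: "cnvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare CNV burden and region association: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

# The analysis

`cnvburden` implements a case–control analysis of rare copy-number
variants (CNVs) called from SNP-array intensity data by a segmentation
caller such as PennCNV. The package consumes *calls* — one interval per
sample with a copy-number state, a probe count and a confidence score —
never raw intensities. The question it answers is whether affected
individuals carry a greater genome-wide burden of rare CNVs than
controls, and whether any individual genomic region is recurrently hit
in one group.

The pipeline has four stages, each exported on its own and composed by
`runCnvPipeline()`:

1. **Quality control** (`applyQcFilters()`): remove unreliable samples
   and calls.
2. **Rare-set derivation** (`deriveRareSet()`): remove calls in
   segmental duplications and calls too frequent to be rare.
3. **Global burden** (`burdenTable()`, `geneBurden()`): compare four
   aggregate statistics between groups by label permutation, across
   type/frequency/size strata.
4. **Region association** (`cnvrAssociation()`): merge overlapping rare
   calls into nonredundant CNV regions (CNVRs) and test each region's
   carrier counts.

## Coordinates and conventions

All coordinates are 1-based inclusive: a call spanning `start`–`end`
has length `end − start + 1`. BED input is 0-based half-open and is
converted at the boundary by `readIntervals()`/`writeIntervalsBed()`.
Chromosome labels lose any `chr` prefix on read; every analysis is
restricted to the autosomes 1–22, because hemizygosity in males and X
inactivation in females make sex-chromosome calls incomparable between
sexes.

Overlap fractions are *directional* throughout: the fraction is of the
focal interval's length, never reciprocal, mirroring how filtering
rules are phrased ("covered for ≥50% of *its* length"). Coverage by a
multi-interval track is per-base union coverage, not the best single
record, because real tracks contain overlapping records.

# Quality control

`qcThresholds()` bundles the tunable thresholds. Defaults, with the
failure direction (a value exactly at a threshold always *passes* —
inequalities are strict in the quoted direction, and the boundary cases
are unit-tested):

| parameter           | default  | a sample/call fails when            |
|---------------------|----------|-------------------------------------|
| `min_call_rate`     | 0.998    | array call rate `< 99.8%`           |
| `max_lrr_sd`        | 0.27     | log R ratio SD `> 0.27`             |
| `max_baf_sd`        | 0.17     | B allele frequency SD `> 0.17`      |
| `max_abs_wave`      | 0.04     | `|wave factor| > 0.04`              |
| `min_probes`        | 5        | call spans `< 5` probes             |
| `min_length_bp`     | 100,000  | call shorter than 100 kb            |
| `min_confidence`    | 10       | log-likelihood margin `< 10`        |
| `region_overlap_frac` | 0.5    | excluded-track coverage `>= 50%`    |
| `outlier_sd_mult`   | 3        | CNV count `> mean + 3 SD`           |
| `max_cnv_length_bp` | 7.5 Mb   | sample carries a call `> 7.5 Mb`    |

Sample metrics may be absent from a manifest; the corresponding rule is
then skipped with a warning rather than failing the run.

Two boundary conventions deserve emphasis because they differ on
purpose: the excluded-region rule removes a call at *exactly* 50%
coverage (`>=`), while the segmental-duplication rule keeps it (strict
`>`). Both follow the stated filtering rules verbatim and both are
asserted at the boundary in the test suite.

The CNV-count outlier rule computes its cutoff (mean + 3 population
SDs of per-sample counts) **once**, over the samples present when the
rule runs — a single cutoff, not an iterative trim. Re-applying the
rule to its own output can therefore remove further samples; this is
deliberate, and it is why the cascade's idempotence tests cover the
deterministic threshold filters only. An absolute per-sample count
cutoff (`max_cnv_count`) is available alongside the statistical rule
for studies that prefer a fixed number. Any sample carrying a call
longer than 7.5 Mb is dropped outright, since such calls usually
reflect karyotype-scale abnormalities rather than polymorphism.

# The rare set

A call's **occurrence count** is 1 plus the number of other calls (any
sample, any type) covering at least 50% of the focal call's length
(`countOccurrences()`). Counting overlapping rather than
identical-boundary calls matters because segmentation boundaries jitter
across samples at a shared locus.

The frequency filter (`filterByFrequency()`) has two modes, because "at
most 1% of cases and controls" admits two readings:

* `conjunctive_by_group` (default): a call is removed only when its
  occurrence count among case calls exceeds 1% of the cases **and** its
  count among control calls exceeds 1% of the controls. This is the
  reading under which a case-only recurrent locus — say 7 carriers
  among 261 cases, 1.6% of cases but absent from controls — remains in
  the rare set, which is precisely the signal a case–control scan is
  after.
* `dataset_wide`: a call is removed when its total occurrence count
  exceeds 1% of all samples. Under this mode that same 7-carrier locus
  (7 > 4.32) would be discarded.

The two modes genuinely disagree and published descriptions of this
kind of filter are not always self-consistent; the package therefore
implements both, defaults to the conjunctive reading, and writes the
active mode into the provenance log of every run.

# Global burden

## The four statistics

For a stratum of calls and a group of samples:

* **CNV rate** — calls per sample;
* **sample proportion** — fraction of samples with ≥ 1 call;
* **total size** — mean per-sample summed length (kb), zeros included;
* **average size** — mean call length (kb) over the group's calls.

Total size is averaged per sample rather than summed per group so that
the statistic is invariant to group size; a group sum would make the
larger group "more burdened" by construction. Each statistic is
reported as the case value, the control (baseline) value and the
case/control ratio; a zero baseline yields `NA` (reported N/A) rather
than an infinite ratio.

## Strata

`defaultStrata()` enumerates the standard report rows: all calls,
deletions only, duplications only; single-occurrence and 2–6×
occurrence classes within each type; and the size classes 100–500 kb,
≥500 kb and ≥1 Mb. Size rows overlap by design (≥500 kb contains
≥1 Mb) and are computed independently, not as a partition.

Frequency classification (`classifyFrequency()`) is *type-aware*: in
the deletions-only analysis, only deletions count as overlap partners,
so a deletion lying under a duplication is still a single occurrence
there while not being one in the both-types analysis. A consequence,
verified in tests, is that type-restricted single-occurrence counts
need not sum to the both-types count. A *single occurrence* overlaps no
other call for strictly more than 50% of its length; the 2–6× class
holds non-single calls overlapped by at most six others at ≥50%.

## Permutation inference

Significance is assessed by case/control label permutation: labels are
reassigned uniformly at random preserving group sizes, the case-group
value of each statistic is recomputed, and the one-sided empirical p is
the add-one estimator

$$p = \frac{1 + \#\{b : T_b \ge T_{obs}\}}{1 + B}.$$

The add-one form cannot return zero (its minimum is `1/(B+1)`,
1.0 × 10⁻⁵ at the default 100,000 permutations) and is the standard
choice when the identity permutation is not guaranteed to be drawn.
The one-sided direction is "cases show greater burden" for every
statistic, matching the alternative hypothesis of a risk-factor scan;
`alternative = "less"` or `"two.sided"` are available. On small
instances `exhaustive = TRUE` enumerates all
$\binom{n}{n_{\text{case}}}$ labelings and returns the exact
permutation p; the test suite checks the sampled estimator against
this enumeration and against an independently coded oracle.

Ties are compared with a small relative tolerance (`1e-9`) so that
floating-point noise in sums of kilobase values cannot flip a
`>=` comparison.

## Gene counts

`geneBurden()` counts, per sample, the distinct genes whose extended
span any of the sample's calls touches. Gene spans are the outermost
boundaries over transcript isoforms (`collapseIsoforms()`) extended by
a 20 kb flank on each side, floored at position 1. A hit requires at
least 1 bp of overlap with the extended span — the flank already
encodes positional tolerance, so no overlap fraction is applied.
Genes count once per sample regardless of how many calls hit them, and
the group comparison permutes the per-sample mean through the same
engine as the other burden statistics.

# Region association

`buildCnvrs()` merges rare calls into CNVRs as connected components of
same-chromosome ≥1 bp overlap (transitive closure), the region interval
running from the members' minimum start to maximum end. The 1 bp
criterion is the common construction for "merging overlapping CNVs"; a
`merge_frac` option requires instead a fraction of the shorter member,
for users who want tighter regions. Output order is deterministic
(chromosome, then start), and merging is idempotent and independent of
input order.

Each region's carriers are *distinct samples* — a sample with two
member calls counts once — and carrier status ignores CNV type by
default, since a region row reports one carrier table; a
`split_by_type` flag analyses deletions and duplications separately.

Three p-values are attached per region:

* **Fisher p** — the one-sided ("cases enriched") Fisher exact test of
  the 2×2 carrier table. One-sided is the package convention for
  consistency with the burden tests' directional alternative; for a
  region whose carriers are all cases it equals the hypergeometric
  tail $\prod_{i=0}^{k-1} (n_{case}-i)/(n-i)$, a closed form the tests
  use as an independent oracle. The two-sided test (sum of all tables
  with point probability ≤ observed) is available via `alternative`.
* **empirical p** — label-permutation p with the region's case carrier
  count as statistic (equivalent in ranking to the one-sided Fisher p),
  add-one estimator as above.
* **corrected p** — family-wise min-p correction: the fraction of
  permutations in which the *minimum* Fisher p across all regions is at
  most the region's observed Fisher p. Min-p was chosen over
  Bonferroni because the permutation stream already exists, because it
  respects the strong dependence between overlapping carrier tables,
  and because it reduces exactly to the empirical p for a family of
  one region. The implementation precomputes, per region, the Fisher p
  for every possible split of its carriers between the groups, so each
  permutation costs only table lookups.

# The synthetic-data generator

`simulateCnvDataset()` exists so that every stage can be exercised with
known ground truth. Its defaults describe the study conditions the
package targets:

* 261 cases and 171 controls, all passing sample QC;
* per-sample call counts Poisson with mean 2.9 (observed rare-CNV
  rates in array studies of this design are close to 3 per sample);
* 39% deletions;
* call sizes = 100 kb detection floor + a log-normal excess
  (`meanlog = log(55000)`, `sdlog = 1.15`), truncated at 1.75 Mb.
  This gives median ≈ 155 kb, mean ≈ 205 kb and size-class
  frequencies (≈ 81% / 15% / 3.6% / 0.6% for 100–250 kb / 250–500 kb /
  500 kb–1 Mb / >1 Mb) matching the summary characteristics of rare
  array-CNV call sets;
* placement uniform over the 22 autosome lengths (NCBI36 build), with
  a sample's calls kept pairwise disjoint, as a per-sample HMM
  segmentation would emit them.

**Planted truths.** A `planted_loci` table plants recurrent loci with
exact carrier counts; boundaries are jittered with a total shrink of up
to 30 kb split randomly between the two ends, emulating the ~30 kb
boundary spread seen at real recurrent loci while never shrinking a
planted call below the envelope length minus 30 kb (so a 148 kb
envelope still yields QC-passing ≥118 kb calls). A group-level effect
(`case_deletion_size_mult`) scales case deletion sizes to plant a
burden enrichment. Noise knobs relocate or mutate disjoint random
subsets of background calls so that each noisy call violates exactly
one QC rule; clean background calls are placed clear of the segdup and
exclusion tracks and of planted loci, so that with all knobs at zero
the QC cascade is the identity — an invariant the tests assert.

**What the generator does not emulate:** intensity-level artefacts
(wave patterns, batch effects), population structure, linkage between
loci, chromosome-specific CNV density, and calls below the 100 kb
floor. Passing tests on synthetic data therefore demonstrate the
correctness of the filtering arithmetic and the permutation inference,
not robustness to raw-intensity pathologies, which must be handled
upstream by the caller and the wave-adjustment procedure.

**Seeding.** Generation is fully reproducible from `config$seed`; the
replicate batches used in simulation tests draw their sub-seeds from a
seeded master stream rather than consecutive small integers, the usual
design for simulation studies.

# Numerical and design choices

* Copy number 2 is rejected on input — a diploid state is not a CNV —
  and states above 4 are clamped to 4 with a warning (homozygous
  duplication), since callers of this class do not resolve higher
  multiplicities reliably.
* Calls removed by a filter are attributed to the *first* failing rule
  in the documented order, so provenance removal counts always sum to
  the input count.
* Problem sizes in the test suite are chosen to keep the full run
  within a few minutes: exhaustive enumerations use ≤ 8 samples
  (≤ 70 labelings), Monte-Carlo checks use 20,000–100,000
  permutations with agreement asserted within 3 Monte-Carlo standard
  errors, the null-uniformity check uses 200 generator replicates at
  199 permutations each, and the planted-enrichment power check uses
  20 generator seeds at 2,000 permutations, n = 260/170.
* `runCnvPipeline()` is the single-config entry point; there is no
  shell executable because the intended users drive analyses from R —
  each stage reads and writes the shared tabular dialects, so stages
  remain individually re-runnable and swappable.

# Known limitations

* The frequency filter's two modes bracket, but cannot resolve, the
  ambiguity in "found in more than 1% of cases and controls"; reports
  always state the active mode.
* The min-p corrected p-value is computed from the same permutation
  stream as the per-region empirical p; for very small families this
  induces simultaneity, which is standard for max-T/min-p procedures.
* Carrier-based region tests ignore zygosity; a homozygous and a
  heterozygous carrier count equally.
* No covariate adjustment (age, sex, ancestry) is available in the
  burden tests; label permutation assumes exchangeability of samples
  under the null.
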