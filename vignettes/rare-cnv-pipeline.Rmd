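---
title: "Rare CNV case-control analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare CNV case-control analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecnv)
```

# The problem

Comitant esotropia — inward misalignment of the eyes — is a common,
heritable neurodevelopmental condition with no established molecular
mechanism. One productive way to probe its genetics is the rare
copy-number-variant (CNV) burden design used in other neurodevelopmental
disorders: call deletions and duplications from SNP-array intensity data in
a large case-control cohort, restrict to rare, well-supported events, and
ask (i) whether cases carry a heavier CNV load overall and (ii) whether any
individual locus is recurrently duplicated or deleted in cases.

`rarecnv` implements that workflow end to end and pairs it with a synthetic
cohort generator, so that every stage — calling, curation, burden,
association — can be exercised and validated without access to genotype
data, which studies of this kind typically cannot release.

# Signal model and CNV calling

## LRR/BAF emissions

A SNP array reports two normalised quantities per marker: the log R ratio
(LRR), a log-scale measure of total intensity that shifts with copy number,
and the B allele frequency (BAF), the relative contribution of the B allele,
whose cluster pattern reflects the allelic composition. The package's five
copy states use Gaussian LRR emissions with means

| copy state | 0 | 1 | 2 | 3 | 4 |
|---|---|---|---|---|---|
| LRR mean | −3.5 | −0.55 | 0 | +0.35 | +0.65 |

and a per-profile standard deviation. These shifts are the standard working
points for Illumina-style arrays: a hemizygous deletion loses about 45% of
intensity (log2-like scale ≈ −0.55), a single extra copy gains about 35%.
BAF emissions are finite mixtures over the allelic clusters each state
admits: a diploid marker clusters near {0, 1/2, 1}, a single-copy deletion
has no heterozygote band ({0, 1}), a three-copy duplication clusters near
{0, 1/3, 2/3, 1}, and a four-copy state near {0, 1/4, 1/2, 3/4, 1}. The
copy-zero state emits uniform noise. Three numerical choices matter:

* every state carries substantial weight on the homozygous clusters at 0
  and 1, so long runs of homozygous markers are uninformative and cannot
  mimic a deletion;
* within three BAF standard deviations of 0 or 1 the states share the same
  Gaussian factor, which cancels from all likelihood *ratios*; the
  implementation therefore uses the cluster weights alone in that band
  (this is what makes decoding cheap at scale, and it is exact for the
  Viterbi path and for confidence scores, which only ever compare states);
* a small uniform "outlier" component (weight 0.02; 0.5 for copy zero)
  keeps single aberrant markers from dominating.

## Transitions and the two caller profiles

Transitions are distance-independent: a per-marker probability of leaving
the diploid state (split evenly over the four CNV states) and of returning
to it. Real array callers use distance-dependent transitions; the
simplification is deliberate, because downstream stages treat the callers as
black boxes that deliver calls and confidence scores, and all boundary-level
behaviour that matters (fragmentation, boundary jitter) is still present.

Consensus pipelines run two independent HMM callers and keep only CNVs seen
by both. The package bundles two parameter profiles standing in for the two
callers:

| profile | LRR sd prior | P(leave CN2) | P(return to CN2) |
|---|---|---|---|
| `callerA` | 0.20 | 1e-4 | 0.020 |
| `callerB` | 0.16 | 5e-5 | 0.015 |

`callerA` assumes noisier intensities with a milder transition penalty;
`callerB` the reverse. On clean segments they agree; on marginal evidence
they disagree about boundaries or miss short segments — the test suite
checks both behaviours, since a consensus stage is vacuous if the callers
are identical and useless if they rarely agree.

## GC-wave correction and confidence

LRR exhibits a long-range wave correlated with regional GC content
("genomic wave"). `gc_adjust_lrr()` removes it by regressing LRR on marker
GC per chromosome and keeping the residuals, which also zero-centres each
chromosome. A chromosome with constant GC is only mean-centred.

Each call's confidence is the log-likelihood ratio of the called state
against diploid summed over the call's markers. It is positive for
well-supported calls, monotone in length at fixed per-marker evidence, and
serves the class-specific confidence filters (deletions ≥ 25, duplications
≥ 10 by default — the conventional cutoffs on this kind of score; they are
configuration parameters because any emulated score scale differs from any
specific caller's).

# Curation cascade

`sample_qc_filter()` excludes samples with LRR sd ≥ 0.3, |waviness factor|
≥ 0.43, BAF drift ≥ 0.01, call rate < 0.98, or more than 50 CNV calls (all
comparisons strict as listed; a sample at exactly the threshold of a
"less-than" rule is excluded). `merge_adjacent_fragments()` repairs HMM
fragmentation: two same-state neighbours merge when the intervening marker
count is below 20% of their combined marker count, iterated to a fixpoint.
The denominator excludes the gap, the literal reading of the rule; the
alternative is available via `include_gap = TRUE`. `intersect_two_callsets()`
emits the intersection interval of overlapping calls of the same copy-number
*class* (DEL/DUP) — two callers may legitimately disagree on CN0 vs CN1 at a
shared deletion, so requiring identical integer copy number (available via
`strict_state = TRUE`) would discard real consensus. `filter_calls()` then
applies, in a fixed, logged order: minimum length 10 kb → minimum 10 markers
→ artifact-region overlap (> 50% of the call against any single region) →
common-CNV overlap (> 50% against any catalog entry with population
frequency > 10%) → class-specific confidence. The order affects the
per-rule removal counts, not the final set, because the rules are
independent; fixing it makes the counts reproducible.
`control_frequency_filter()` finally clusters same-class calls by ≥ 50%
reciprocal overlap (single linkage) and removes every member of clusters
carried by more than 1% of controls. "Presence" of the same CNV across
samples is not self-defining; 50% reciprocal overlap is the field's standard
equivalence and is symmetric in the two call sizes.

# Burden and association statistics

`summarize_burden()` reduces curated calls to per-sample counts, total
lengths and mean lengths per class. `compare_burden()` tests a group
difference in any of these metrics with a two-sided label-swapping
permutation test: the statistic is the case mean minus the control mean,
labels are permuted preserving group sizes, and the empirical p value is
`(r + 1) / (n_perm + 1)` — the add-one convention avoids zero p values and
makes the attainable floor explicit. A permutation test is used because
per-sample burden distributions are zero-inflated and long-tailed, and
because it matches the association stage's permutation framing.
`burden_bin_odds()` reproduces the partitioned view: samples are binned by
burden, each bin is tested as exposed-vs-rest in a 2×2 table with the
cross-product odds ratio, a Woolf (log-scale normal) confidence interval
and Fisher's exact p. Tables with a zero cell get the Haldane–Anscombe 0.5
correction and are flagged rather than dropped.

The locus-level machinery evaluates the segmental (breakpoint) test: the
unique start/end positions of the retained calls of one class are the
evaluation positions; at each, the carrier 2×2 table (a sample carries the
locus if any retained call of the class overlaps it by at least 1 bp)
yields a Pearson chi-square. Pointwise empirical p values come from
case/control label swapping; family-wise corrected p values use the max(T)
device — each permutation contributes its maximum statistic over all
positions, and a position's corrected p is the rank of its observed
statistic in that maximum distribution. The chi-square was chosen as the
per-position statistic because max(T) needs statistics on a comparable
scale across positions with very different carrier counts; a one-sided
case-enrichment variant is available (`alternative = "case_enriched"`).
Adjacent positions with identical carrier sets are collapsed into one
reported segment. The gene-based test (`gene_test()`) runs the same
machinery over genes, counting a call only if it overlaps at least one
exonic bp, which catches non-overlapping CNVs that hit the same gene.
`classify_nested_carriers()` separates carriers of a full-length
duplication from carriers of a nested shorter form by overlap with the
distinguishing (full-only) region, and `keep_unrelated()` supports the
relatedness re-test by keeping the lowest-LRR-sd member per family.

Woolf intervals are reported for odds ratios throughout. They are the
standard large-sample choice but not the only one, and different interval
methods give visibly different bounds at small carrier counts; the package
treats OR point estimates as the stable quantity and interval bounds as
method-dependent.

# The synthetic cohort generator

`cohort_config()` defaults encode the study conditions this package was
built around: 1614 cases and 3922 controls; background rare-CNV rates of
0.8 deletions and 1.1 duplications per person; per-person mean total
lengths of 220.7/177.8 kb (deletions, cases/controls) and 419.6/258 kb
(duplications), so cases carry longer CNVs at equal rates; and three
planted risk duplication loci at their reported hg19 coordinates and
carrier frequencies — chr2 (23/1614 cases, 4/3922 controls), chr4
(27/1614, 6/3922), and chr10 (64/1614, 18/3922) with the chr10 locus split
into full-length carriers (36 cases, 0 controls) and carriers of a ~300 kb
nested duplication (28 cases, 18 controls) placed at the distal end of the
654 kb span. Carrier draws are independent Bernoulli per sample at the
group frequency; carriers receive the configured boundaries jittered by
0–2 markers per endpoint, so recurrent carriers have distinct breakpoints,
as real recurrent duplications do. Per-CNV lengths are log-normal with the
mean fixed at total/rate and `sdlog = 0.7`; the cohort-level data behind
the defaults constrain only means, so the shape is an assumption, recorded
here and in fixture manifests. A configured fraction of samples receives QC
metrics beyond the exclusion thresholds, and a configured fraction of cases
is grouped into families sharing risk-locus carrier status, to exercise the
QC filter and the unrelated-subset re-test.

What the generator does **not** emulate: probe-level genotype calling and
call-rate structure, mosaicism, sex chromosomes, distance-dependent
transition behaviour, population stratification, batch/plate effects, and
the genuinely genome-wide scale of marker grids. Passing tests therefore
demonstrate that the pipeline's logic and statistics behave correctly under
a faithful signal model, not that any specific biological dataset would
reproduce specific values.

## Scaling to the toy genome

The bundled `toy_marker_map()` holds 20,000 markers (4 chromosomes × 5,000
markers at 1 kb spacing) — about 1/35 of a genotyping array condensed into
20 Mb. The full per-person CNV load cannot be transplanted onto it: ~1.9
background CNVs per person across 5,536 samples with lengths of hundreds of
kb would tile the toy genome many times over, so reciprocal-overlap
clustering (the control-frequency filter, the breakpoint carrier sets)
would degenerate by construction. `scaled_study_config()` therefore scales
the background load while keeping everything the published numbers pin down
— cohort sizes, risk loci, carrier frequencies — exact:

* background rates 0.11 deletions and 0.15 duplications per person
  (≈ 1/7 of the full rates). The duplication rate is the binding
  constraint: a two-group mean-difference test on total duplication length
  needs roughly `z ∝ sqrt(rate)`, and 0.15/person keeps per-seed power for
  the configured length excess near 99%, so a multi-seed acceptance run is
  not dominated by burden-test noise;
* per-CNV mean lengths ≈ 1/5 of the full-scale per-CNV means (deletions
  55.2/44.5 kb, duplications 76.3/46.9 kb for cases/controls), preserving
  the published case:control ratios. At 1 kb marker spacing these lengths
  keep nearly all true CNVs above the 10 kb / 10-marker filters while the
  filters still see genuine removals;
* together these give ~1,400 background CNVs over 20 Mb. Single-linkage
  chains under 50% reciprocal overlap then stay short (geometric tail), so
  no background cluster approaches the 1%-of-controls threshold by chance,
  while planted common-CNV loci (15% and 12% population frequency) are
  removed by the catalog filter as intended.

These values were fixed from the constraints above before any end-to-end
run and are not tuned thereafter.

## What recovery means at this scale

With 10^4 permutations the smallest attainable corrected p is
1/10001 ≈ 1e-4. A planted locus is "recovered at the floor" when its
observed chi-square exceeds all 10^4 permuted maxima. At the expected
carrier counts the three loci sit comfortably above the permutation-maximum
distribution, but the carrier draws are Bernoulli: a low draw at the chr2
locus (expected 23 case carriers, binomial sd ≈ 4.8, against ~4 control
carriers) can push its statistic into the upper range of the permuted
maxima, in which case that seed reports the locus one rank short of the
floor. This is a property of the design itself — max(T) correction against
~1,500 breakpoint segments, carrier counts in the twenties — not of the
implementation; the acceptance suite runs 20 seeds and requires 19 to
recover all three loci at the floor with no null segment doing so.

# Problem sizes and runtime

The default test suite simulates full 5,536-sample cohorts on the 20k-marker
toy genome for the end-to-end recovery check (about 40 s per seed, 20
seeds), runs one million permutations once for the empirical-floor check
(~10 s), and keeps all other tests on cohorts of tens of samples and maps
of a few hundred markers. Exhaustive-enumeration oracles are used wherever
the label-assignment space is enumerable (≤ 12 samples, ≤ C(12,6) = 924
assignments).

# Known limitations

* The HMM is a deliberately simplified stand-in: distance-independent
  transitions, no trio information, no allele-specific copy number beyond
  five states. Its calls and confidence scores have the right interface and
  qualitative behaviour, but its score scale is its own.
* Confidence-score cutoffs (25/10) are conventions carried over from
  practice with an established caller's score scale; on any other scale
  they are tunables, which is why they live in `filter_thresholds()`.
* Woolf confidence intervals do not reproduce every published interval at
  small counts; point odds ratios do.
* The control-frequency filter's notion of "the same CNV" (50% reciprocal
  overlap, single linkage) is a convention; chains of partially overlapping
  calls can in principle link distinct events.
* Empirical p values are bounded below by 1/(n_perm + 1); reported floors
  must always be read together with the permutation count.
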