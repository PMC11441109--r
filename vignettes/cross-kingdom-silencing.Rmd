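---
title: "Inferring endogenous and cross-kingdom RNA silencing from dual RNA-seq"
author: "xksilence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring endogenous and cross-kingdom RNA silencing from dual RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xksilence)
```

## The problem

When a biocontrol fungus colonizes plant roots, both organisms reprogram
their transcriptomes, and part of that reprogramming is mediated by small
RNAs: microRNAs (miRNAs) in the plant, microRNA-like RNAs (milRNAs) in the
fungus. Small RNAs can also move between the interacting organisms and
silence genes in the partner — cross-kingdom RNA silencing. Demonstrating a
cross-kingdom silencing candidate from sequencing data alone requires a
chain of inferences, each individually weak: a predicted complementary
target site, expression of the small RNA, opposite regulation of the
putative target, anticorrelation of the two expression profiles across
samples, and evidence that this anticorrelation is stronger than what the
same small RNA shows against arbitrary transcripts.

`xksilence` implements that chain as a reusable, testable pipeline for a
two-species (plant root + fungus) dual RNA-seq design, together with a
synthetic data generator that plants known miRNAs, known differential
expression, and known endogenous and cross-kingdom target pairs, so every
stage of the inference can be scored against ground truth without any
sequencing download.

## Read triage

Small-RNA libraries from interaction samples contain reads from both
organisms plus structural-RNA fragments. The triage contract is:

1. **Length filter** — keep reads of 18–32 nt, boundaries inclusive
   (`lengthFilter()`).
2. **Structural removal** — drop a read iff it occurs as a substring of an
   rRNA/tRNA/snRNA/snoRNA reference within a configurable number of edits,
   0 by default (`removeStructural()`).
3. **Collapse** — merge identical sequences within a sample, summing
   multiplicities (`collapseReads()`).
4. **Species partition** — a read *maps* to a species iff the read or its
   reverse complement occurs as a substring of any transcript of that
   species within `maxErrors` edits (1 by default). Reads mapping to both
   species are *ambiguous* and excluded from species-specific counting;
   reads mapping to neither are *unmapped* (`partitionBySpecies()`).

Matching is by approximate substring search over transcriptomes rather than
genome alignment: at the read lengths involved (18–32 nt) splicing is
irrelevant, and the substring-with-&le;1-edit contract is simple enough to
verify against a brute-force dynamic-programming scan, which the test suite
does read-by-read. The matcher is base R's TRE engine (`agrep`), whose
error model — any substring of the text within a given edit distance of the
pattern — is exactly the contract; the oracle in the tests is
`utils::adist(partial = TRUE)`, an independent implementation. A read
matching several transcripts of one species is recorded once per
transcript, capped at 200 placements, each placement weighted `1/n`, so
multiplicity totals are conserved. Match positions are recorded 0-based,
half-open; *antisense* means the read's reverse complement matches the
transcript, the orientation relevant for silencing-target counting.

## miRNA quantification

Mature miRNAs are quantified by counting, per sample, the reads that
contain the mature sequence within edit distance 1
(`approximateCount()`, `quantifyMirnas()`). Design choices:

* **Error model.** "One mismatch" is interpreted as edit distance &le; 1
  with indels allowed (the approximate-grep default); a Hamming-only mode
  (`mode = "hamming"`) restricts to substitutions for users who prefer the
  stricter reading. Both are exposed because the underlying convention is
  genuinely ambiguous in the field.
* **IsomiR double counting.** Each catalog entry is counted independently,
  so a read within one edit of two near-identical matures (e.g. an isomiR
  family member) counts for both. This mirrors independent per-miRNA runs
  of a matcher and is intentional.
* **Strandedness.** Catalogs are oriented; no reverse-complement search.

Detection uses a summed-count threshold, 50 copies by default, boundary
inclusive (`detectExpressed()`).

## Normalization and differential expression

Size factors are plain median-of-ratios (`computeSizeFactors()`): the
factor of a sample is the median, over features with positive counts in
every sample, of the count divided by the feature's geometric mean. The
test suite cross-checks this against DESeq2's
`estimateSizeFactorsForMatrix` on random matrices.

The two-group test (`differentialExpression()`) is a deliberately plain
negative-binomial Wald test, not a DESeq2 re-implementation: group means on
normalized counts with a 0.5 pseudocount, a per-feature method-of-moments
dispersion, and a Wald statistic on log2 fold change. Two numerical choices
matter at the three-replicate scale this design uses:

* **Dispersion pooling.** The method-of-moments dispersion is pooled over
  the within-group residuals of *every* condition with at least two
  replicates, not just the two contrasted conditions. In the default
  design each species' matrix spans four replicated conditions, raising
  the residual degrees of freedom from 4 to 8, and this is how the
  downstream FDR &lt; 0.05 filters remain attainable at
  n = 3; it is also how the established NB frameworks use a multi-condition
  design.
* **t reference.** The Wald statistic is referred to a t distribution with
  the pooled residual degrees of freedom rather than a standard normal. A
  plug-in normal reference ignores the uncertainty of the dispersion
  estimate and, at n = 3, roughly doubles the nominal type-I error (we
  measured ~0.12 at a nominal 0.05); with the t reference the measured
  type-I error on 2000 null synthetic features is ~0.05. The acceptance
  suite re-measures both calibration and power on every run.

Calls combine an effect-size and a significance threshold:
`|log2FC| >= 1.5` and BH-adjusted FDR &lt; 0.05 by default, the thresholds
used for both transcripts and small RNAs in the study design this package
emulates. Term enrichment (`termEnrichment()`) is a one-sided upper-tail
hypergeometric test per flat term label, BH-corrected; no ontology
propagation is performed.

## Target inference

`classifyTargets()` runs a fixed filter cascade; each candidate pair's
verdict is the first failing stage, which makes the rejection reasons
directly interpretable:

1. **Consensus** (`consensusFilter()`): at least 2 plant-style or at least
   3 animal-style prediction-tool votes, duplicates collapsed. External
   predictions arrive as tables; the package's own `surrogateExpectation()`
   scorer counts as one plant-style vote. The surrogate slides the mature
   sequence along the transcript without gaps and scores Watson–Crick 0,
   G:U wobble 0.5, mismatch 1.0, doubled over miRNA positions 2–13, site
   cutoff 5.0. It is gapless on purpose — every score is verifiable by
   hand — and is a stated convention, not a claim of parity with any
   published tool.
2. **Opposite expression** (`oppositeExpressionFilter()`): the miRNA must
   be called (|log2FC| &ge; 1.5, FDR &lt; 0.05), the transcript must be
   significant (FDR &lt; 0.05, *no* fold-change threshold), and the two
   fold changes must have opposite signs.
3. **Correlation** (`pairCorrelation()`): Spearman (mean ranks on ties) on
   size-factor-normalized counts across all samples in which both features
   are measured — for an endogenous pair that includes the species'
   control samples, for a cross-kingdom pair only the interaction samples.
   The retained set requires Spearman &le; `spearmanMax`; the `lenient`
   profile uses −0.4 and the `strict` profile −0.7, reflecting the two
   thresholds quoted in the literature this emulates. Pairs with a constant
   count vector are rejected as degenerate.
4. **Background test** (`backgroundTest()`): the pair's correlation must be
   lower than the correlations of the same miRNA with the other transcripts
   of the target's organism. With a single target-side value the rank-sum
   comparison degenerates to the empirical percentile
   `p = (1 + #{background <= r}) / (1 + |background|)`; the pair passes at
   p &lt; 0.1. Fewer than 10 background transcripts flags the p-value as
   low-power. The degenerate form is a documented stand-in: whether the
   original procedure compared one value or a set is an open question, so
   the function accepts either.

A pair is *cross-kingdom* iff the miRNA's species differs from the
transcript's. Retained pairs are reported sorted by Spearman ascending;
identical inputs always give byte-identical tables.

## The synthetic experiment

`simulateExperiment()` builds the whole study from a
`simulationConfig()`:

* **Design.** Five conditions by default — plant-only control, fungus-only
  control, and three interaction conditions (a wildtype and two
  silencing-mutant strains) — with three biological replicates each. This
  mirrors the dual-culture designs the pipeline targets, in which the
  mutant interactions are the lever that separates miRNA-driven effects
  from generic interaction effects.
* **References.** Random transcripts (300–1500 nt); 5% of fungal
  transcripts are copied identically into the plant reference to create
  genuinely ambiguous reads; four structural-RNA references provide the
  contaminant source.
* **Planted miRNAs.** 30 per species, 19–24 nt. Pair-owning miRNAs respond
  during the wildtype interaction only (magnitude 3.5 log2 units, the
  center of the milRNA fold changes reported in the emulated study), with
  alternating polarity across pairs; a further ~15% of unpaired miRNAs
  respond too, so differentially expressed miRNAs exist beyond the planted
  pairs but remain a minority — which keeps median-of-ratios normalization
  unbiased. Per-sample abundances carry lognormal variation (sd 0.35 on the
  log scale) around these condition means.
* **Planted pairs.** Each pair's mature sequence is embedded as its exact
  reverse complement inside the target transcript. Target means couple to
  the miRNA's relative abundance `rel = a/max(a)` as
  `2^(repression * (1 - rel))` for a down-regulated (releasing) miRNA and
  `2^(-repression * rel)` for an up-regulated (repressing) one, with
  repression 3.0 by default; with repression 0 a planted target follows
  exactly the background model. Because the wildtype and mutant conditions
  put the miRNA at opposite levels, miRNA and target counts anticorrelate
  across the nine interaction samples; on the default design the planted
  Spearman correlation is &le; −0.7 in ~95% of seeds.
* **Counts.** Negative binomial with dispersion 0.05 (a typical
  biological-replicate dispersion for controlled culture designs), feature
  base means lognormal around 300, per-sample depth factors lognormal
  (sd 0.15), planted non-target differential expression of |log2FC| 2–6.
  Planted target base means are drawn log-uniformly from 300–1000 so the
  anticorrelation signal is not drowned by shot noise at low counts.
* **Reads.** Per-sample pools are a multinomial mixture of mature miRNA
  copies (at most one substitution error per read, probability
  `seqErrorRate`), degradation fragments of 18–32 nt from both strands,
  exact windows of the structural references, and out-of-range-length
  fragments. Per-sample totals always equal `readsPerSample`; qualities
  are constant "I" since the pipeline ignores them.
* **Determinism.** Every stage runs on its own RNG substream derived once
  from the master seed, in a fixed documented order, so a stage called
  standalone is byte-identical to the same stage inside a composed run and
  adding later stages can never reshuffle earlier outputs.
* **Emulated tools.** Two pseudo prediction tools vote for every planted
  pair and for random decoy pairs (some shared between tools, some not),
  so the consensus, expression, correlation and background rejections are
  all exercised by construction.

### What the generator does and does not emulate

The generator reproduces the *statistical structure* the inference relies
on: two species, ambiguous reads, NB counts, realistic normalization bias
sources, condition-driven miRNA responses, dose-coupled targets, decoy
predictions. It deliberately does not model hairpin precursors, adapter
contamination, positional degradation bias, isomiR spectra, or sequence
composition bias. Passing tests on this generator therefore demonstrate
that the pipeline's logic and statistics behave as specified under the
assumed model — not that the model captures every failure mode of real
libraries. The known structural asymmetry: planted pairs with up-regulated
miRNAs (repressed targets) show slightly weaker within-condition coupling
than released targets, so under the `strict` (−0.7) profile their recovery
is lower; the default `lenient` profile recovers both polarities.

## Descriptive summaries

`lengthFivePrimeProfile()` gives multiplicity-weighted read-length and
5'-nucleotide fractions per species partition.
`percentileRankAnalysis()` reproduces the antisense-load analysis: genes
with zero antisense counts are removed, the rest are percentile-ranked by
antisense count (mean ranks on ties), binned into right-closed quintiles
((0,20], (20,40], …), and per-bin mean expression is compared by one-way
ANOVA with Tukey HSD at 0.05; the compact letter display is computed by the
standard insert-and-absorb construction on the Tukey p-value matrix, run
once per species panel. `ddct()` implements 2^−ΔΔCt relative
quantification, and `colonizationRatio()` / `colonizationTest()` the
fungal/plant DNA ratio with ANOVA plus pairwise Fisher LSD (plain
unadjusted LSD, stated as such).

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale: references of 30–100 transcripts per species for read-level
checks, 100–2000 features for count-level checks, read pools of a few
hundred collapsed reads for the brute-force oracle comparisons, 20-seed
replication for specificity and 100-seed replication for the
anticorrelation contract. These sizes were chosen so every brute-force
oracle stays exactly computable while leaving the statistical contracts
(calibration within [0.03, 0.07], power &ge; 0.95, recovery &ge; 4/5)
measurable with useful Monte-Carlo precision.

Conventions worth knowing when extending the package: sequences are
normalized to uppercase RNA (T→U) at every boundary; FASTQ is written in
the DNA alphabet as sequencers emit it; dispersion estimates are floored at
1e-8; fold changes use a 0.5 pseudocount; BH is applied per contrast over
all tested features; undefined correlations (constant vectors) are
excluded rather than imputed; and every user-facing table is sorted
deterministically so reruns are byte-identical.

## Limitations

* The species partitioner is a transcriptome substring matcher, a stand-in
  for the genome-alignment exclusion pipelines used with real data; it is
  exact for the contract it states but does not model spliced or
  intergenic alignments.
* The NB Wald test trades DESeq2's shrinkage machinery for verifiability;
  effect estimates at very low counts are noisier than shrunken ones, and
  the fold-change threshold applies to the plain estimate.
* The background test's percentile form is a documented interpretation of
  an underspecified procedure; with backgrounds under ten transcripts its
  p-values are flagged low-power rather than suppressed.
* Tukey letters follow the stated algorithm; no parity with any particular
  statistics package's letter assignment is guaranteed beyond it.
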