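---
title: "Calling, timing and dosage-modelling of amplification-embedded focal deletions"
author: "ampliDel maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling, timing and dosage-modelling of amplification-embedded focal deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliDel)
```

# The problem

Some tumor genomes carry a paradoxical lesion: a gene sits inside a large
somatic amplification -- driven by a neighboring oncogene -- yet carries a
small (sub-100-kbp) deletion of its own promoter-proximal region. The
motivating case is *BRD4*, which is co-amplified with *CCNE1* on
chromosome 19 in breast, ovarian and endometrial cancers but is toxic when
overexpressed, so tumors that amplify the region appear to selectively
clip *BRD4* back down. Studying this requires three computational pieces,
which this package implements as one tested pipeline:

1. **Focal-deletion calling** at a target locus from copy-number segments
   and SV junctions, with a read-depth *rescue* pathway for deletions the
   segment-level caller missed, and a *relative-loss* classification
   against the neighbor gene for non-focal cases.
2. **Event timing**: given allele-specific copy number, deciding for each
   carrier whether the amplification or the deletion came first, and
   testing for enrichment of one order with an exact binomial test.
3. **Dosage modelling**: expression of the target gene as a linear
   function of tumor type, absolute copy number and focal-deletion
   status; copy-number-adjusted isoform expression; a per-gene
   differential-expression stage with Bonferroni and fold-change gates;
   and ORF-screen log-fold-change utilities.

Because the original cohort data are access-controlled, the package ships
a **synthetic cohort generator** whose ground-truth ledger is the oracle
for every test: each guarantee the package makes is demonstrated by
planting events with known properties and recovering them blind.

# The generative model

One ~5 Mbp synthetic chromosome carries three loci: a driver oncogene
analog (`CCNE1L`), the target (`BRD4L`, 100 kbp) with a designated
promoter-proximal deletion window, and its neighbor (`NOTCH3L`) used for
copy-number normalization. Per sample:

* With probability `pAmplification` (default 0.4) one haplotype is
  amplified over a region spanning all three loci, to a total copy number
  drawn uniformly from `ampTotalCnRange` (default 3--6).
* A focal deletion is planted inside the target window with probability
  `pFocalDelGivenAmp` (0.4) in amplified samples and
  `pFocalDelGivenNoAmp` (0.02) otherwise; its length is uniform on
  `delLengthRange` (10--60 kbp, respecting the 100 kbp focality cap).
  The deletion removes exactly one copy-unit from one haplotype -- the
  amplified one with probability `pDelOnAmpHaplotype` (0.8).
* When both events occur, the deletion precedes the amplification with
  probability `pDeletionFirst` (0.15). Order matters allelically: a
  deletion-first history leaves *nothing* of the affected haplotype to
  amplify, so the deleted interval shows loss of heterozygosity inside an
  amplification; an amplification-first history removes one of several
  co-amplified copies, leaving a non-zero reduced allelic copy number.
  This asymmetry is exactly what the timing classifier reads back.
* Emitted observables: allele-specific segments (minor copy number is
  withheld as `NA` for deletions shorter than `allelicMinBp`, emulating
  too-few phased SNPs); deletion junctions with outward breakend
  orientations, plus tandem-duplication-like junctions at amplification
  boundaries (so orientation gates are exercised); 200-bp binned
  tumor/normal depth ratios, negative-binomial around coverage times
  CN/2; and FPKM expression from the dosage model below. With
  probability `pScnaDropout` a planted deletion is omitted from the
  segment table only -- the scenario the read-depth rescue exists for.

## Choice of the amplification range

The default amplification range is 3--6 total copies. This is the regime
in which a *single-copy* nested loss remains physically resolvable in
binned read depth: the fractional depth drop of one lost copy among $n$
is $1/n$, so at 10 copies the signal is a 10% dip that neither an
automated threshold nor the by-eye review the rescue pathway formalizes
could separate reliably from counting noise. The moderate range keeps the
simulated cohort within the regime the rescue method is meant for; the
`rescueDropFrac` default (0.1) sits below the weakest in-range signal
(1/6) with a noise margin of several standard errors given the
≥50-bin deletions the generator plants. These two defaults are chosen
jointly and deliberately, from the detection physics rather than from any
specific dataset.

Other defaults: depth coverage 100x per 200-bp bin with negative-binomial
size 100 (mild overdispersion beyond Poisson; the generator accepts
`Inf` for the exact Poisson limit, under which mean depth calibrates to
CN/2 within 2% over 10^4 bins); tumor purity 1 by default because
consensus copy-number inputs are purity-corrected, with a mixing
parameter available; FPKM is clamped at zero after noise because FPKM
cannot be negative.

## Expression coefficients

The generative dosage model is
$$\mathrm{FPKM} = \beta_{0,\mathrm{type}} + \beta_{cn}\,CN +
\beta_{del}\,\mathbf{1}\{\text{focal deletion}\} + \varepsilon,$$
with defaults chosen so the ovarian-vs-reference contrast is 26.1 FPKM,
the per-copy slope 3.6 and the deletion offset -6.3 -- the values the
recovery tests target. The copy-number covariate is the neighbor-gene
copy number, because copy number *within* the target is variable by
definition in carriers. Baselines (Other 12, BRCA 21, UCEC 23, OV 38.1)
keep all subgroup means far from the zero clamp at the default noise SD
of 5 FPKM, so OLS assumptions hold to excellent approximation. An
isoform split (long 70%, dominant short 27%, secondary short 3%) is
emitted alongside the gene-level row.

# The caller

`callScnaFocalDeletions()` formalizes "a relative copy-loss at the
locus" as a maximal run of segments at least `relLossDelta` (0.5) copies
below **both** flanking segments, overlapping the gene, spanning less
than `maxEventBp` (100 kbp), with a segment boundary within
`proximityBp` (50 kbp) of the gene (distance measured from the nearer
gene boundary, zero inside). The original analysis left the dip depth to
manual review; the both-flanks rule is this package's operationalization
and lives in `callerParams()` where it is reported in run provenance.

`rescueFromDepth()` automates the manual read-depth review: for each
deletion-consistent junction (lower breakend `+`, upper `-`, both
pointing outward from the lost interval) bracketing a sub-cap interval
that overlaps the target window, it compares the mean depth ratio inside
against `rescueFlankBp` (50 kb) flanks, excluding other candidate
intervals from the baseline, and additionally requires the best
single-changepoint step locations to fall within `junctionMatchBp`
(1 kb) of the breakends. Orientation, size, drop and step gates are all
individually exercised in the test suite. Candidates whose flanks the
track does not cover are skipped with a warning rather than an error.

`callRelativeLoss()` emits the non-focal class -- target mean CN at
least `relLossDelta` below the neighbor's -- and such calls are excluded
from the focal carrier set that downstream statistics use.
`callFocalDeletions()` orders the pathways so that no sample receives
both a segment-supported and a rescued call for one interval.

# Event timing

`classifyTiming()` derives major/minor haplotype copy numbers inside the
deletion and on the flanks within the amplification. The amplified
haplotype is the flank major. The observed inside pair is matched, up to
a tolerance `allelicTol` (0.3 copies -- the threshold below which an
allelic difference is treated as indiscernible; the source analysis
never quantifies "discernible", so this is an exposed parameter), to one
of three hypotheses: loss on the amplified haplotype (verdict
deletion-first if it fell to zero, amplification-first if non-zero
reduced), loss on the other haplotype (`different_alleles`, ambiguous),
or no allelic change (`deletion_below_allelic_resolution`, the verdict
for deletions the segment table never recorded). Missing minor copy
number, balanced flanks above one copy (`uniparental_disomy`), and
flanks that disagree with exactly equal overlap (`discordant_flanks`)
are the remaining ambiguity reasons. Uniparental-disomy-like samples are
*always* reported ambiguous: the one published case where UPD could be
manually ordered was a per-sample judgment call, not a rule, and is not
encoded.

`timingBinomialTest()` computes the one-sided exact tail
$\sum_{i\ge k}\binom{n}{i}/2^n$ for $k$ the majority count -- by direct
binomial-coefficient summation, no approximation. One-sidedness in the
direction of the observed majority is a deliberate reading: for the
worked 11-vs-2 configuration the one-sided tail is $92/8192 = 0.0112$,
which matches the printed two-decimal value 0.01, while the two-sided
value (0.0225) does not. The summary always records the sidedness and
direction, and the test is symmetric in its arguments.

# The statistics layer

The rank-sum comparison enumerates all group assignments exactly for
combined $n \le 12$ (ties handled by mid-ranks over the enumeration) and
otherwise uses the tie-corrected normal approximation without continuity
correction; the two paths are compared at the boundary in the tests, and
the exact path is validated against brute-force enumeration and
`stats::wilcox.test`. The 2x2 co-occurrence test enumerates the
hypergeometric support and sums probabilities at most that of the
observed table; the odds ratio gets a 0.5 continuity correction only
when a cell is zero, flagged. These exact small-sample tests are
implemented in-package because their exact behaviour is part of the
package's contract; the base-R equivalents serve as independent
cross-checks in the test suite, never as the implementation.

Copy-number adjustment multiplies FPKM by $2/CN_{\mathrm{neighbor}}$:
normalizing to the *diploid* state rather than dividing by raw CN keeps
adjusted and unadjusted values in the same units and makes the
adjustment the identity at CN 2 (the source analysis says only
"normalized to copy number"; this is the package's resolution of that
ambiguity). The dosage model is ordinary least squares with tumor type
as a factor (reference `Other`), 95% t-intervals, and multi-sample
patients collapsed to per-patient means *before* fitting -- collapsing
afterwards (or not at all) weights multiply-profiled patients and is
demonstrably different in the tests. Rank-deficient designs are refused
with the collinear columns named.

Differential expression is a plain per-gene OLS on $\log_2(\mathrm{FPKM}+1)$
with carrier and tumor-type covariates, one shared design solved by a
single QR decomposition; empirical-Bayes moderation and precision
weights are deliberately out of scope (count-level data and library
sizes do not exist in the FPKM world this models), so the test surface
is planted-signal recovery and permutation-null cleanliness rather than
numerical equivalence with moderated pipelines. Bonferroni
$q = \min(1, p \cdot n_{\mathrm{genes}})$ with pass gates $q < 0.1$ and
$|\log_2 FC| \ge 1$; zero-variance genes get $p = 1$, a flag, and can
never pass. Testing is restricted to a caller-supplied gene list, by
contract the autosomal protein-coding genes.

ORF-screen utilities compute $\log_2((\mathrm{late}+pc)/(\mathrm{early}+pc))$
-- negative meaning the construct depleted, i.e. toxicity -- and compare
two isoforms' per-cell-line log fold changes with a paired two-tailed t
test.

# Pipeline, determinism and problem sizes

`runPipeline()` chains simulate, call, time, model, DE and report into an
output directory with a JSON manifest (package version, config, caller
thresholds, input digests, per-stage status). One master seed drives
everything; stage sub-seeds derive from it through a fixed affine map
(`subSeed()`), so identical config and seed give byte-identical stage
outputs, which the tests assert literally. Degenerate cohorts (no
carriers, no informative timing, too few groups) skip downstream stages
gracefully and say so in report and manifest; genuine stage failures
abort with the stage named and the manifest marked incomplete.

The shipped validation sizes are: 200-sample cohorts (with depth tracks)
for caller recovery, 500 histories for timing soundness, $n = 1000$ with
200 replicates for dosage-model CI coverage, and 2000 genes with 100
label permutations for DE calibration -- sizes at which the binomial
wobble of the measured rates is comfortably inside the asserted bands
while a full run of the suite stays in the minutes range on one core.

# What passing tests do and do not show

The generator emulates the *statistical structure* of consensus tumor
callsets: piecewise-constant absolute copy number, junction orientations,
binned depth ratios, FPKM-scale expression with tumor-type structure. It
does not emulate subclonality, germline variation, complex rearrangement
grammars (chromothripsis, breakage-fusion-bridge), caller-specific
artifacts, or read-level noise -- all deliberate non-goals. Recovery
results on this cohort therefore demonstrate that the implementations are
*correct against their definitions* (and the generator's inverse), not
that the thresholds are optimal for any particular real dataset; on real
data the rescue thresholds especially are decisions that replace a
manual review, not reconstructions of it, and should be revisited per
cohort.

Known limitations: the caller assumes one deletion event per locus per
sample for timing (multiple overlapping candidates are all reported, but
the per-sample verdict uses the first focal call); haplotype phase is
inferred only locally from flank/inside consistency, which is exactly as
much as unphased major/minor copy number permits; and purity mixing is a
simple linear blend with no subclonal structure.
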