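# ampliDel

Calling, timing and dosage-modelling of focal deletions nested inside
somatic amplifications.

## The scientific problem

Some tumors amplify a chromosomal region to drive an oncogene, then
surgically delete a small piece of it again. The motivating case is
*BRD4*: it rides along inside *CCNE1*-driven chromosome 19 amplicons in
breast, ovarian and endometrial cancers, but high *BRD4* expression is
toxic, so a recurrent sub-100-kbp deletion of its promoter-proximal
region appears selectively *on top of* the amplification. Analyzing this
pattern needs three connected pieces, and this package provides all of
them for anyone studying amplification-embedded deletions at a locus of
interest:

- **A focal-deletion caller** that combines copy-number segment dips, SV
  junction orientations (both breakends pointing outward from the lost
  interval), a read-depth *rescue* pathway for deletions that never
  received a segment-level call, and a *relative-loss* classification
  against a neighbor gene for non-focal cases.
- **Event-timing inference** from allele-specific copy number. If the
  amplified haplotype shows loss of heterozygosity inside the deletion,
  the deletion came first (there was nothing left to amplify); if it
  shows a non-zero reduced copy number, the amplification came first.
  Enrichment of one order across carriers is tested with the exact
  one-sided binomial tail `sum(choose(n, k:n)) / 2^n` — for 11
  amplification-first among 13 informative carriers this is
  92/8192 ≈ 0.011.
- **A gene-dosage expression layer**: OLS of target-gene FPKM on tumor
  type, absolute copy number and focal-deletion status
  (`FPKM ~ β₀,type + β_cn·CN + β_del·del`); copy-number-adjusted
  expression (`FPKM × 2 / CN_neighbor`); per-gene differential
  expression on log2(FPKM+1) with Bonferroni *q* < 0.1 and ≥2-fold
  gates; exact rank-sum and Fisher tests; ORF-screen log-fold-change
  utilities.

Because the cohort data this kind of analysis runs on are
access-controlled, the package ships a synthetic tumor-cohort generator
(`simulateCohort()`) with a complete ground-truth ledger — planted
amplifications, deletions, event orders, affected haplotypes, expression
coefficients — which is the oracle for every guarantee in the test
suite.

## Worked example

```r
library(ampliDel)

cfg    <- simConfig(nSamples = 60L, pScnaDropout = 0.2)  # 20% of planted
cohort <- simulateCohort(cfg, seed = 42)                 # deletions lack a CN call
layout <- defaultGenomeLayout()

calls <- callFocalDeletions(cohort$segments, cohort$junctions, cohort$depth,
                            target = layout@target, neighbor = layout@neighbor)
table(calls$evidence_class)
#> rescued    scna
#>       2      10
head(calls[, c("sample", "start", "end", "evidence_class", "cn_inside", "cn_flank")], 4)
#>   sample   start     end evidence_class cn_inside cn_flank
#> 8  S0007 3020957 3061750           scna         2        3
#> 3  S0010 3031019 3055414           scna         1        3
#> 2  S0011 3036135 3050670           scna         2        3
#> 1  S0015 3032426 3077939           scna         3        4
```

Twelve samples carry focal deletions: ten found from segment dips
(`scna`), two recovered by the read-depth rescue (`rescued`) because
their segment tables show no dip — `cn_inside`/`cn_flank` report the
copy number inside the event versus its flanks.

```r
timing <- runTiming(calls, cohort$segments, layout@target)
timing$summary
#> Event-order enrichment: 6 amplification-first vs 2 deletion-first (8 informative)
#>   exact binomial p = 0.1445, one-sided (direction of observed majority), toward amplification_first
```

Eight carriers had usable allelic copy number; six look
amplification-first, two deletion-first (at this small n the exact
binomial tail, 0.14, is unsurprisingly not significant).

```r
fpkm <- SummarizedExperiment::assay(cohort$expression, "fpkm")["BRD4L", ]
cn   <- locusCN(cohort$segments, layout@neighbor)   # neighbor CN as dosage covariate
fit  <- fitDosageModel(unname(fpkm), unname(cn[names(fpkm)]),
                       names(fpkm) %in% carrierSamples(calls),
                       cohort$metadata$tumor_type, cohort$metadata$patient)
fit
#> Dosage linear model (n = 60 patients, reference type Other)
#>          term estimate ci_lower ci_upper
#> 1 (Intercept)    10.32     6.81    13.83
#> 2          cn     4.24     3.22     5.27
#> 3     delTRUE    -7.22   -10.28    -4.15
#> 4    typeBRCA     8.95     6.09    11.81
#> 5      typeOV    25.57    22.56    28.59
#> 6    typeUCEC    11.54     8.52    14.56
```

The fitted coefficients bracket the generative ones (per-copy slope 3.6,
deletion offset −6.3, ovarian contrast 26.1): each 95% CI covers its
generative value. `runPipeline(outDir, cfg, seed)` chains all stages and
writes segments/junctions/depth/expression files, calls, timing, model
fit, DE table, a human-readable report and a JSON run manifest;
`inst/scripts/run-pipeline.R` is a thin command-line wrapper over it.

## Layout

- `R/simulate.R` — cohort generator + truth ledger, expression emission,
  DE matrix generator
- `R/io.R` — SEG/BEDPE/BED/bedGraph/TSV/JSON readers and writers
  (0-based half-open on disk, GRanges conventions in memory)
- `R/caller.R` — locus CN, amplification status, the three calling
  pathways
- `R/timing.R` — allelic timing classifier, exact binomial test, cohort
  driver
- `R/stats-tests.R` — exact rank-sum/Fisher, dosage model, DE, ORF
  utilities
- `R/pipeline.R` — end-to-end orchestration with manifest and report
- `vignettes/methods.Rmd` — model assumptions, parameter rationale,
  numerical choices, limitations
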