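test_that("identical config and seed give identical cohorts", {
  cfg <- simConfig(nSamples = 8L, pScnaDropout = 0.3)
  a <- simulateCohort(cfg, seed = 42)
  b <- simulateCohort(cfg, seed = 42)
  expect_identical(a$truth, b$truth)
  expect_identical(a$segments, b$segments)
  expect_identical(junctionTable(a$junctions), junctionTable(b$junctions))
  expect_identical(lapply(a$depth, depthRatio), lapply(b$depth, depthRatio))
  expect_identical(SummarizedExperiment::assay(a$expression, "fpkm"),
                   SummarizedExperiment::assay(b$expression, "fpkm"))
  c2 <- simulateCohort(cfg, seed = 43)
  expect_false(identical(a$truth$amp_cn, c2$truth$amp_cn))
})

test_that("amplification-first deletion leaves non-zero copies inside", {
  # forced history: amplification to 4 copies, then a deletion removing one
  cfg <- simConfig(nSamples = 1L, pAmplification = 1,
                   ampTotalCnRange = c(4L, 4L), pFocalDelGivenAmp = 1,
                   pDeletionFirst = 0, pDelOnAmpHaplotype = 1)
  ch <- simulateCohort(cfg, seed = 2, emitDepth = FALSE)
  tr <- ch$truth
  expect_equal(tr$event_order, "amp_first")
  seg <- ch$segments
  inDel <- BiocGenerics::start(seg) == tr$del_start
  expect_equal(totalCN(seg)[inDel], 3)       # 4 minus one amplified copy
  expect_equal(minorCN(seg)[inDel], 1)       # minor haplotype untouched
  # deletion-first instead: the amplified haplotype has nothing left inside
  cfg2 <- simConfig(nSamples = 1L, pAmplification = 1,
                    ampTotalCnRange = c(4L, 4L), pFocalDelGivenAmp = 1,
                    pDeletionFirst = 1, pDelOnAmpHaplotype = 1)
  ch2 <- simulateCohort(cfg2, seed = 2, emitDepth = FALSE)
  inDel2 <- BiocGenerics::start(ch2$segments) == ch2$truth$del_start
  expect_equal(totalCN(ch2$segments)[inDel2], 1)
  expect_equal(minorCN(ch2$segments)[inDel2], 0)   # LOH
})

test_that("event-free config yields a fully diploid cohort with no junctions", {
  cfg <- simConfig(nSamples = 6L, pAmplification = 0,
                   pFocalDelGivenNoAmp = 0)
  ch <- simulateCohort(cfg, seed = 9, emitDepth = FALSE)
  expect_equal(length(ch$junctions), 0L)
  expect_true(all(totalCN(ch$segments) == 2))
  expect_true(all(minorCN(ch$segments) == 1))
  expect_true(all(ch$truth$event_order == "na"))
})

test_that("amplification frequency matches the configured rate (binomial bounds)", {
  cfg <- simConfig(nSamples = 500L)
  ch <- simulateCohort(cfg, seed = 7, emitDepth = FALSE)
  nAmp <- sum(!is.na(ch$truth$amp_cn))
  # exact central 99.7% binomial band at p = 0.4
  lo <- qbinom(0.0013, 500, 0.4); hi <- qbinom(0.9987, 500, 0.4)
  expect_gte(nAmp, lo)
  expect_lte(nAmp, hi)
})

test_that("allelic bookkeeping: a deletion removes one copy from one haplotype", {
  cfg <- simConfig(nSamples = 40L, pAmplification = 1,
                   pFocalDelGivenAmp = 1, pDeletionFirst = 0.3,
                   pDelOnAmpHaplotype = 0.6)
  ch <- simulateCohort(cfg, seed = 13, emitDepth = FALSE)
  tr <- ch$truth
  seg <- ch$segments
  for (i in seq_len(nrow(tr))) {
    if (!tr$allelic_emitted[i]) next
    s <- tr$sample[i]
    sub <- seg[segSample(seg) == s]
    inDel <- BiocGenerics::start(sub) == tr$del_start[i]
    left <- BiocGenerics::end(sub) == tr$del_start[i] - 1
    hapIn <- c(totalCN(sub)[inDel] - minorCN(sub)[inDel],
               minorCN(sub)[inDel])
    hapOut <- c(totalCN(sub)[left] - minorCN(sub)[left],
                minorCN(sub)[left])
    # minor + major always recombine to the total
    expect_equal(sum(hapIn), totalCN(sub)[inDel])
    # exactly one haplotype lost copies; the other is unchanged
    if (tr$event_order[i] == "del_first" && tr$del_on_amp_haplotype[i]) {
      expect_equal(sort(hapIn), sort(c(0, min(hapOut))))
    } else {
      d <- sort(hapOut) - sort(hapIn)
      expect_equal(sum(d != 0), 1L)
    }
  }
})

test_that("expression means follow the dosage model exactly at zero noise", {
  co <- expressionCoeffs(baselineByType = c(OV = 26.1), betaCN = 3.6,
                         betaDel = -6.3)
  tr <- data.frame(sample = c("a", "b"), tumor_type = "OV", patient = c("a", "b"),
                   cn_covariate = 4, del_start = c(NA, 100))
  fpkm <- SummarizedExperiment::assay(emitExpression(tr, co, 0, 1), "fpkm")
  expect_equal(unname(fpkm["BRD4L", "a"]), 26.1 + 3.6 * 4)   # 40.5
  expect_equal(unname(fpkm["BRD4L", "b"]), 40.5 - 6.3)       # 34.2
  # isoform split: secondary short isoform far below the dominant one
  expect_lt(fpkm["BRD4L-shortB", "a"], fpkm["BRD4L-shortA", "a"] / 5)
  expect_gt(fpkm["BRD4L-long", "a"], fpkm["BRD4L-shortA", "a"])
})

test_that("expression noise is centred: residual mean within 3 SEM of zero", {
  cfg <- simConfig(nSamples = 1000L, exprNoiseSd = 5)
  ch <- simulateCohort(cfg, seed = 21, emitDepth = FALSE)
  fpkm <- SummarizedExperiment::assay(ch$expression, "fpkm")["BRD4L", ]
  resid <- unname(fpkm) - ch$truth$expr_mean_gene
  expect_lt(abs(mean(resid)), 3 * 5 / sqrt(1000))
})

test_that("depth ratio is calibrated to CN/2 in the Poisson limit", {
  cfg <- simConfig(nSamples = 4L, pAmplification = 0,
                   pFocalDelGivenNoAmp = 0, depthDispersion = Inf)
  ch <- simulateCohort(cfg, seed = 5)
  ratios <- unlist(lapply(ch$depth, depthRatio))
  expect_gte(length(ratios), 10000L)
  expect_lt(abs(mean(ratios) - 1), 0.02)   # local CN 2 everywhere
  # amplified sample: bins inside the amplification track CN/2
  cfg2 <- simConfig(nSamples = 2L, pAmplification = 1,
                    ampTotalCnRange = c(6L, 6L), pFocalDelGivenAmp = 0,
                    depthDispersion = Inf)
  ch2 <- simulateCohort(cfg2, seed = 6)
  tr2 <- ch2$truth
  d <- ch2$depth[[1]]
  inside <- BiocGenerics::start(d) >= tr2$amp_start[1] &
    BiocGenerics::end(d) <= tr2$amp_end[1]
  expect_lt(abs(mean(depthRatio(d)[inside]) - 3), 0.06)      # 2% of 3
})

test_that("dropout removes the segment dip but keeps junctions and depth", {
  cfg <- simConfig(nSamples = 1L, pAmplification = 1,
                   ampTotalCnRange = c(5L, 5L), pFocalDelGivenAmp = 1,
                   pDeletionFirst = 0, pDelOnAmpHaplotype = 1,
                   pScnaDropout = 1)
  ch <- simulateCohort(cfg, seed = 8)
  tr <- ch$truth
  expect_false(tr$scna_emitted)
  # no segment boundary at the deletion
  expect_false(any(BiocGenerics::start(ch$segments) == tr$del_start))
  # but the deletion junction is there, with outward orientations
  jt <- junctionTable(ch$junctions)
  del <- jt[jt$strand1 == "+" & jt$strand2 == "-", ]
  expect_equal(del$pos1 + 1, tr$del_start)
  expect_equal(del$pos2, tr$del_end)
  # and the depth dips inside
  d <- ch$depth[[1]]
  inside <- BiocGenerics::start(d) >= tr$del_start &
    BiocGenerics::end(d) <= tr$del_end
  outside <- BiocGenerics::start(d) >= tr$amp_start &
    BiocGenerics::end(d) <= tr$amp_end & !inside
  expect_lt(mean(depthRatio(d)[inside]), mean(depthRatio(d)[outside]))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(simConfig(pAmplification = 1.4), "pAmplification")
  expect_error(simConfig(nSamples = 0L), "nSamples")
  expect_error(simConfig(delLengthRange = c(5000L, 90000L)),
               "delLengthRange")
  expect_error(simConfig(tumorTypeWeights = c(OV = 0.5, BRCA = 0.1)),
               "tumorTypeWeights")
  expect_error(simConfig(depthDispersion = 0), "depthDispersion")
})
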