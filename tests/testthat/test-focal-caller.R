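test_that("locusCN is the overlap-weighted mean and matches brute force", {
  seg <- CNSegments(c("s1", "s1"), "chrS", c(1, 5001), c(5000, 10000),
                    total_cn = c(2, 4), minor_cn = 1)
  expect_equal(unname(locusCN(seg, GeneLocus("g", "chrS", 1, 10000))), 3)
  one <- CNSegments("s1", "chrS", 1, 1e6, total_cn = 6.7, minor_cn = 1)
  expect_equal(unname(locusCN(one, GeneLocus("g", "chrS", 1000, 2000))), 6.7)
  # uncovered samples are flagged missing
  expect_true(is.na(locusCN(one, GeneLocus("g", "chr2", 1, 100))))

  # random segmentations against a base-by-base oracle
  set.seed(404)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    brk <- sort(sample(1000:9000, k - 1))
    starts <- c(1, brk + 1); ends <- c(brk, 10000)
    cns <- round(runif(k, 0, 8), 2)
    seg <- CNSegments(rep("s", k), "chrS", starts, ends, cns, NA)
    ls <- sample(500:4000, 1); le <- ls + sample(500:5000, 1)
    expect_equal(unname(locusCN(seg, GeneLocus("g", "chrS", ls, le))),
                 bruteLocusMeanCN(starts, ends, cns, ls, le),
                 tolerance = 1e-9)
  }
})

test_that("amplification status uses a strict total-CN threshold", {
  locus <- GeneLocus("g", "chrS", 1000, 2000)
  at2 <- CNSegments("s1", "chrS", 1, 1e5, 2.0, 1)
  expect_false(unname(isAmplified(at2, locus)))            # strictly above 2
  # a deletion segment at CN 3.3 inside an amplified background still
  # counts as amplified via the flanking CN-5 segments
  seg <- ampDipSegments(delStart = 1200, delEnd = 1800, ampStart = 500,
                        ampEnd = 5000, totalAmp = 5, totalIn = 3.3,
                        minorIn = 1)
  expect_true(unname(isAmplified(seg, locus)))
  off <- CNSegments("s1", "chr9", 1, 1e5, 8, 1)
  expect_false(unname(isAmplified(off, locus)))
})

test_that("SCNA-supported focal deletions are called from dip geometry", {
  locus <- targetLocus()
  seg <- ampDipSegments(delStart = 3020001, delEnd = 3060000,
                        totalAmp = 5, totalIn = 3)
  jx <- deletionJunction(delStart = 3020001, delEnd = 3060000)
  calls <- callScnaFocalDeletions(seg, jx, locus)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$evidence_class, "scna")
  expect_equal(calls$start, 3020001)
  expect_equal(calls$end, 3060000)
  expect_equal(calls$cn_inside, 3)
  expect_equal(calls$cn_flank, 5)
  expect_equal(calls$junction_ids, "jx1")

  # the same geometry above the focal size cap is not called
  wide <- ampDipSegments(delStart = 3000001, delEnd = 3150001,
                         totalAmp = 5, totalIn = 3)
  expect_equal(nrow(callScnaFocalDeletions(wide, SVJunctions(), locus)), 0L)

  # a dip shallower than relLossDelta is not a copy-loss event
  shallow <- ampDipSegments(delStart = 3020001, delEnd = 3060000,
                            totalAmp = 5, totalIn = 4.7)
  expect_equal(nrow(callScnaFocalDeletions(shallow, SVJunctions(), locus)), 0L)

  # a dip far from the locus is not attributed to it
  away <- ampDipSegments(delStart = 1600001, delEnd = 1640000,
                         totalAmp = 5, totalIn = 3)
  expect_equal(nrow(callScnaFocalDeletions(away, SVJunctions(), locus)), 0L)
})

test_that("caller reproduces the truth ledger exactly without dropout", {
  cfg <- simConfig(nSamples = 60L)
  ch <- simulateCohort(cfg, seed = 31, emitDepth = FALSE)
  calls <- callScnaFocalDeletions(ch$segments, ch$junctions, targetLocus())
  truthDel <- ch$truth$sample[!is.na(ch$truth$del_start)]
  expect_setequal(carrierSamples(calls), truthDel)
  # called intervals are the planted ones, sample-exact
  m <- merge(calls, ch$truth, by = "sample")
  expect_equal(m$start, m$del_start)
  expect_equal(m$end, m$del_end)
})

test_that("shrinking the size cap never adds calls (monotonicity)", {
  cfg <- simConfig(nSamples = 40L)
  ch <- simulateCohort(cfg, seed = 17, emitDepth = FALSE)
  caps <- c(100000, 60000, 30000, 15000)
  prev <- NULL
  for (cap in caps) {
    calls <- callScnaFocalDeletions(ch$segments, ch$junctions, targetLocus(),
                                    callerParams(maxEventBp = cap))
    key <- paste(calls$sample, calls$start, calls$end)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("read-depth rescue requires a drop, matching steps, and deletion orientation", {
  locus <- targetLocus()
  jx <- deletionJunction(delStart = 3020001, delEnd = 3050000)
  dip <- dipDepthTrack(delStart = 3020001, delEnd = 3050000,
                       flankRatio = 2.5, insideRatio = 1.5)
  calls <- rescueFromDepth(jx, dip, locus)
  expect_equal(nrow(calls), 1L)                 # 40% drop > 10% threshold
  expect_equal(calls$evidence_class, "rescued")
  expect_equal(calls$start, 3020001)
  expect_equal(calls$end, 3050000)
  expect_equal(calls$cn_inside, 3, tolerance = 1e-6)
  expect_equal(calls$cn_flank, 5, tolerance = 1e-6)

  # flat track: no depth drop, no call
  flat <- dipDepthTrack(delStart = 3020001, delEnd = 3050000,
                        flankRatio = 2.5, insideRatio = 2.5)
  expect_equal(nrow(rescueFromDepth(jx, flat, locus)), 0L)

  # duplication-like (-,+) orientation over a genuine drop: orientation gate
  dup <- SVJunctions("s1", "chrS", 3020000, "-", "chrS", 3050000, "+")
  expect_equal(nrow(rescueFromDepth(dup, dip, locus)), 0L)

  # depth step displaced from the breakends: step-location gate
  shifted <- dipDepthTrack(delStart = 3025001, delEnd = 3045000,
                           flankRatio = 2.5, insideRatio = 0.5)
  expect_equal(nrow(rescueFromDepth(jx, shifted, locus)), 0L)

  # track that does not cover the flanks: candidate skipped with a warning
  short <- dipDepthTrack(from = 3020001, to = 3050000,
                         delStart = 3020001, delEnd = 3050000,
                         flankRatio = 2.5, insideRatio = 1.5)
  expect_warning(out <- rescueFromDepth(jx, short, locus), "does not cover")
  expect_equal(nrow(out), 0L)
})

test_that("raising the rescue drop threshold never adds rescued calls", {
  jx <- deletionJunction(delStart = 3020001, delEnd = 3050000)
  dip <- dipDepthTrack(delStart = 3020001, delEnd = 3050000,
                       flankRatio = 2.5, insideRatio = 2.1)   # 16% drop
  prev <- Inf
  for (frac in c(0.05, 0.1, 0.2, 0.4)) {
    n <- nrow(rescueFromDepth(jx, dip, targetLocus(),
                              callerParams(rescueDropFrac = frac)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("relative copy-loss versus the neighbor is called and flagged non-focal", {
  # target at CN 3.3 against neighbor at 4.5: a relative loss
  seg <- CNSegments(rep("s1", 2), "chrS", c(3000001, 3120001),
                    c(3100000, 3180000), total_cn = c(3.3, 4.5),
                    minor_cn = 1)
  calls <- callRelativeLoss(seg, targetLocus(), neighborLocus())
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$evidence_class, "relative_loss")
  expect_false(calls$focal)
  expect_equal(calls$cn_inside, 3.3)
  expect_equal(calls$cn_flank, 4.5)
  # relative-loss carriers are not part of the focal carrier set
  expect_equal(length(carrierSamples(calls)), 0L)

  # equal copy number: no call
  eq <- CNSegments(rep("s1", 2), "chrS", c(3000001, 3120001),
                   c(3100000, 3180000), total_cn = 4, minor_cn = 1)
  expect_equal(nrow(callRelativeLoss(eq, targetLocus(), neighborLocus())), 0L)

  # missing neighbor coverage: sample skipped with a warning
  half <- CNSegments("s1", "chrS", 3000001, 3100000, 4, 1)
  expect_warning(out <- callRelativeLoss(half, targetLocus(), neighborLocus()),
                 "missing locus copy number")
  expect_equal(nrow(out), 0L)
})

test_that("a carrier mix of 16 segment-supported plus 6 rescued is recovered", {
  # two sub-cohorts: 16 samples with emitted SCNA dips, 6 with dropout
  cfgA <- simConfig(nSamples = 16L, pAmplification = 1,
                    pFocalDelGivenAmp = 1, pScnaDropout = 0)
  cfgB <- simConfig(nSamples = 6L, pAmplification = 1,
                    pFocalDelGivenAmp = 1, pScnaDropout = 1)
  a <- simulateCohort(cfgA, seed = 51)
  b <- simulateCohort(cfgB, seed = 52)
  jb <- junctionTable(b$junctions); jb$sample <- sub("^S", "T", jb$sample)
  segB <- b$segments; S4Vectors::mcols(segB)$sample <-
    sub("^S", "T", segSample(segB))
  depthB <- b$depth; names(depthB) <- sub("^S", "T", names(depthB))
  depthB <- lapply(names(depthB), function(s) {
    tr <- depthB[[s]]
    ReadDepthTrack(s, as.character(GenomeInfoDb::seqnames(tr)),
                   BiocGenerics::start(tr), BiocGenerics::end(tr),
                   depthRatio(tr))
  })
  names(depthB) <- sub("^S", "T", names(b$depth))
  segAll <- CNSegments(c(segSample(a$segments), segSample(segB)),
                       c(as.character(GenomeInfoDb::seqnames(a$segments)),
                         as.character(GenomeInfoDb::seqnames(segB))),
                       c(BiocGenerics::start(a$segments), BiocGenerics::start(segB)),
                       c(BiocGenerics::end(a$segments), BiocGenerics::end(segB)),
                       c(totalCN(a$segments), totalCN(segB)),
                       c(minorCN(a$segments), minorCN(segB)))
  ja <- junctionTable(a$junctions)
  jall <- rbind(ja, jb)
  jxAll <- SVJunctions(jall$sample, jall$chrom1, jall$pos1, jall$strand1,
                       jall$chrom2, jall$pos2, jall$strand2)
  calls <- callFocalDeletions(segAll, jxAll, c(a$depth, depthB),
                              targetLocus(), neighborLocus())
  expect_equal(length(carrierSamples(calls)), 22L)
  tab <- table(calls$evidence_class[calls$focal])
  expect_equal(unname(tab["scna"]), 16L)
  expect_equal(unname(tab["rescued"]), 6L)
  # evidence classes partition samples: no interval called under both
  byClass <- split(calls$sample, calls$evidence_class)
  expect_equal(length(intersect(byClass$scna, byClass$rescued)), 0L)
})
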