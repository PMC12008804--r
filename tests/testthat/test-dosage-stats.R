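test_that("rank-sum comparison: exact path, degenerate input, tie-corrected approximation", {
  gc <- compareLocusCN(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc$p_value, 0.1)      # 2 of the 20 assignments are as extreme
  expect_equal(gc$test, "exact")

  same <- compareLocusCN(c(2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_true(same$zero_variance)

  # the approximation equals the reference tie-corrected normal p
  set.seed(77)
  for (rep in 1:10) {
    x <- sample(1:6, 9, replace = TRUE); y <- sample(2:8, 11, replace = TRUE)
    ours <- compareLocusCN(x, y)
    expect_equal(ours$test, "normal_approx")
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # exact and approximate paths agree to first order at the size boundary
  x <- c(1.2, 3.4, 0.8, 5.1, 2.2, 4.4); y <- c(2.9, 6.3, 1.7, 3.8, 5.5, 0.4)
  pe <- compareLocusCN(x, y, exactMax = 12L)$p_value
  pa <- compareLocusCN(x, y, exactMax = 2L)$p_value
  expect_lt(abs(pe - pa), 0.1)
})

test_that("rank-sum power grows with sample size when carriers run higher", {
  pAt <- function(n, seed) {
    set.seed(seed)
    compareLocusCN(rnorm(n, 4, 1), rnorm(n, 2.8, 1))$p_value
  }
  p20 <- mean(vapply(1:20, function(s) pAt(10, s), numeric(1)))
  p100 <- mean(vapply(1:20, function(s) pAt(60, s), numeric(1)))
  expect_lt(p100, p20)
})

test_that("co-occurrence Fisher test matches the hypergeometric closed form", {
  expect_equal(cooccurrenceFisher(3, 1, 1, 3)$p_value, 34 / 70)
  expect_equal(cooccurrenceFisher(0, 0, 2, 3)$p_value, 1)  # empty margin
  expect_error(cooccurrenceFisher(-1, 1, 1, 1), "negative")
  or <- cooccurrenceFisher(4, 1, 1, 4)
  expect_equal(or$odds_ratio, 16)
  expect_false(or$continuity)
  withZero <- cooccurrenceFisher(4, 0, 1, 4)
  expect_true(withZero$continuity)   # 0.5 correction applied and flagged
})

test_that("deletions co-occur with amplification in the generated cohort", {
  cfg <- simConfig(nSamples = 500L)
  ch <- simulateCohort(cfg, seed = 61, emitDepth = FALSE)
  tr <- ch$truth
  amp <- !is.na(tr$amp_cn); del <- !is.na(tr$del_start)
  fish <- cooccurrenceFisher(sum(amp & del), sum(amp & !del),
                             sum(!amp & del), sum(!amp & !del))
  expect_lt(fish$p_value, 0.05)
  expect_gt(fish$odds_ratio, 1)
})

test_that("copy-number adjustment normalizes to the diploid state", {
  seg <- CNSegments(rep(c("a", "b"), each = 1), "chrS",
                    c(3120001, 3120001), c(3180000, 3180000),
                    total_cn = c(2, 4), minor_cn = 1)
  co <- expressionCoeffs()
  tr <- data.frame(sample = c("a", "b"), tumor_type = "OV",
                   patient = c("a", "b"), cn_covariate = 2,
                   del_start = NA)
  se <- emitExpression(tr, co, 0, 1)
  adj <- cnAdjustedExpression(se, seg, neighborLocus())
  raw <- SummarizedExperiment::assay(se, "fpkm")
  out <- SummarizedExperiment::assay(adj, "fpkm")
  expect_equal(out[, "a"], raw[, "a"])           # identity at CN 2
  expect_equal(out[, "b"], raw[, "b"] / 2)       # halved at CN 4
  # samples without neighbor copy number are dropped with a warning
  segHalf <- CNSegments("a", "chrS", 3120001, 3180000, 2, 1)
  expect_warning(adj2 <- cnAdjustedExpression(se, segHalf, neighborLocus()),
                 "dropping sample")
  expect_equal(colnames(adj2), "a")
})

test_that("carriers show reduced CN-adjusted target expression across a cohort", {
  cfg <- simConfig(nSamples = 300L)
  ch <- simulateCohort(cfg, seed = 71, emitDepth = FALSE)
  adj <- cnAdjustedExpression(ch$expression, ch$segments, neighborLocus())
  fpkm <- SummarizedExperiment::assay(adj, "fpkm")["BRD4L", ]
  del <- !is.na(ch$truth$del_start)[match(colnames(adj), ch$truth$sample)]
  cmp <- compareLocusCN(unname(fpkm[del]), unname(fpkm[!del]))
  expect_lt(cmp$medians[1], cmp$medians[2])
  expect_lt(cmp$p_value, 0.05)
})

test_that("dosage model recovers generative coefficients exactly at zero noise", {
  cfg <- simConfig(nSamples = 400L, exprNoiseSd = 0)
  ch <- simulateCohort(cfg, seed = 81, emitDepth = FALSE)
  tr <- ch$truth
  fpkm <- SummarizedExperiment::assay(ch$expression, "fpkm")["BRD4L", ]
  fit <- suppressWarnings(
    fitDosageModel(unname(fpkm), tr$cn_covariate, !is.na(tr$del_start),
                   tr$tumor_type, tr$patient))
  co <- fit$coefficients
  est <- function(term) co$estimate[co$term == term]
  expect_equal(est("cn"), 3.6, tolerance = 1e-10)
  expect_equal(est("delTRUE"), -6.3, tolerance = 1e-8)
  expect_equal(est("typeOV"), 26.1, tolerance = 1e-9)
  expect_equal(est("(Intercept)"), 12, tolerance = 1e-9)
  expect_true(all(co$ci_lower <= co$estimate & co$estimate <= co$ci_upper))
})

test_that("multi-sample patients are collapsed to means before fitting", {
  # one patient profiled twice: the collapsed fit must differ from the fit
  # on raw duplicated rows
  fpkm <- c(10, 30, 20, 25, 14, 22)
  cn <- c(2, 6, 4, 4, 3, 5)
  del <- c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE)
  type <- c("OV", "OV", "Other", "Other", "OV", "Other")
  pat <- c("p1", "p1", "p2", "p3", "p4", "p5")
  collapsed <- fitDosageModel(fpkm, cn, del, type, pat)
  raw <- fitDosageModel(fpkm, cn, del, type, patient = NULL)
  expect_equal(collapsed$n, 5)
  expect_equal(raw$n, 6)
  expect_false(isTRUE(all.equal(
    collapsed$coefficients$estimate, raw$coefficients$estimate)))
  # a patient whose samples disagree on tumor type is an input error
  expect_error(fitDosageModel(fpkm, cn, del,
                              c("OV", "BRCA", type[3:6]), pat),
               "inconsistent tumor types")
})

test_that("collinear designs are rejected naming the offending columns", {
  # deletion status perfectly aliased with tumor type
  type <- rep(c("OV", "Other"), each = 10)
  del <- type == "OV"
  cn <- rep(c(2, 4), 10)
  fpkm <- 10 + 3 * cn + 5 * del + rnorm(20, 0, 0.1)
  expect_error(fitDosageModel(fpkm, cn, del, type), "collinear")
})

test_that("differential expression recovers planted signals and gates fold change", {
  d <- simulateDEMatrix(nSamples = 80L, nCarriers = 15L, nGenes = 500L,
                        nPlanted = 5L, log2fc = 2, seed = 12)
  types <- SummarizedExperiment::colData(d$expression)$tumor_type
  res <- differentialExpression(d$expression, d$carriers, types,
                                genes = d$testable)
  expect_setequal(res$gene[res$pass], d$planted)
  expect_true(all(res$q >= res$p))                  # Bonferroni dominance
  expect_true(!is.unsorted(res$p))                  # sorted by p

  # a 1.5-fold planted shift fails the 2-fold gate regardless of q
  d2 <- simulateDEMatrix(nSamples = 80L, nCarriers = 15L, nGenes = 500L,
                         nPlanted = 5L, log2fc = log2(1.5), noiseSd = 0.05,
                         seed = 13)
  res2 <- differentialExpression(d2$expression, d2$carriers,
                                 SummarizedExperiment::colData(d2$expression)$tumor_type,
                                 genes = d2$testable)
  hit <- res2[res2$gene %in% d2$planted, ]
  expect_true(all(hit$q < 0.1))                     # significant ...
  expect_true(all(abs(hit$log2fc) < 1))             # ... but below the gate
  expect_false(any(res2$pass))
})

test_that("the Bonferroni pass set only shrinks as the tested gene list grows", {
  d <- simulateDEMatrix(nSamples = 60L, nCarriers = 12L, nGenes = 600L,
                        nPlanted = 8L, log2fc = 1.4, noiseSd = 0.6,
                        seed = 14)
  types <- SummarizedExperiment::colData(d$expression)$tumor_type
  small <- d$testable[1:300]
  small <- union(small, d$planted)
  resSmall <- differentialExpression(d$expression, d$carriers, types,
                                     genes = small)
  resAll <- differentialExpression(d$expression, d$carriers, types,
                                   genes = d$testable)
  passSmall <- resSmall$gene[resSmall$pass]
  passAll <- resAll$gene[resAll$pass]
  expect_true(all(passAll[passAll %in% small] %in% passSmall))
})

test_that("zero-variance genes are flagged and never pass", {
  d <- simulateDEMatrix(nSamples = 40L, nCarriers = 8L, nGenes = 50L,
                        nPlanted = 2L, seed = 15)
  mat <- SummarizedExperiment::assay(d$expression, "fpkm")
  flatGene <- setdiff(d$testable, d$planted)[1]
  mat[flatGene, ] <- 7
  SummarizedExperiment::assay(d$expression, "fpkm") <- mat
  res <- differentialExpression(d$expression, d$carriers,
                                SummarizedExperiment::colData(d$expression)$tumor_type,
                                genes = d$testable)
  row <- res[res$gene == flatGene, ]
  expect_true(row$zero_variance)
  expect_equal(row$p, 1)
  expect_false(row$pass)
  expect_error(differentialExpression(d$expression,
                                      rep(c(TRUE, FALSE), c(1, 39)),
                                      genes = d$testable),
               "at least 2 carriers")
})

test_that("ORF log fold changes follow the toxicity sign convention", {
  expect_equal(orfLfc(100, 100), 0)
  expect_equal(orfLfc(100, 25), -2)      # depletion = growth deficit
  expect_equal(orfLfc(0, 8, pseudocount = 1), log2(9))
  expect_error(orfLfc(0, 0), "undefined")

  # a constant short-vs-long deficit with vanishing spread drives p down
  set.seed(301)
  long <- c(-0.1, 0.2, 0.05, -0.3, 0.15, 0)
  pBig <- orfIsoformCompare(long, long - 1 + rnorm(6, 0, 0.2))$p_value
  pTiny <- orfIsoformCompare(long, long - 1 + rnorm(6, 0, 0.001))$p_value
  expect_lt(pTiny, 1e-8)
  expect_lt(pTiny, pBig)
  # agrees with the reference paired t test
  set.seed(9)
  a <- rnorm(8); b <- a - 0.8 + rnorm(8, 0, 0.3)
  expect_equal(orfIsoformCompare(a, b)$p_value,
               t.test(b, a, paired = TRUE)$p.value)
})
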