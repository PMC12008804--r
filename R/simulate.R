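#' @importFrom stats rnorm rpois rnbinom runif
NULL

#' Generative coefficients of the expression dosage model
#'
#' Houses the linear dosage model used both to generate synthetic
#' expression and as the recovery target of \code{\link{fitDosageModel}}:
#' mean FPKM of the target gene in a sample of tumor type \eqn{t} with
#' absolute locus copy number \eqn{c} and focal-deletion indicator \eqn{d}
#' is \deqn{\mu = baseline_t + \beta_{cn} c + \beta_{del} d.}
#'
#' The default coefficients place the ovarian-vs-reference contrast at
#' 26.1 FPKM, the per-copy slope at 3.6 FPKM and the focal-deletion offset
#' at -6.3 FPKM, so that parameter-recovery tests target those values.
#'
#' @slot baselineByType named numeric vector of per-tumor-type intercepts
#'   (FPKM); must cover every tumor type in the simulation.
#' @slot betaCN FPKM per absolute copy.
#' @slot betaDel FPKM offset for focal-deletion carriers.
#' @export
setClass("ExpressionCoeffs",
         representation(baselineByType = "numeric", betaCN = "numeric",
                        betaDel = "numeric"))

setValidity("ExpressionCoeffs", function(object) {
  if (is.null(names(object@baselineByType)) ||
      any(!nzchar(names(object@baselineByType))))
    return("baselineByType must be a named vector")
  if (!all(is.finite(object@baselineByType)))
    return("baselineByType must be finite")
  if (length(object@betaCN) != 1L || !is.finite(object@betaCN))
    return("betaCN must be a finite scalar")
  if (length(object@betaDel) != 1L || !is.finite(object@betaDel))
    return("betaDel must be a finite scalar")
  TRUE
})

#' @describeIn ExpressionCoeffs constructor with the default dosage
#'   coefficients (reference tumor type \code{Other}; the \code{OV} minus
#'   \code{Other} contrast equals 26.1 FPKM).
#' @param baselineByType,betaCN,betaDel see slot documentation.
#' @export
expressionCoeffs <- function(baselineByType = c(Other = 12, BRCA = 21,
                                                UCEC = 23, OV = 38.1),
                             betaCN = 3.6, betaDel = -6.3) {
  new("ExpressionCoeffs", baselineByType = baselineByType,
      betaCN = betaCN, betaDel = betaDel)
}

#' Synthetic genome layout
#'
#' A single ~5 Mbp synthetic chromosome carrying three named loci: a driver
#' oncogene analog (\code{CCNE1L}), the target gene analog (\code{BRD4L})
#' with a designated promoter-proximal deletion window (the exon 1-intron 1
#' analog), and its adjacent neighbor (\code{NOTCH3L}) used for
#' copy-number normalization.  Amplifications span all three loci; planted
#' focal deletions fall inside the target window.  All calling and timing
#' logic is locus-relative, so a whole genome adds nothing.
#'
#' @slot chrom chromosome name.
#' @slot genomeLength chromosome length (bp).
#' @slot driver,target,neighbor \linkS4class{GeneLocus} objects; the target
#'   carries the deletion window.
#' @slot ampStartRange,ampEndRange numeric(2) ranges from which
#'   amplification boundaries are drawn uniformly.
#' @slot depthRegion \code{GRanges} over which binned read depth is emitted.
#' @export
setClass("GenomeLayout",
         representation(chrom = "character", genomeLength = "numeric",
                        driver = "GeneLocus", target = "GeneLocus",
                        neighbor = "GeneLocus", ampStartRange = "numeric",
                        ampEndRange = "numeric", depthRegion = "GRanges"))

setValidity("GenomeLayout", function(object) {
  if (object@ampStartRange[2] >= BiocGenerics::start(object@driver))
    return("ampStartRange must lie left of the driver locus")
  if (object@ampEndRange[1] <= BiocGenerics::end(object@neighbor))
    return("ampEndRange must lie right of the neighbor locus")
  if (length(locusWindow(object@target)) != 1L)
    return("target locus must carry a deletion window")
  TRUE
})

#' @describeIn GenomeLayout the default layout.
#' @export
defaultGenomeLayout <- function() {
  new("GenomeLayout",
      chrom = "chrS", genomeLength = 5e6,
      driver   = GeneLocus("CCNE1L",  "chrS", 2000001, 2040000),
      target   = GeneLocus("BRD4L",   "chrS", 3000001, 3100000,
                           windowStart = 3005001, windowEnd = 3080000),
      neighbor = GeneLocus("NOTCH3L", "chrS", 3120001, 3180000),
      ampStartRange = c(1500001, 1900000),
      ampEndRange   = c(3300001, 3800000),
      depthRegion = GRanges("chrS", IRanges(2800001, 3400000)))
}

#' Simulation configuration
#'
#' Parameters of the synthetic tumor-cohort generator.  Defaults define the
#' study conditions used throughout the package's tests; see the methods
#' vignette for the rationale behind each value.
#'
#' @slot nSamples number of tumor samples.
#' @slot tumorTypeWeights named probabilities of each tumor type.
#' @slot pAmplification probability a sample carries a large amplification
#'   spanning the driver, target and neighbor loci.
#' @slot ampTotalCnRange integer range of amplification total copy number.
#' @slot pFocalDelGivenAmp probability of a focal deletion nested in an
#'   amplification.
#' @slot pFocalDelGivenNoAmp background focal-deletion probability.
#' @slot delLengthRange bp range of planted deletion lengths (max must stay
#'   below the focal cap of 100 kbp and fit in the target window).
#' @slot pDeletionFirst probability the deletion precedes the amplification
#'   in the generative history.
#' @slot pDelOnAmpHaplotype probability the deletion hits the amplified
#'   haplotype (timing is only informative when it does).
#' @slot allelicMinBp deletions shorter than this are emitted with missing
#'   minor-allele copy number (too few phased SNPs to resolve).
#' @slot depthCoverage mean normal-sample depth per 200-bp bin.
#' @slot depthDispersion negative-binomial size parameter for binned depth
#'   (\code{Inf} gives the Poisson limit).
#' @slot exprCoeffs an \linkS4class{ExpressionCoeffs}.
#' @slot exprNoiseSd Gaussian FPKM noise standard deviation.
#' @slot pScnaDropout probability a planted focal deletion is emitted
#'   without a segment-level CN call (junctions and read depth only; the
#'   read-depth rescue scenario).
#' @slot purity tumor purity; emitted copy numbers are
#'   \code{purity * cn + (1 - purity) * 2}.
#' @slot genome a \linkS4class{GenomeLayout}.
#' @seealso \code{\link{simConfig}}, \code{\link{simulateCohort}}
#' @export
setClass("SimConfig",
         representation(nSamples = "integer", tumorTypeWeights = "numeric",
                        pAmplification = "numeric", ampTotalCnRange = "integer",
                        pFocalDelGivenAmp = "numeric",
                        pFocalDelGivenNoAmp = "numeric",
                        delLengthRange = "integer", pDeletionFirst = "numeric",
                        pDelOnAmpHaplotype = "numeric", allelicMinBp = "integer",
                        depthCoverage = "numeric", depthDispersion = "numeric",
                        exprCoeffs = "ExpressionCoeffs", exprNoiseSd = "numeric",
                        pScnaDropout = "numeric", purity = "numeric",
                        genome = "GenomeLayout"))

setValidity("SimConfig", function(object) {
  p <- function(field) {
    v <- slot(object, field)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      return(sprintf("invalid configuration: '%s' must be a probability in [0,1]",
                     field))
    NULL
  }
  for (f in c("pAmplification", "pFocalDelGivenAmp", "pFocalDelGivenNoAmp",
              "pDeletionFirst", "pDelOnAmpHaplotype", "pScnaDropout",
              "purity")) {
    msg <- p(f); if (!is.null(msg)) return(msg)
  }
  if (object@nSamples < 1L)
    return("invalid configuration: 'nSamples' must be >= 1")
  w <- object@tumorTypeWeights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-6 || is.null(names(w)))
    return("invalid configuration: 'tumorTypeWeights' must be named, non-negative and sum to 1")
  if (!all(names(w) %in% names(object@exprCoeffs@baselineByType)))
    return("invalid configuration: 'exprCoeffs' baselineByType must cover every tumor type")
  if (object@ampTotalCnRange[1] < 3L ||
      object@ampTotalCnRange[2] < object@ampTotalCnRange[1])
    return("invalid configuration: 'ampTotalCnRange' must be an increasing range with minimum >= 3")
  if (object@delLengthRange[1] < 1L ||
      object@delLengthRange[2] < object@delLengthRange[1])
    return("invalid configuration: 'delLengthRange' must be an increasing positive range")
  g <- object@genome
  minAmpLen <- g@ampEndRange[1] - g@ampStartRange[2]
  if (object@delLengthRange[2] >= minAmpLen)
    return("invalid configuration: 'delLengthRange' maximum must be smaller than the amplification length")
  win <- locusWindow(g@target)
  if (object@delLengthRange[2] > BiocGenerics::width(win))
    return("invalid configuration: 'delLengthRange' maximum must fit inside the target deletion window")
  if (object@depthCoverage <= 0)
    return("invalid configuration: 'depthCoverage' must be positive")
  if (object@depthDispersion <= 0)
    return("invalid configuration: 'depthDispersion' must be positive")
  if (object@exprNoiseSd < 0)
    return("invalid configuration: 'exprNoiseSd' must be non-negative")
  TRUE
})

#' @describeIn SimConfig constructor with the package's default study
#'   conditions.
#' @param nSamples,tumorTypeWeights,pAmplification,ampTotalCnRange see slots.
#' @param pFocalDelGivenAmp,pFocalDelGivenNoAmp,delLengthRange see slots.
#' @param pDeletionFirst,pDelOnAmpHaplotype,allelicMinBp see slots.
#' @param depthCoverage,depthDispersion,exprCoeffs,exprNoiseSd see slots.
#' @param pScnaDropout,purity,genome see slots.
#' @export
simConfig <- function(nSamples = 200L,
                      tumorTypeWeights = c(OV = 0.35, BRCA = 0.30,
                                           UCEC = 0.15, Other = 0.20),
                      pAmplification = 0.4,
                      ampTotalCnRange = c(3L, 6L),
                      pFocalDelGivenAmp = 0.4,
                      pFocalDelGivenNoAmp = 0.02,
                      delLengthRange = c(10000L, 60000L),
                      pDeletionFirst = 0.15,
                      pDelOnAmpHaplotype = 0.8,
                      allelicMinBp = 2000L,
                      depthCoverage = 100,
                      depthDispersion = 100,
                      exprCoeffs = expressionCoeffs(),
                      exprNoiseSd = 5,
                      pScnaDropout = 0,
                      purity = 1,
                      genome = defaultGenomeLayout()) {
  new("SimConfig", nSamples = as.integer(nSamples),
      tumorTypeWeights = tumorTypeWeights,
      pAmplification = pAmplification,
      ampTotalCnRange = as.integer(ampTotalCnRange),
      pFocalDelGivenAmp = pFocalDelGivenAmp,
      pFocalDelGivenNoAmp = pFocalDelGivenNoAmp,
      delLengthRange = as.integer(delLengthRange),
      pDeletionFirst = pDeletionFirst,
      pDelOnAmpHaplotype = pDelOnAmpHaplotype,
      allelicMinBp = as.integer(allelicMinBp),
      depthCoverage = depthCoverage, depthDispersion = depthDispersion,
      exprCoeffs = exprCoeffs, exprNoiseSd = exprNoiseSd,
      pScnaDropout = pScnaDropout, purity = purity, genome = genome)
}

# purity mixing of a clonal copy number against the diploid normal
.mixPurity <- function(cn, purity, normal) purity * cn + (1 - purity) * normal

# sample() that never unpacks a length-1 x into 1:x
.resample <- function(x, ...) x[sample.int(length(x), ...)]

#' Simulate a synthetic tumor cohort with ground truth
#'
#' Draws per-sample generative histories (large amplification spanning the
#' driver/target/neighbor loci; nested focal deletion in the target's
#' deletion window; event order; affected haplotype), then emits the
#' observable data a consensus pipeline would produce: allele-specific
#' copy-number segments, SV junctions (deletion junctions with outward
#' orientations, tandem-duplication-like junctions at amplification
#' boundaries), binned tumor/normal read-depth ratios, an FPKM expression
#' table following the linear dosage model, and sample metadata.  The truth
#' ledger records every planted event and is the oracle for all tests.
#'
#' With probability \code{pScnaDropout} a planted deletion is omitted from
#' the segment table (but not from junctions or read depth), emulating the
#' consensus-caller misses that the read-depth rescue pathway recovers.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed integer RNG seed; identical \code{(config, seed)} give
#'   byte-identical output.
#' @param emitDepth emit binned read-depth tracks (default \code{TRUE};
#'   switch off when only segments/expression are needed -- depth is the
#'   bulk of the simulation cost).
#' @return A list with elements \code{segments} (\linkS4class{CNSegments}),
#'   \code{junctions} (\linkS4class{SVJunctions}), \code{depth} (named list
#'   of \linkS4class{ReadDepthTrack}), \code{expression}
#'   (\link[SummarizedExperiment]{SummarizedExperiment}, assay
#'   \code{fpkm}), \code{metadata} (data.frame), and \code{truth}
#'   (data.frame; see Details).
#'
#' @details The truth ledger has one row per sample with columns:
#' \code{sample}, \code{patient}, \code{tumor_type}; amplification interval
#' and total CN (\code{amp_start}, \code{amp_end}, \code{amp_cn}; NA when
#' absent); deletion interval (\code{del_start}, \code{del_end});
#' generative \code{event_order} (\code{amp_first} / \code{del_first} /
#' \code{na}); \code{del_on_amp_haplotype}; \code{scna_emitted};
#' \code{allelic_emitted}; the expression copy-number covariate
#' \code{cn_covariate}; the noiseless target-gene mean
#' \code{expr_mean_gene}; and the timing-informativeness bookkeeping
#' (\code{timing_informative}, \code{ambiguous_reason}).
#' @examples
#' cohort <- simulateCohort(simConfig(nSamples = 10L), seed = 1)
#' table(cohort$truth$event_order)
#' @export
simulateCohort <- function(config, seed, emitDepth = TRUE) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(as.integer(seed))
  n <- config@nSamples
  g <- config@genome
  win <- locusWindow(g@target)
  winStart <- BiocGenerics::start(win); winEnd <- BiocGenerics::end(win)

  sampleIds <- sprintf("S%04d", seq_len(n))
  types <- sample(names(config@tumorTypeWeights), n, replace = TRUE,
                  prob = config@tumorTypeWeights)

  hasAmp <- runif(n) < config@pAmplification
  ampCN  <- .resample(seq(config@ampTotalCnRange[1],
                          config@ampTotalCnRange[2]),
                      n, replace = TRUE)
  ampStart <- floor(runif(n, g@ampStartRange[1], g@ampStartRange[2] + 1))
  ampEnd   <- floor(runif(n, g@ampEndRange[1],   g@ampEndRange[2] + 1))
  pDel <- ifelse(hasAmp, config@pFocalDelGivenAmp, config@pFocalDelGivenNoAmp)
  hasDel <- runif(n) < pDel
  delLen <- floor(runif(n, config@delLengthRange[1],
                        config@delLengthRange[2] + 1))
  delStart <- floor(runif(n, winStart, winEnd - delLen + 1))
  delEnd <- delStart + delLen - 1
  delFirst <- runif(n) < config@pDeletionFirst
  onAmp <- runif(n) < config@pDelOnAmpHaplotype
  dropout <- runif(n) < config@pScnaDropout

  ampCN[!hasAmp] <- NA_integer_
  ampStart[!hasAmp] <- NA_integer_; ampEnd[!hasAmp] <- NA_integer_
  delStart[!hasDel] <- NA_integer_; delEnd[!hasDel] <- NA_integer_
  delLen[!hasDel] <- NA_integer_
  twoEvents <- hasAmp & hasDel
  eventOrder <- ifelse(twoEvents, ifelse(delFirst, "del_first", "amp_first"),
                       "na")
  delOnAmp <- ifelse(twoEvents, onAmp, NA)
  scnaEmitted <- ifelse(hasDel, !dropout, NA)
  allelicEmitted <- ifelse(hasDel, delLen >= config@allelicMinBp, NA)

  segL <- vector("list", n); jxL <- vector("list", n)
  depth <- vector("list", n); names(depth) <- sampleIds

  bins <- .tileRegion(g@depthRegion, 200L)
  binMid <- (BiocGenerics::start(bins) + BiocGenerics::end(bins)) / 2
  binChrom <- as.character(seqnames(bins))
  binStart <- BiocGenerics::start(bins); binEnd <- BiocGenerics::end(bins)

  for (i in seq_len(n)) {
    hap <- .sampleHaplotypeProfile(
      genomeLength = g@genomeLength,
      hasAmp = hasAmp[i], ampStart = ampStart[i], ampEnd = ampEnd[i],
      ampCN = ampCN[i], hasDel = hasDel[i], delStart = delStart[i],
      delEnd = delEnd[i], delFirst = delFirst[i], onAmp = onAmp[i])
    segL[[i]] <- .emitSegments(hap, sampleIds[i], g@chrom,
                               dropout = hasDel[i] && dropout[i],
                               allelicNA = hasDel[i] &&
                                 delLen[i] < config@allelicMinBp,
                               delStart = delStart[i], delEnd = delEnd[i],
                               purity = config@purity)
    jx <- NULL
    if (hasDel[i])
      jx <- data.frame(sample = sampleIds[i], chrom1 = g@chrom,
                       pos1 = delStart[i] - 1, strand1 = "+",
                       chrom2 = g@chrom, pos2 = delEnd[i], strand2 = "-")
    if (hasAmp[i])
      jx <- rbind(jx, data.frame(sample = sampleIds[i], chrom1 = g@chrom,
                                 pos1 = ampStart[i] - 1, strand1 = "-",
                                 chrom2 = g@chrom, pos2 = ampEnd[i],
                                 strand2 = "+"))
    jxL[[i]] <- jx

    if (emitDepth) {
      totalAt <- .profileLookup(hap, binMid)
      mixed <- .mixPurity(totalAt, config@purity, 2)
      mu <- config@depthCoverage * mixed / 2
      counts <- if (is.finite(config@depthDispersion))
        rnbinom(length(mu), mu = mu, size = config@depthDispersion)
      else rpois(length(mu), lambda = mu)
      depth[[i]] <- ReadDepthTrack(sampleIds[i], binChrom, binStart, binEnd,
                                   counts / config@depthCoverage)
    }
  }

  segs <- do.call(rbind, segL)
  segments <- CNSegments(segs$sample, segs$chrom, segs$start, segs$end,
                         segs$total_cn, segs$minor_cn)
  jx <- do.call(rbind, jxL)
  junctions <- if (is.null(jx)) SVJunctions() else
    SVJunctions(jx$sample, jx$chrom1, jx$pos1, jx$strand1,
                jx$chrom2, jx$pos2, jx$strand2)

  cnCov <- .mixPurity(ifelse(hasAmp, ampCN, 2L), config@purity, 2)
  coef <- config@exprCoeffs
  exprMean <- coef@baselineByType[types] + coef@betaCN * cnCov +
    coef@betaDel * as.numeric(hasDel)

  truth <- data.frame(sample = sampleIds, patient = sub("^S", "P", sampleIds),
                      tumor_type = types,
                      amp_start = ampStart, amp_end = ampEnd, amp_cn = ampCN,
                      del_start = delStart, del_end = delEnd,
                      event_order = eventOrder,
                      del_on_amp_haplotype = delOnAmp,
                      scna_emitted = scnaEmitted,
                      allelic_emitted = allelicEmitted,
                      cn_covariate = cnCov,
                      expr_mean_gene = unname(exprMean),
                      stringsAsFactors = FALSE)
  truth$timing_informative <- twoEvents &
    !is.na(delOnAmp) & delOnAmp &
    truth$scna_emitted %in% TRUE & truth$allelic_emitted %in% TRUE
  truth$ambiguous_reason <- ifelse(
    !twoEvents, NA_character_,
    ifelse(!truth$scna_emitted, "deletion_below_allelic_resolution",
    ifelse(!truth$allelic_emitted, "missing_minor_cn",
    ifelse(!truth$del_on_amp_haplotype, "different_alleles",
           NA_character_))))

  expression <- emitExpression(truth, coef, config@exprNoiseSd,
                               seed = subSeed(seed, 101L))

  metadata <- data.frame(sample = sampleIds, tumor_type = types,
                         patient = truth$patient, stringsAsFactors = FALSE)
  list(segments = segments, junctions = junctions, depth = depth,
       expression = expression, metadata = metadata, truth = truth)
}

# Per-haplotype copy-number profile of one sample as a piecewise-constant
# table (breaks are 1-based segment starts).  Haplotype A is the amplified
# one when an amplification is present.
.sampleHaplotypeProfile <- function(genomeLength, hasAmp, ampStart, ampEnd,
                                    ampCN, hasDel, delStart, delEnd,
                                    delFirst, onAmp) {
  brk <- c(1, genomeLength + 1)
  if (hasAmp) brk <- c(brk, ampStart, ampEnd + 1)
  if (hasDel) brk <- c(brk, delStart, delEnd + 1)
  brk <- sort(unique(brk))
  start <- brk[-length(brk)]; end <- brk[-1] - 1
  hapA <- rep(1, length(start)); hapB <- rep(1, length(start))
  if (hasAmp) {
    inAmp <- start >= ampStart & end <= ampEnd
    hapA[inAmp] <- ampCN - 1
  }
  if (hasDel) {
    inDel <- start >= delStart & end <= delEnd
    if (hasAmp && onAmp) {
      # deletion-first: nothing left on the amplified haplotype to amplify;
      # amplification-first: one amplified copy is lost
      hapA[inDel] <- if (delFirst) 0 else ampCN - 2
    } else if (hasAmp) {
      hapB[inDel] <- 0
    } else {
      hapA[inDel] <- 0
    }
  }
  data.frame(start = start, end = end, hapA = hapA, hapB = hapB)
}

# piecewise-constant total-CN lookup at positions
.profileLookup <- function(hap, pos) {
  idx <- findInterval(pos, hap$start)
  hap$hapA[idx] + hap$hapB[idx]
}

# Collapse a haplotype profile into emitted segments.  When dropout is
# requested the deletion rows are replaced by their flanking state (no
# segment-level CN call); when allelicNA is requested the minor CN of the
# deletion rows is emitted as NA.
.emitSegments <- function(hap, sample, chrom, dropout, allelicNA,
                          delStart, delEnd, purity) {
  total <- hap$hapA + hap$hapB
  minor <- pmin(hap$hapA, hap$hapB)
  isDel <- !is.na(delStart) & hap$start >= delStart & hap$end <= delEnd
  if (dropout && any(isDel)) {
    # the consensus caller missed the dip: re-emit the flanking state
    flank <- which(isDel)[1] - 1L
    total[isDel] <- total[flank]; minor[isDel] <- minor[flank]
  }
  total <- .mixPurity(total, purity, 2)
  minor <- .mixPurity(minor, purity, 1)
  if (allelicNA && !dropout) minor[isDel] <- NA_real_
  # merge adjacent rows with identical emitted state
  key <- paste(total, minor)
  run <- c(TRUE, key[-1] != key[-length(key)])
  grp <- cumsum(run)
  data.frame(sample = sample, chrom = chrom,
             start = as.numeric(tapply(hap$start, grp, min)),
             end = as.numeric(tapply(hap$end, grp, max)),
             total_cn = total[run], minor_cn = minor[run],
             row.names = NULL)
}

# 200-bp tiling of a single-range region; last bin may be short
.tileRegion <- function(region, width) {
  stopifnot(length(region) == 1L)
  s <- seq(BiocGenerics::start(region), BiocGenerics::end(region), by = width)
  e <- pmin(s + width - 1, BiocGenerics::end(region))
  GRanges(as.character(seqnames(region)), IRanges(s, e))
}

#' Emit an FPKM expression table from a truth ledger
#'
#' The generative inverse of the dosage model: for each sample the
#' target-gene mean is \code{baselineByType[type] + betaCN * cn_covariate +
#' betaDel * [deletion]}; Gaussian noise is added and the result clamped at
#' zero (FPKM cannot be negative).  An isoform split is emitted alongside
#' the gene-level row: a long isoform and two short isoforms, with the
#' secondary short isoform scaled far below the dominant one.
#'
#' @param truth a truth ledger from \code{\link{simulateCohort}} (or any
#'   data.frame with columns \code{sample}, \code{tumor_type},
#'   \code{cn_covariate}, \code{del_start}, \code{expr_mean_gene} optional).
#' @param coeffs an \linkS4class{ExpressionCoeffs}.
#' @param noiseSd Gaussian noise SD in FPKM units.
#' @param seed RNG seed.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{fpkm} (rows: gene plus three transcripts; columns: samples),
#'   rowData columns \code{feature_id}, \code{gene}, \code{class},
#'   \code{isoform}, and the sample table as colData.
#' @export
emitExpression <- function(truth, coeffs, noiseSd, seed) {
  stopifnot(is(coeffs, "ExpressionCoeffs"))
  if (!all(truth$tumor_type %in% names(coeffs@baselineByType)))
    stop("invalid configuration: 'exprCoeffs' baselineByType must cover every tumor type")
  set.seed(as.integer(seed))
  n <- nrow(truth)
  del <- as.numeric(!is.na(truth$del_start))
  mu <- unname(coeffs@baselineByType[truth$tumor_type]) +
    coeffs@betaCN * truth$cn_covariate + coeffs@betaDel * del
  isoFrac <- c(long = 0.70, shortA = 0.27, shortB = 0.03)
  feats <- c("BRD4L", paste0("BRD4L-", names(isoFrac)))
  mat <- matrix(0, nrow = length(feats), ncol = n,
                dimnames = list(feats, truth$sample))
  mat["BRD4L", ] <- pmax(0, mu + rnorm(n, 0, noiseSd))
  for (k in names(isoFrac))
    mat[paste0("BRD4L-", k), ] <-
      pmax(0, isoFrac[[k]] * mu + rnorm(n, 0, noiseSd * isoFrac[[k]]))
  rowInfo <- DataFrame(feature_id = feats, gene = "BRD4L",
                       class = c("gene", rep("transcript", 3L)),
                       isoform = c(NA, names(isoFrac)))
  colInfo <- DataFrame(sample = truth$sample,
                       tumor_type = truth$tumor_type,
                       patient = if ("patient" %in% names(truth))
                         truth$patient else truth$sample)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat), rowData = rowInfo, colData = colInfo)
}

#' Simulate a gene expression matrix with planted differential signals
#'
#' Generates \code{nGenes} genes over a cohort with carrier / non-carrier
#' labels and tumor types; \code{nPlanted} autosomal protein-coding genes
#' receive a carrier shift of \code{log2fc} on the log2(FPKM + 1) scale.
#' Used to calibrate the differential-expression stage: at the default low
#' noise the planted genes are recoverable exactly and label permutation
#' yields no passes under the Bonferroni + fold-change gates.
#'
#' @param nSamples number of samples.
#' @param nCarriers number of focal-deletion carriers among them.
#' @param nGenes total number of genes.
#' @param nPlanted number of planted differential genes.
#' @param log2fc planted carrier shift (log2 scale; 2 = 4-fold).
#' @param noiseSd residual SD on the log2 scale.
#' @param tumorTypeWeights named tumor-type probabilities.
#' @param typeEffectSd SD of per-gene tumor-type effects (log2 scale).
#' @param fracNonCoding fraction of genes labelled non-protein-coding or
#'   sex-chromosomal (excluded from testing by contract).
#' @param seed RNG seed.
#' @return list with \code{expression} (SummarizedExperiment, assay
#'   \code{fpkm}; rowData \code{gene_id}, \code{chrom}, \code{biotype}),
#'   \code{carriers} (logical per sample), \code{planted} (gene ids),
#'   \code{testable} (autosomal protein-coding gene ids).
#' @export
simulateDEMatrix <- function(nSamples = 120L, nCarriers = 20L,
                             nGenes = 2000L, nPlanted = 20L, log2fc = 2,
                             noiseSd = 0.3,
                             tumorTypeWeights = c(OV = 0.35, BRCA = 0.30,
                                                  UCEC = 0.15, Other = 0.20),
                             typeEffectSd = 0.5, fracNonCoding = 0.05,
                             seed = 1L) {
  set.seed(as.integer(seed))
  samples <- sprintf("S%04d", seq_len(nSamples))
  types <- sample(names(tumorTypeWeights), nSamples, replace = TRUE,
                  prob = tumorTypeWeights)
  carriers <- rep(FALSE, nSamples)
  carriers[sample(nSamples, nCarriers)] <- TRUE

  genes <- sprintf("G%05d", seq_len(nGenes))
  chrom <- sample(paste0("chr", 1:22), nGenes, replace = TRUE)
  biotype <- rep("protein_coding", nGenes)
  nNC <- round(fracNonCoding * nGenes)
  if (nNC > 0) {
    nc <- sample(nGenes, nNC)
    biotype[nc] <- "lncRNA"
    chrom[nc[seq_len(ceiling(nNC / 2))]] <- "chrX"
  }
  testable <- genes[biotype == "protein_coding" & chrom != "chrX"]
  planted <- sample(testable, nPlanted)

  base <- runif(nGenes, 3, 8)
  typeEff <- matrix(rnorm(nGenes * length(tumorTypeWeights), 0, typeEffectSd),
                    nrow = nGenes,
                    dimnames = list(genes, names(tumorTypeWeights)))
  y <- matrix(base, nGenes, nSamples) + typeEff[, types] +
    matrix(rnorm(nGenes * nSamples, 0, noiseSd), nGenes, nSamples)
  y[planted, carriers] <- y[planted, carriers] + log2fc
  fpkm <- pmax(2^y - 1, 0)
  dimnames(fpkm) <- list(genes, samples)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm),
    rowData = DataFrame(gene_id = genes, chrom = chrom, biotype = biotype),
    colData = DataFrame(sample = samples, tumor_type = types,
                        patient = samples, carrier = carriers))
  list(expression = se, carriers = carriers, planted = sort(planted),
       testable = testable)
}
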