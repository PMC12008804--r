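#' Focal-deletion caller parameters
#'
#' Thresholds of the deletion-calling stage.  The proximity window (50
#' kbp), focal size cap (100 kbp) and amplification threshold (total CN
#' strictly above 2) follow the published definitions; the read-depth
#' rescue thresholds formalize what was originally a manual review of
#' tumor/normal depth plots and are reported in output provenance.
#'
#' @param proximityBp maximum distance from an SCNA breakpoint to the
#'   locus (measured from the nearer of the gene's start/end; 0 when the
#'   breakpoint falls inside the gene).  Default 50000.
#' @param maxEventBp focal size cap: a copy-loss event must span fewer bp
#'   than this to be called focal.  Default 100000.
#' @param relLossDelta minimum copy-number deficit, in copies, of the
#'   internal event relative to BOTH flanking segments (and of the target
#'   vs the neighbor gene for relative-loss calls).  Default 0.5.
#' @param ampCnThreshold total copy number strictly above which an
#'   overlapping segment marks the locus amplified.  Default 2.
#' @param rescueDropFrac minimum fractional read-depth drop inside a
#'   candidate interval relative to its flanks.  Default 0.1: a single-copy
#'   loss inside an n-copy amplification drops depth by 1/n, so the
#'   threshold must sit below 1/n for the amplification range of interest
#'   (up to ~6 copies here) with margin for counting noise.
#' @param rescueFlankBp flank width used for the depth baseline.  Default
#'   50000.
#' @param junctionMatchBp maximum distance between a depth step location
#'   (or an SCNA event boundary) and a junction breakend.  Default 1000.
#' @return A named list of class \code{CallerParams}.
#' @export
callerParams <- function(proximityBp = 50000, maxEventBp = 100000,
                         relLossDelta = 0.5, ampCnThreshold = 2,
                         rescueDropFrac = 0.1, rescueFlankBp = 50000,
                         junctionMatchBp = 1000) {
  p <- list(proximityBp = proximityBp, maxEventBp = maxEventBp,
            relLossDelta = relLossDelta, ampCnThreshold = ampCnThreshold,
            rescueDropFrac = rescueDropFrac, rescueFlankBp = rescueFlankBp,
            junctionMatchBp = junctionMatchBp)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v > 0, logical(1))))
  if (rescueDropFrac >= 1)
    stop("rescueDropFrac must be in (0, 1)")
  structure(p, class = "CallerParams")
}

.emptyCalls <- function() {
  data.frame(sample = character(), chrom = character(),
             start = numeric(), end = numeric(),
             evidence_class = character(), cn_inside = numeric(),
             cn_flank = numeric(), junction_ids = character(),
             focal = logical(), stringsAsFactors = FALSE)
}

#' Mean total copy number across a locus
#'
#' Overlap-length-weighted mean of segment total copy number over the gene
#' interval, per sample; bases not covered by any segment are excluded
#' from the weighting.  Samples with zero overlap get \code{NA}.
#'
#' @param segments a \linkS4class{CNSegments}.
#' @param locus a \linkS4class{GeneLocus}.
#' @param samples samples to report (default: all samples in
#'   \code{segments}).
#' @return Named numeric vector of mean copy numbers.
#' @examples
#' seg <- CNSegments(c("s1", "s1"), "chrS", c(1, 5001), c(5000, 10000),
#'                   total_cn = c(2, 4), minor_cn = 1)
#' locusCN(seg, GeneLocus("g", "chrS", 1, 10000))  # 3
#' @export
locusCN <- function(segments, locus, samples = unique(segSample(segments))) {
  stopifnot(is(segments, "CNSegments"), is(locus, "GeneLocus"))
  out <- vapply(samples, function(s) {
    sub <- segments[segSample(segments) == s]
    .weightedOverlapMean(granges(sub), totalCN(sub), locus)
  }, numeric(1))
  names(out) <- samples
  out
}

#' Amplification status of a locus
#'
#' A sample is amplified at the locus iff any of its segments with total
#' copy number strictly above \code{ampCnThreshold} overlaps the gene
#' interval, irrespective of any concomitant focal deletion.
#'
#' @inheritParams locusCN
#' @param params a \code{\link{callerParams}} list.
#' @return Named logical vector.
#' @export
isAmplified <- function(segments, locus, params = callerParams(),
                        samples = unique(segSample(segments))) {
  stopifnot(is(segments, "CNSegments"), is(locus, "GeneLocus"))
  lS <- BiocGenerics::start(locus); lE <- BiocGenerics::end(locus)
  hit <- totalCN(segments) > params$ampCnThreshold &
    as.character(seqnames(segments)) == as.character(seqnames(locus))[1] &
    BiocGenerics::start(segments) <= lE & BiocGenerics::end(segments) >= lS
  out <- vapply(samples, function(s) any(hit[segSample(segments) == s]),
                logical(1))
  names(out) <- samples
  out
}

# distance from a breakpoint position to a locus; 0 inside
.locusDistance <- function(pos, locus) {
  s <- BiocGenerics::start(locus); e <- BiocGenerics::end(locus)
  ifelse(pos < s, s - pos, ifelse(pos > e, pos - e, 0))
}

# dip events in one sample's per-chromosome segment profile: maximal runs
# of segments sitting at least `delta` copies below BOTH flanking segments
.findDipRuns <- function(start, end, cn, delta) {
  m <- length(cn)
  runs <- list()
  k <- 2L
  while (k <= m - 1L) {
    if (cn[k] <= cn[k - 1L] - delta) {
      j <- k
      while (j + 1L <= m && cn[j + 1L] <= cn[k - 1L] - delta) j <- j + 1L
      if (j + 1L <= m && max(cn[k:j]) <= cn[j + 1L] - delta) {
        runs[[length(runs) + 1L]] <-
          list(from = k, to = j, flankL = k - 1L, flankR = j + 1L)
      }
      k <- j + 1L
    } else k <- k + 1L
  }
  runs
}

#' Call SCNA-supported focal deletions at a locus
#'
#' A call is emitted for a sample iff its segment profile contains a
#' bounded copy-loss event -- a maximal run of segments at least
#' \code{relLossDelta} copies below both flanking segments -- that
#' overlaps the gene, spans fewer than \code{maxEventBp} bp, and has a
#' segment boundary within \code{proximityBp} of the locus.  Supporting
#' deletion-consistent junctions whose breakends match the event
#' boundaries (within \code{junctionMatchBp}) are attached.
#'
#' @param segments a \linkS4class{CNSegments}.
#' @param junctions an \linkS4class{SVJunctions} (may be empty).
#' @param locus the target \linkS4class{GeneLocus}.
#' @param params a \code{\link{callerParams}} list.
#' @return A calls data.frame (columns \code{sample}, \code{chrom},
#'   \code{start}, \code{end}, \code{evidence_class}, \code{cn_inside},
#'   \code{cn_flank}, \code{junction_ids}, \code{focal}); zero rows when
#'   nothing is called.
#' @export
callScnaFocalDeletions <- function(segments, junctions = SVJunctions(),
                                   locus, params = callerParams()) {
  stopifnot(is(segments, "CNSegments"), is(locus, "GeneLocus"))
  chrom <- as.character(seqnames(locus))
  jt <- junctionTable(junctions)
  jDel <- if (nrow(jt)) jt[isDeletionConsistent(junctions), , drop = FALSE]
          else jt
  out <- list()
  for (s in unique(segSample(segments))) {
    sub <- segments[segSample(segments) == s &
                      as.character(seqnames(segments)) == chrom]
    if (length(sub) < 3L) next
    o <- order(BiocGenerics::start(sub))
    st <- BiocGenerics::start(sub)[o]; en <- BiocGenerics::end(sub)[o]
    cn <- totalCN(sub)[o]
    for (run in .findDipRuns(st, en, cn, params$relLossDelta)) {
      evS <- st[run$from]; evE <- en[run$to]
      span <- evE - evS + 1
      if (span >= params$maxEventBp) next
      ev <- GRanges(chrom, IRanges(evS, evE))
      if (!overlapsAny(ev, granges(locus), ignore.strand = TRUE)) next
      if (min(.locusDistance(evS, locus), .locusDistance(evE, locus)) >
            params$proximityBp) next
      w <- en[run$from:run$to] - st[run$from:run$to] + 1
      cnIn <- sum(w * cn[run$from:run$to]) / sum(w)
      cnFl <- mean(cn[c(run$flankL, run$flankR)])
      jid <- character()
      if (nrow(jDel)) {
        hit <- jDel$sample == s & jDel$chrom1 == chrom &
          abs(jDel$pos1 + 1 - evS) <= params$junctionMatchBp &
          abs(jDel$pos2 - evE) <= params$junctionMatchBp
        jid <- jDel$name[hit]
      }
      out[[length(out) + 1L]] <-
        data.frame(sample = s, chrom = chrom, start = evS, end = evE,
                   evidence_class = "scna", cn_inside = cnIn,
                   cn_flank = cnFl,
                   junction_ids = paste(jid, collapse = ","),
                   focal = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else .emptyCalls()
}

# best single changepoint position (1-based boundary coordinate) of a
# depth vector over bins [st, en]; NULL when fewer than 2 bins
.bestStep <- function(st, en, v) {
  B <- length(v)
  if (B < 2L) return(NULL)
  cs <- cumsum(v); tot <- cs[B]
  b <- seq_len(B - 1L)
  sse <- -(cs[b]^2 / b + (tot - cs[b])^2 / (B - b))
  en[b[which.min(sse)]]
}

#' Rescue focal deletions from binned read depth
#'
#' For each deletion-consistent junction whose breakends bound an interval
#' shorter than \code{maxEventBp} and overlapping the locus (its deletion
#' window when one is defined), the mean tumor/normal depth ratio inside
#' the interval is compared with the mean over \code{rescueFlankBp} flanks
#' (excluding other candidate intervals).  A rescued call is emitted iff
#' the inside mean is at most \code{(1 - rescueDropFrac)} times the flank
#' mean and the depth step locations fall within \code{junctionMatchBp} of
#' the junction breakends.  Candidates whose flanks are not covered by the
#' track are skipped with a warning.
#'
#' @param junctions an \linkS4class{SVJunctions}.
#' @param depth a \linkS4class{ReadDepthTrack} for one sample.
#' @param locus the target \linkS4class{GeneLocus}.
#' @param params a \code{\link{callerParams}} list.
#' @return A calls data.frame as in \code{\link{callScnaFocalDeletions}}
#'   with \code{evidence_class = "rescued"}; \code{cn_inside}/
#'   \code{cn_flank} are depth-derived copy numbers (2 x depth ratio).
#' @export
rescueFromDepth <- function(junctions, depth, locus,
                            params = callerParams()) {
  stopifnot(is(junctions, "SVJunctions"), is(depth, "ReadDepthTrack"),
            is(locus, "GeneLocus"))
  sampleId <- trackSample(depth)
  chrom <- as.character(seqnames(locus))
  jt <- junctionTable(junctions)
  keep <- jt$sample == sampleId & isDeletionConsistent(junctions) &
    jt$chrom1 == chrom
  jt <- jt[keep, , drop = FALSE]
  if (nrow(jt) == 0L) return(.emptyCalls())
  target <- if (length(locusWindow(locus))) locusWindow(locus) else
    granges(locus)
  cand <- GRanges(chrom, IRanges(jt$pos1 + 1, pmax(jt$pos2, jt$pos1 + 1)))
  spans <- BiocGenerics::width(cand)
  ok <- spans < params$maxEventBp &
    overlapsAny(cand, target, ignore.strand = TRUE)
  jt <- jt[ok, , drop = FALSE]; cand <- cand[ok]
  if (nrow(jt) == 0L) return(.emptyCalls())

  binStart <- BiocGenerics::start(depth); binEnd <- BiocGenerics::end(depth)
  ratio <- depthRatio(depth)
  inAnyCand <- overlapsAny(granges(depth), cand, ignore.strand = TRUE)
  out <- list()
  for (i in seq_len(nrow(jt))) {
    s <- BiocGenerics::start(cand)[i]; e <- BiocGenerics::end(cand)[i]
    inside <- binStart >= s & binEnd <= e
    flank <- ((binEnd >= s - params$rescueFlankBp & binEnd < s) |
                (binStart > e & binStart <= e + params$rescueFlankBp)) &
      !inAnyCand
    leftFlank <- any(flank & binEnd < s); rightFlank <- any(flank & binStart > e)
    if (!any(inside) || !leftFlank || !rightFlank) {
      warning(sprintf("rescue candidate %s skipped for sample %s: depth track does not cover interval and flanks",
                      jt$name[i], sampleId))
      next
    }
    mIn <- mean(ratio[inside]); mFl <- mean(ratio[flank])
    if (!(mIn <= (1 - params$rescueDropFrac) * mFl)) next
    # step locations must sit at the breakends
    winL <- binEnd >= s - params$rescueFlankBp &
      binStart <= min(e, s + params$rescueFlankBp) & (inside | flank)
    winR <- binEnd >= max(s, e - params$rescueFlankBp) &
      binStart <= e + params$rescueFlankBp & (inside | flank)
    stepL <- .bestStep(binStart[winL], binEnd[winL], ratio[winL])
    stepR <- .bestStep(binStart[winR], binEnd[winR], ratio[winR])
    if (is.null(stepL) || is.null(stepR)) next
    if (abs(stepL - (s - 1)) > params$junctionMatchBp ||
        abs(stepR - e) > params$junctionMatchBp) next
    out[[length(out) + 1L]] <-
      data.frame(sample = sampleId, chrom = chrom, start = s, end = e,
                 evidence_class = "rescued", cn_inside = 2 * mIn,
                 cn_flank = 2 * mFl, junction_ids = jt$name[i],
                 focal = TRUE, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else .emptyCalls()
}

#' Call relative copy-loss of the target gene versus its neighbor
#'
#' Emits a non-focal \code{relative_loss} call for every sample whose mean
#' target-gene copy number sits at least \code{relLossDelta} copies below
#' the neighbor gene's.  These calls are flagged \code{focal = FALSE} and
#' are excluded from the focal-deletion carrier set used by downstream
#' statistics.  Samples with missing copy number at either locus are
#' skipped with a warning.
#'
#' @param segments a \linkS4class{CNSegments}.
#' @param target,neighbor \linkS4class{GeneLocus} objects.
#' @param params a \code{\link{callerParams}} list.
#' @param samples samples to evaluate (default: all).
#' @return A calls data.frame with \code{evidence_class = "relative_loss"}.
#' @export
callRelativeLoss <- function(segments, target, neighbor,
                             params = callerParams(),
                             samples = unique(segSample(segments))) {
  tcn <- locusCN(segments, target, samples)
  ncn <- locusCN(segments, neighbor, samples)
  miss <- is.na(tcn) | is.na(ncn)
  if (any(miss))
    warning(sprintf("relative-loss: skipping sample(s) with missing locus copy number: %s",
                    paste(samples[miss], collapse = ", ")))
  hit <- !miss & tcn <= ncn - params$relLossDelta
  if (!any(hit)) return(.emptyCalls())
  data.frame(sample = samples[hit],
             chrom = as.character(seqnames(target)),
             start = BiocGenerics::start(target),
             end = BiocGenerics::end(target),
             evidence_class = "relative_loss",
             cn_inside = unname(tcn[hit]), cn_flank = unname(ncn[hit]),
             junction_ids = "", focal = FALSE, stringsAsFactors = FALSE)
}

#' Call focal deletions at the target locus across a cohort
#'
#' Orchestrates the three evidence pathways: segment-supported calls
#' first; then read-depth rescue for deletion-consistent junctions not
#' already explained by a segment-supported call in the same sample (so no
#' sample receives both classes for one interval); finally, for samples
#' with no focal call, relative copy-loss versus the neighbor gene when
#' one is supplied.  The focal-deletion carrier set is the set of samples
#' with at least one \code{scna} or \code{rescued} call
#' (\code{\link{carrierSamples}}).
#'
#' @param segments a \linkS4class{CNSegments}.
#' @param junctions an \linkS4class{SVJunctions}.
#' @param depth named list of \linkS4class{ReadDepthTrack} (names =
#'   samples); may be \code{NULL} to skip the rescue pathway.
#' @param target the target \linkS4class{GeneLocus}.
#' @param neighbor optional neighbor \linkS4class{GeneLocus} for
#'   relative-loss classification.
#' @param params a \code{\link{callerParams}} list.
#' @return A calls data.frame; see \code{\link{callScnaFocalDeletions}}.
#' @export
callFocalDeletions <- function(segments, junctions, depth = NULL, target,
                               neighbor = NULL, params = callerParams()) {
  calls <- callScnaFocalDeletions(segments, junctions, target, params)
  if (!is.null(depth)) {
    scna <- calls
    scnaGr <- GRanges(scna$chrom, IRanges(scna$start, scna$end))
    for (s in names(depth)) {
      resc <- rescueFromDepth(junctions, depth[[s]], target, params)
      if (nrow(resc) == 0L) next
      # drop rescue calls whose interval a segment-supported call already covers
      rg <- GRanges(resc$chrom, IRanges(resc$start, resc$end))
      dup <- overlapsAny(rg, scnaGr[scna$sample == s], ignore.strand = TRUE)
      calls <- rbind(calls, resc[!dup, , drop = FALSE])
    }
  }
  if (!is.null(neighbor)) {
    rest <- setdiff(unique(segSample(segments)), carrierSamples(calls))
    if (length(rest))
      calls <- rbind(calls, callRelativeLoss(segments, target, neighbor,
                                             params, samples = rest))
  }
  rownames(calls) <- NULL
  calls[order(calls$sample, calls$start), , drop = FALSE]
}

#' @describeIn callFocalDeletions samples carrying at least one focal
#'   (scna or rescued) deletion call.
#' @param calls a calls data.frame.
#' @export
carrierSamples <- function(calls) {
  sort(unique(calls$sample[calls$evidence_class %in% c("scna", "rescued")]))
}

#' Read / write focal-deletion call tables
#'
#' Tab-separated with columns \code{sample}, \code{chrom}, \code{start},
#' \code{end} (0-based half-open on disk), \code{evidence_class},
#' \code{cn_inside}, \code{cn_flank}, \code{junction_ids}, \code{focal}.
#'
#' @param path file path.
#' @return \code{readCalls} returns the calls data.frame; \code{writeCalls}
#'   returns \code{path} invisibly.
#' @export
readCalls <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  d$start <- d$start + 1
  d$junction_ids[is.na(d$junction_ids)] <- ""
  d
}

#' @rdname readCalls
#' @param calls a calls data.frame.
#' @export
writeCalls <- function(calls, path) {
  d <- calls
  d$start <- d$start - 1
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
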