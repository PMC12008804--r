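#' Classify amplification/deletion temporal order from allelic copy number
#'
#' Given one sample's allele-specific segments, an amplification interval
#' and a nested focal-deletion interval, infers which event came first.
#' Per-haplotype copy numbers (major = total - minor, minor) are derived
#' inside the deletion and on the flanking segments within the
#' amplification; the amplified haplotype is the one with flank copy
#' number above 1.  If that haplotype drops to zero inside the deletion
#' (loss of heterozygosity on the amplified allele) the deletion happened
#' first: a deletion after amplification could only remove one of several
#' co-amplified copies.  If it drops to a non-zero value below its flank
#' level, the amplification came first.  Everything else is ambiguous,
#' with a reason: the deletion registered only on the non-amplified
#' haplotype (\code{different_alleles}), minor copy number is missing
#' (\code{missing_minor_cn}), the allelic profile inside equals the flank
#' (\code{deletion_below_allelic_resolution}), both flank haplotypes are
#' equal and above 1 so the loss cannot be assigned
#' (\code{uniparental_disomy}), or the two flanks disagree with equal
#' overlap weight (\code{discordant_flanks}).
#'
#' @param segments \linkS4class{CNSegments} of one sample.
#' @param amplification length-1 \code{GRanges}: the amplification span.
#' @param deletion length-1 \code{GRanges}: the focal-deletion interval.
#' @param allelicTol minimum allelic copy-number difference treated as
#'   discernible (copies; default 0.3).
#' @return A list with elements \code{verdict}
#'   (\code{amplification_first} / \code{deletion_first} /
#'   \code{ambiguous}), \code{reason}, \code{amp_allele_outside},
#'   \code{amp_allele_inside}.
#' @examples
#' seg <- CNSegments(rep("s1", 3), "chrS", c(1e6, 2e6, 2.1e6),
#'                   c(2e6 - 1, 2.1e6 - 1, 3e6),
#'                   total_cn = c(4, 3, 4), minor_cn = 1)
#' classifyTiming(seg, GenomicRanges::GRanges("chrS", IRanges::IRanges(1e6, 3e6)),
#'                GenomicRanges::GRanges("chrS", IRanges::IRanges(2e6, 2.1e6 - 1)))
#' @export
classifyTiming <- function(segments, amplification, deletion,
                           allelicTol = 0.3) {
  stopifnot(is(segments, "CNSegments"),
            length(amplification) == 1L, length(deletion) == 1L)
  amb <- function(reason, M = NA_real_, x = NA_real_)
    list(verdict = "ambiguous", reason = reason,
         amp_allele_outside = M, amp_allele_inside = x)
  near <- function(a, b) abs(a - b) <= allelicTol

  gr <- granges(segments)
  segStart <- BiocGenerics::start(gr); segEnd <- BiocGenerics::end(gr)
  onChr <- as.character(seqnames(gr)) ==
    as.character(seqnames(deletion))[1]
  dS <- BiocGenerics::start(deletion); dE <- BiocGenerics::end(deletion)
  aS <- BiocGenerics::start(amplification)
  aE <- BiocGenerics::end(amplification)
  ovW <- pmin(segEnd, dE) - pmax(segStart, dS) + 1
  idx <- which(onChr & ovW > 0)
  if (length(idx) == 0L)
    stop("deletion interval not covered by any segment")
  totIn <- sum(ovW[idx] * totalCN(segments)[idx]) / sum(ovW[idx])
  if (any(is.na(minorCN(segments)[idx])))
    return(amb("missing_minor_cn"))
  minIn <- sum(ovW[idx] * minorCN(segments)[idx]) / sum(ovW[idx])

  # flanks: segments immediately adjacent to the deletion inside the
  # amplification; if they disagree the wider-overlap flank wins, an exact
  # tie is ambiguous
  pickFlank <- function(pos) {
    f <- which(onChr & segStart <= pos & segEnd >= pos)
    if (length(f) == 0L) return(NULL)
    f[1]
  }
  fl <- pickFlank(dS - 1); fr <- pickFlank(dE + 1)
  if (is.null(fl) && is.null(fr))
    stop("deletion flanks not covered by any segment")
  flankState <- function(f) {
    if (is.null(f)) return(NULL)
    if (is.na(minorCN(segments)[f])) return(NA)
    ov <- max(0, min(segEnd[f], aE) - max(segStart[f], aS) + 1)
    c(total = totalCN(segments)[f], minor = minorCN(segments)[f], w = ov)
  }
  sL <- flankState(fl); sR <- flankState(fr)
  if ((!is.null(sL) && all(is.na(sL))) || (!is.null(sR) && all(is.na(sR))))
    return(amb("missing_minor_cn"))
  flank <- if (is.null(sR)) sL else if (is.null(sL)) sR else {
    if (near(sL["total"], sR["total"]) && near(sL["minor"], sR["minor"])) sL
    else if (sL["w"] > sR["w"]) sL
    else if (sR["w"] > sL["w"]) sR
    else return(amb("discordant_flanks"))
  }

  M <- unname(flank["total"] - flank["minor"])  # putative amplified haplotype
  m <- unname(flank["minor"])
  if (M <= 1 + allelicTol)
    return(amb("deletion_below_allelic_resolution", M))
  if (near(M, m) && m > 1 + allelicTol)
    return(amb("uniparental_disomy", M))

  Mi <- totIn - minIn; mi <- minIn
  if (near(Mi, M) && near(mi, m))
    return(amb("deletion_below_allelic_resolution", M, M))
  # hypothesis: loss hit the amplified haplotype (the unamplified one is
  # unchanged at m); the amplified haplotype's inside CN is the other value
  x <- if (near(mi, m) && Mi < M - allelicTol) Mi
       else if (near(Mi, m) && mi < min(m, M) - allelicTol) mi
       else NA
  if (!is.na(x)) {
    if (x <= allelicTol)
      return(list(verdict = "deletion_first", reason = "loh_on_amp_allele",
                  amp_allele_outside = M, amp_allele_inside = x))
    return(list(verdict = "amplification_first",
                reason = "nonzero_loss_on_amp_allele",
                amp_allele_outside = M, amp_allele_inside = x))
  }
  # loss registered on the non-amplified haplotype (or unassignable)
  amb("different_alleles", M, M)
}

#' One-sided exact binomial test for event-order enrichment
#'
#' Tests whether one temporal order dominates among informative samples:
#' the one-sided exact tail probability of observing at least
#' \code{max(nAmpFirst, nDelFirst)} successes in
#' \code{nAmpFirst + nDelFirst} fair coin flips, computed by exact
#' summation of binomial coefficients (no normal approximation).  The
#' tested direction (the observed majority) and sidedness are recorded.
#' The test is symmetric in its two arguments.
#'
#' @param nAmpFirst number of amplification-first verdicts.
#' @param nDelFirst number of deletion-first verdicts.
#' @return A \code{TimingSummary}: list with \code{n_informative},
#'   \code{n_amp_first}, \code{n_del_first}, \code{direction},
#'   \code{sidedness}, \code{p_value}.
#' @examples
#' timingBinomialTest(11, 2)  # p = 92/8192 = 0.0112, prints as 0.01
#' @export
timingBinomialTest <- function(nAmpFirst, nDelFirst) {
  stopifnot(nAmpFirst >= 0, nDelFirst >= 0)
  n <- nAmpFirst + nDelFirst
  if (n < 1) stop("no informative samples")
  k <- max(nAmpFirst, nDelFirst)
  p <- sum(choose(n, k:n)) / 2^n
  structure(list(n_informative = n, n_amp_first = nAmpFirst,
                 n_del_first = nDelFirst,
                 direction = if (nAmpFirst >= nDelFirst)
                   "amplification_first" else "deletion_first",
                 sidedness = "one-sided (direction of observed majority)",
                 p_value = p),
            class = "TimingSummary")
}

#' @export
print.TimingSummary <- function(x, ...) {
  cat(sprintf("Event-order enrichment: %d amplification-first vs %d deletion-first (%d informative)\n",
              x$n_amp_first, x$n_del_first, x$n_informative))
  cat(sprintf("  exact binomial p = %.4g, %s, toward %s\n",
              x$p_value, x$sidedness, x$direction))
  invisible(x)
}

# merged amplified region overlapping the locus for one sample; internal
# dips narrower than the focal cap are bridged
.ampInterval <- function(segments, locus, params) {
  chrom <- as.character(seqnames(locus))[1]
  sel <- as.character(seqnames(segments)) == chrom &
    totalCN(segments) > params$ampCnThreshold
  if (!any(sel)) return(NULL)
  s <- BiocGenerics::start(segments)[sel]; e <- BiocGenerics::end(segments)[sel]
  o <- order(s); s <- s[o]; e <- cummax(e[o])
  grp <- cumsum(c(1, as.integer(s[-1] - e[-length(e)] - 1 >
                                  params$maxEventBp)))
  ms <- as.numeric(tapply(s, grp, min)); me <- as.numeric(tapply(e, grp, max))
  lS <- BiocGenerics::start(locus); lE <- BiocGenerics::end(locus)
  hit <- which(ms <= lE & me >= lS)
  if (length(hit) == 0L) return(NULL)
  GRanges(chrom, IRanges(ms[hit[1]], me[hit[1]]))
}

#' Run event-timing classification over a cohort's deletion calls
#'
#' Classifies every focal-deletion carrier that also has an amplification
#' spanning the target locus (carriers without one are not informative for
#' ordering and are omitted).  Per-sample ambiguity reasons are reported;
#' the enrichment summary is computed over non-ambiguous verdicts only.
#'
#' @param calls a calls data.frame from \code{\link{callFocalDeletions}}.
#' @param segments the cohort \linkS4class{CNSegments}.
#' @param locus the target \linkS4class{GeneLocus}.
#' @param params a \code{\link{callerParams}} list (amplification
#'   threshold and dip-bridging width).
#' @param allelicTol see \code{\link{classifyTiming}}.
#' @return A list with \code{calls} (data.frame: sample, verdict, reason,
#'   amp_allele_outside, amp_allele_inside) and \code{summary} (a
#'   \code{TimingSummary}; errors with "no informative samples" when every
#'   verdict is ambiguous).
#' @export
runTiming <- function(calls, segments, locus, params = callerParams(),
                      allelicTol = 0.3) {
  carriers <- carrierSamples(calls)
  idxBySample <- split(seq_along(segments), segSample(segments))
  rows <- list()
  for (s in carriers) {
    sub <- segments[idxBySample[[s]]]
    amp <- .ampInterval(sub, locus, params)
    if (is.null(amp)) next
    cs <- calls[calls$sample == s & calls$focal, , drop = FALSE]
    del <- GRanges(cs$chrom[1], IRanges(cs$start[1], cs$end[1]))
    tc <- classifyTiming(sub, amp, del, allelicTol)
    rows[[s]] <- data.frame(sample = s, verdict = tc$verdict,
                            reason = tc$reason,
                            amp_allele_outside = tc$amp_allele_outside,
                            amp_allele_inside = tc$amp_allele_inside,
                            stringsAsFactors = FALSE)
  }
  tcalls <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
            else data.frame(sample = character(), verdict = character(),
                            reason = character(),
                            amp_allele_outside = numeric(),
                            amp_allele_inside = numeric())
  summary <- timingBinomialTest(
    sum(tcalls$verdict == "amplification_first"),
    sum(tcalls$verdict == "deletion_first"))
  list(calls = tcalls, summary = summary)
}
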