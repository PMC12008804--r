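#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges findOverlaps pintersect reduce
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom GenomeInfoDb seqnames
NULL

# tolerance used when checking minor <= total/2 on real-valued copy numbers
.CN_TOL <- 1e-6

#' Per-sample allele-specific copy-number segments
#'
#' A \linkS4class{GRanges} subclass in which every range is one copy-number
#' segment of one tumor sample.  Required metadata columns are
#' \code{sample} (sample identifier), \code{total_cn} (total copy number,
#' non-negative real) and \code{minor_cn} (copy number of the less abundant
#' parental haplotype; may be \code{NA} when allelic information is not
#' available).  Segments belonging to the same sample and chromosome must
#' not overlap.
#'
#' Coordinates follow the Bioconductor convention (1-based, closed); the
#' on-disk SEG dialect handled by \code{\link{readSeg}} / \code{\link{writeSeg}}
#' is 0-based half-open and is converted at the IO boundary.
#'
#' @seealso \code{\link{CNSegments}}, \code{\link{readSeg}}, \code{\link{locusCN}}
#' @export
setClass("CNSegments", contains = "GRanges")

setValidity("CNSegments", function(object) {
  m <- mcols(object)
  need <- c("sample", "total_cn", "minor_cn")
  if (!all(need %in% colnames(m)))
    return(sprintf("missing metadata column(s): %s",
                   paste(setdiff(need, colnames(m)), collapse = ", ")))
  if (length(object) == 0L) return(TRUE)
  if (any(is.na(m$total_cn)) || any(m$total_cn < 0))
    return("total_cn must be non-negative and non-missing")
  bad <- !is.na(m$minor_cn) & (m$minor_cn < 0 |
                               m$minor_cn > m$total_cn / 2 + .CN_TOL)
  if (any(bad))
    return("minor_cn must satisfy 0 <= minor_cn <= total_cn/2")
  # same-sample, same-chromosome segments must not overlap
  for (s in unique(m$sample)) {
    gr <- granges(object)[m$sample == s]
    hits <- findOverlaps(gr, gr, ignore.strand = TRUE)
    if (length(hits) > length(gr))
      return(sprintf("overlapping segments for sample '%s' on %s", s,
                     paste(unique(as.character(seqnames(gr))), collapse = ",")))
  }
  TRUE
})

#' Construct a CNSegments object
#'
#' @param sample character vector of sample identifiers.
#' @param chrom character vector of chromosome names.
#' @param start,end 1-based closed interval bounds (\code{start <= end}).
#' @param total_cn total copy number per segment (non-negative real).
#' @param minor_cn minor-allele copy number per segment; \code{NA} when
#'   allelic information is unavailable.
#' @return A \linkS4class{CNSegments} object.
#' @examples
#' seg <- CNSegments("s1", "chrS", 1, 1000, total_cn = 2, minor_cn = 1)
#' totalCN(seg)
#' @export
CNSegments <- function(sample, chrom, start, end, total_cn,
                       minor_cn = NA_real_) {
  n <- max(length(sample), length(chrom), length(start), length(end),
           length(total_cn), length(minor_cn))
  gr <- GRanges(rep_len(chrom, n), IRanges(rep_len(start, n), rep_len(end, n)))
  mcols(gr) <- DataFrame(sample   = rep_len(as.character(sample), n),
                         total_cn = rep_len(as.numeric(total_cn), n),
                         minor_cn = rep_len(as.numeric(minor_cn), n))
  new("CNSegments", sort(gr, ignore.strand = TRUE))
}

#' @describeIn CNSegments total copy number accessor
#' @param x a \code{CNSegments} object.
#' @export
totalCN <- function(x) mcols(x)$total_cn

#' @describeIn CNSegments minor-allele copy number accessor
#' @export
minorCN <- function(x) mcols(x)$minor_cn

#' @describeIn CNSegments sample identifier accessor
#' @export
segSample <- function(x) mcols(x)$sample

#' Structural-variant junctions (breakpoint pairs)
#'
#' Each junction joins two breakends.  A breakend is a (chromosome,
#' position, orientation) triple where the position is a 0-based inter-base
#' coordinate (the breakpoint falls between reference base \code{pos} and
#' \code{pos + 1}) and orientation \code{"+"} means the joined fragment
#' continues toward lower coordinates from the breakend (the left flank is
#' retained) while \code{"-"} means it continues toward higher coordinates.
#' A simple deletion therefore produces a junction whose lower breakend is
#' \code{"+"} and whose higher breakend is \code{"-"}: both point outward
#' from the lost interval.  Breakends are stored sorted by (chrom, pos).
#'
#' @slot junctions a \code{data.frame} with columns \code{sample},
#'   \code{chrom1}, \code{pos1}, \code{strand1}, \code{chrom2}, \code{pos2},
#'   \code{strand2}, \code{name}.
#' @seealso \code{\link{SVJunctions}}, \code{\link{readBedpe}},
#'   \code{\link{isDeletionConsistent}}
#' @export
setClass("SVJunctions", representation(junctions = "data.frame"))

setValidity("SVJunctions", function(object) {
  j <- object@junctions
  need <- c("sample", "chrom1", "pos1", "strand1",
            "chrom2", "pos2", "strand2", "name")
  if (!all(need %in% colnames(j)))
    return(sprintf("missing column(s): %s",
                   paste(setdiff(need, colnames(j)), collapse = ", ")))
  if (nrow(j) == 0L) return(TRUE)
  if (!all(j$strand1 %in% c("+", "-")) || !all(j$strand2 %in% c("+", "-")))
    return("breakend orientations must be '+' or '-'")
  if (any(j$pos1 < 0) || any(j$pos2 < 0))
    return("breakend positions must be >= 0")
  swapped <- j$chrom1 > j$chrom2 | (j$chrom1 == j$chrom2 & j$pos1 > j$pos2)
  if (any(swapped))
    return("breakends must be sorted by (chrom, pos) within each junction")
  TRUE
})

#' Construct an SVJunctions object
#'
#' Breakends are canonicalized so that end 1 precedes end 2 in genome order.
#'
#' @param sample sample identifiers.
#' @param chrom1,pos1,strand1 first breakend (0-based inter-base position).
#' @param chrom2,pos2,strand2 second breakend.
#' @param name junction identifiers (default \code{jx1, jx2, ...}).
#' @return An \linkS4class{SVJunctions} object.
#' @export
SVJunctions <- function(sample = character(), chrom1 = character(),
                        pos1 = integer(), strand1 = character(),
                        chrom2 = character(), pos2 = integer(),
                        strand2 = character(), name = NULL) {
  n <- length(pos1)
  if (is.null(name)) name <- if (n) paste0("jx", seq_len(n)) else character()
  j <- data.frame(sample = as.character(sample),
                  chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                  strand1 = as.character(strand1),
                  chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                  strand2 = as.character(strand2),
                  name = as.character(name),
                  stringsAsFactors = FALSE)
  swap <- j$chrom1 > j$chrom2 | (j$chrom1 == j$chrom2 & j$pos1 > j$pos2)
  if (any(swap)) {
    j[swap, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")] <-
      j[swap, c("chrom2", "pos2", "strand2", "chrom1", "pos1", "strand1")]
  }
  new("SVJunctions", junctions = j)
}

#' @describeIn SVJunctions number of junctions
#' @param x an \code{SVJunctions} object.
#' @export
setMethod("length", "SVJunctions", function(x) nrow(x@junctions))

#' @describeIn SVJunctions junction table as a data.frame
#' @export
junctionTable <- function(x) x@junctions

#' Deletion-consistent orientation test
#'
#' A junction is deletion-consistent when both breakends sit on the same
#' chromosome and point outward from the bracketed interval: the lower
#' breakend has orientation \code{"+"} and the higher \code{"-"}.  This is
#' the breakpoint signature of a simple copy-loss.
#'
#' @param x an \linkS4class{SVJunctions} object.
#' @return Logical vector, one element per junction.
#' @export
isDeletionConsistent <- function(x) {
  j <- junctionTable(x)
  j$chrom1 == j$chrom2 & j$strand1 == "+" & j$strand2 == "-"
}

#' Interval bracketed by each intra-chromosomal junction
#'
#' Converts each same-chromosome junction into the 1-based closed genomic
#' interval lying strictly between its breakends (the putative deleted
#' segment for deletion-consistent junctions).
#'
#' @param x an \linkS4class{SVJunctions} object (same-chromosome junctions).
#' @return A \code{GRanges} with one range per junction and metadata column
#'   \code{name}.
#' @export
junctionSpan <- function(x) {
  j <- junctionTable(x)
  stopifnot(all(j$chrom1 == j$chrom2))
  gr <- GRanges(j$chrom1, IRanges(j$pos1 + 1, pmax(j$pos2, j$pos1 + 1)))
  mcols(gr)$name <- j$name
  mcols(gr)$sample <- j$sample
  gr
}

setMethod("show", "SVJunctions", function(object) {
  cat(sprintf("SVJunctions with %d junction(s) from %d sample(s)\n",
              length(object), length(unique(object@junctions$sample))))
  if (length(object)) print(utils::head(object@junctions, 6L))
})

#' Binned tumor/normal read-depth ratio track for one sample
#'
#' A \code{GRanges} subclass of uniform-width bins (conventionally 200 bp;
#' the final bin of a chromosome may be shorter) carrying the metadata
#' column \code{depth_ratio} (tumor/normal depth ratio, \eqn{\ge 0}; 1
#' corresponds to diploid).  Bins are sorted and non-overlapping.
#'
#' @slot sample sample identifier.
#' @slot binWidth nominal bin width in bp.
#' @seealso \code{\link{ReadDepthTrack}}, \code{\link{readBedgraph}}
#' @export
setClass("ReadDepthTrack", contains = "GRanges",
         representation(sample = "character", binWidth = "integer"))

setValidity("ReadDepthTrack", function(object) {
  m <- mcols(object)
  if (!"depth_ratio" %in% colnames(m))
    return("missing metadata column 'depth_ratio'")
  if (length(object) == 0L) return(TRUE)
  if (any(!is.finite(m$depth_ratio)) || any(m$depth_ratio < 0))
    return("depth_ratio must be finite and >= 0")
  w <- BiocGenerics::width(object)
  bw <- object@binWidth
  # uniform bins; the last bin per chromosome may be short
  perchr <- split(seq_along(object), as.character(seqnames(object)))
  for (idx in perchr) {
    if (any(w[idx[-length(idx)]] != bw) || w[idx[length(idx)]] > bw)
      return(sprintf("bins must have uniform width %d bp (last may be short)", bw))
    st <- BiocGenerics::start(object)[idx]
    if (is.unsorted(st, strictly = TRUE))
      return("bins must be sorted")
    if (any(BiocGenerics::end(object)[idx][-length(idx)] >= st[-1]))
      return("bins must be non-overlapping")
  }
  TRUE
})

#' Construct a ReadDepthTrack
#'
#' @param sample sample identifier (length 1).
#' @param chrom chromosome per bin.
#' @param start,end 1-based closed bin bounds.
#' @param depth_ratio tumor/normal depth ratio per bin.
#' @param binWidth nominal bin width (default 200).
#' @return A \linkS4class{ReadDepthTrack}.
#' @export
ReadDepthTrack <- function(sample, chrom, start, end, depth_ratio,
                           binWidth = 200L) {
  gr <- GRanges(chrom, IRanges(start, end))
  mcols(gr)$depth_ratio <- as.numeric(depth_ratio)
  gr <- sort(gr, ignore.strand = TRUE)
  new("ReadDepthTrack", gr, sample = as.character(sample),
      binWidth = as.integer(binWidth))
}

#' @describeIn ReadDepthTrack depth-ratio accessor
#' @param x a \code{ReadDepthTrack}.
#' @export
depthRatio <- function(x) mcols(x)$depth_ratio

#' @describeIn ReadDepthTrack sample identifier accessor
#' @export
trackSample <- function(x) x@sample

#' A named gene locus with an optional sub-window
#'
#' A length-1 \code{GRanges} subclass describing a gene interval, optionally
#' carrying a sub-window (for example the promoter-proximal exon 1-intron 1
#' region that is the hotspot of nested focal deletions at the target gene).
#'
#' @slot geneName gene name.
#' @slot window a \code{GRanges} of length 0 (no window) or 1, contained in
#'   the gene interval.
#' @seealso \code{\link{GeneLocus}}, \code{\link{readBedLoci}}
#' @export
setClass("GeneLocus", contains = "GRanges",
         representation(geneName = "character", window = "GRanges"))

setValidity("GeneLocus", function(object) {
  if (length(object) != 1L) return("a GeneLocus is a single interval")
  if (length(object@window) > 1L) return("window must have length 0 or 1")
  if (length(object@window) == 1L) {
    ok <- as.character(seqnames(object@window)) ==
            as.character(seqnames(object)) &&
          BiocGenerics::start(object@window) >= BiocGenerics::start(object) &&
          BiocGenerics::end(object@window) <= BiocGenerics::end(object)
    if (!ok) return("window must be contained in the gene interval")
  }
  TRUE
})

#' Construct a GeneLocus
#'
#' @param name gene name.
#' @param chrom chromosome.
#' @param start,end 1-based closed gene bounds.
#' @param windowStart,windowEnd optional sub-window bounds (1-based closed),
#'   contained in \code{[start, end]}.
#' @return A \linkS4class{GeneLocus}.
#' @examples
#' GeneLocus("BRD4L", "chrS", 3000001, 3100000,
#'           windowStart = 3005001, windowEnd = 3080000)
#' @export
GeneLocus <- function(name, chrom, start, end,
                      windowStart = NULL, windowEnd = NULL) {
  win <- if (is.null(windowStart)) GRanges() else
    GRanges(chrom, IRanges(windowStart, windowEnd))
  new("GeneLocus", GRanges(chrom, IRanges(start, end)),
      geneName = as.character(name), window = win)
}

#' @describeIn GeneLocus gene name accessor
#' @param x a \code{GeneLocus}.
#' @export
geneName <- function(x) x@geneName

#' @describeIn GeneLocus sub-window accessor (GRanges of length 0 or 1)
#' @export
locusWindow <- function(x) x@window

setMethod("show", "GeneLocus", function(object) {
  cat(sprintf("GeneLocus %s: %s:%d-%d%s\n", object@geneName,
              as.character(seqnames(object)),
              BiocGenerics::start(object), BiocGenerics::end(object),
              if (length(object@window))
                sprintf(" (window %d-%d)",
                        BiocGenerics::start(object@window),
                        BiocGenerics::end(object@window)) else ""))
})
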