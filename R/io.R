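#' @importFrom utils read.delim write.table head
#' @importFrom rtracklayer import export
NULL

# ---- SEG-like allele-specific copy-number tables -------------------------

#' Read / write allele-specific copy-number segments (SEG dialect)
#'
#' The dialect is a tab-separated table with header columns \code{sample},
#' \code{chrom}, \code{start}, \code{end}, \code{total_cn}, \code{minor_cn}
#' (the last may be absent or \code{NA}: downstream timing then reports the
#' affected samples as lacking allelic information).  Coordinates on disk
#' are 0-based half-open; absolute (not log-ratio) copy numbers are
#' expected.  Overlapping same-sample segments are rejected.  Gzipped files
#' are read transparently.
#'
#' @param path file path.
#' @return \code{readSeg} returns a \linkS4class{CNSegments};
#'   \code{writeSeg} writes its canonical form (sorted; write then read is
#'   the identity) and returns \code{path} invisibly.
#' @examples
#' seg <- CNSegments("s1", "chrS", 1, 1000, 2, 1)
#' f <- tempfile(fileext = ".seg")
#' writeSeg(seg, f)
#' identical(readSeg(f), seg)
#' @export
readSeg <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t",
                  colClasses = "character", check.names = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn")
  if (!all(need %in% colnames(d)))
    stop(sprintf("SEG parse error: missing column(s) %s in '%s'",
                 paste(setdiff(need, colnames(d)), collapse = ", "), path))
  if (!"minor_cn" %in% colnames(d)) d$minor_cn <- NA
  num <- function(col) suppressWarnings(as.numeric(d[[col]]))
  start <- num("start"); end <- num("end")
  total <- num("total_cn"); minor <- num("minor_cn")
  bad <- which(is.na(start) | is.na(end) | is.na(total) |
                 (is.na(minor) & !(is.na(d$minor_cn) | d$minor_cn %in%
                                     c("NA", ""))))
  bad <- union(bad, which(is.nan(total) | is.nan(minor)))
  if (length(bad))
    stop(sprintf("SEG parse error at line %d of '%s': non-numeric value",
                 bad[1] + 1L, path))
  badiv <- which(end <= start)
  if (length(badiv))
    stop(sprintf("SEG parse error at line %d of '%s': end <= start",
                 badiv[1] + 1L, path))
  CNSegments(d$sample, d$chrom, start + 1, end, total, minor)
}

#' @rdname readSeg
#' @param segments a \linkS4class{CNSegments}.
#' @export
writeSeg <- function(segments, path) {
  stopifnot(is(segments, "CNSegments"))
  o <- order(segSample(segments), as.character(seqnames(segments)),
             BiocGenerics::start(segments))
  d <- data.frame(sample = segSample(segments)[o],
                  chrom = as.character(seqnames(segments))[o],
                  start = BiocGenerics::start(segments)[o] - 1L,
                  end = BiocGenerics::end(segments)[o],
                  total_cn = totalCN(segments)[o],
                  minor_cn = minorCN(segments)[o])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- BEDPE junctions -----------------------------------------------------

#' Read / write SV junctions (BEDPE)
#'
#' Ten-column BEDPE minimum (chrom1, start1, end1, chrom2, start2, end2,
#' name, score, strand1, strand2) with an optional eleventh \code{sample}
#' column; lines starting with \code{#} (or a \code{chrom1} header) are
#' skipped.  Breakends are point positions taken from the interval starts
#' (width-1 intervals accepted); ends are stored sorted in genome order.
#' Orientation symbols outside \code{+}/\code{-} are a parse error.
#'
#' @param path file path.
#' @param sample sample identifier used when the file has no sample column.
#' @return \code{readBedpe} returns an \linkS4class{SVJunctions};
#'   \code{writeBedpe} returns \code{path} invisibly.
#' @export
readBedpe <- function(path, sample = "sample1") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  lines <- lines[!grepl("^chrom1\\b", lines)]
  if (length(lines) == 0L)
    return(SVJunctions())
  d <- read.delim(text = lines, header = FALSE, sep = "\t",
                  colClasses = "character")
  if (ncol(d) < 10L)
    stop(sprintf("BEDPE parse error in '%s': expected >= 10 columns, got %d",
                 path, ncol(d)))
  colnames(d)[1:10] <- c("chrom1", "start1", "end1", "chrom2", "start2",
                         "end2", "name", "score", "strand1", "strand2")
  badStrand <- which(!(d$strand1 %in% c("+", "-")) |
                       !(d$strand2 %in% c("+", "-")))
  if (length(badStrand))
    stop(sprintf("BEDPE parse error at record %d of '%s': orientation must be '+' or '-'",
                 badStrand[1], path))
  p1 <- suppressWarnings(as.numeric(d$start1))
  p2 <- suppressWarnings(as.numeric(d$start2))
  if (any(is.na(p1)) || any(is.na(p2)))
    stop(sprintf("BEDPE parse error in '%s': non-numeric position", path))
  samp <- if (ncol(d) >= 11L) d[[11L]] else rep(sample, nrow(d))
  SVJunctions(samp, d$chrom1, p1, d$strand1, d$chrom2, p2, d$strand2,
              name = d$name)
}

#' @rdname readBedpe
#' @param junctions an \linkS4class{SVJunctions}.
#' @export
writeBedpe <- function(junctions, path) {
  stopifnot(is(junctions, "SVJunctions"))
  j <- junctionTable(junctions)
  d <- data.frame(chrom1 = j$chrom1, start1 = format(j$pos1, scientific = FALSE, trim = TRUE),
                  end1 = format(j$pos1 + 1, scientific = FALSE, trim = TRUE),
                  chrom2 = j$chrom2, start2 = format(j$pos2, scientific = FALSE, trim = TRUE),
                  end2 = format(j$pos2 + 1, scientific = FALSE, trim = TRUE),
                  name = j$name, score = ".",
                  strand1 = j$strand1, strand2 = j$strand2,
                  sample = j$sample)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(d), collapse = "\t")), con)
  if (nrow(d))
    write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

# ---- bedGraph read-depth tracks ------------------------------------------

#' Read / write a binned read-depth ratio track (bedGraph)
#'
#' Standard 4-column bedGraph (0-based half-open); values are tumor/normal
#' depth ratios.  Bins must share one uniform width (the last bin may be
#' short); \code{NaN} or negative values are rejected.
#'
#' @param path file path.
#' @param sample sample identifier for the returned track (defaults to the
#'   file base name).
#' @return \code{readBedgraph} returns a \linkS4class{ReadDepthTrack};
#'   \code{writeBedgraph} returns \code{path} invisibly.
#' @export
readBedgraph <- function(path, sample = sub("\\.bedgraph(\\.gz)?$", "",
                                            basename(path))) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L)
    stop(sprintf("bedGraph '%s' is empty", path))
  if (any(is.nan(gr$score)))
    stop(sprintf("bedGraph parse error in '%s': NaN depth ratio", path))
  w <- sort(unique(BiocGenerics::width(gr)), decreasing = TRUE)
  ReadDepthTrack(sample, as.character(seqnames(gr)),
                 BiocGenerics::start(gr), BiocGenerics::end(gr),
                 gr$score, binWidth = w[1])
}

#' @rdname readBedgraph
#' @param track a \linkS4class{ReadDepthTrack}.
#' @export
writeBedgraph <- function(track, path) {
  stopifnot(is(track, "ReadDepthTrack"))
  gr <- granges(track)
  mcols(gr)$score <- depthRatio(track)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# ---- BED gene loci -------------------------------------------------------

#' Read gene loci from a BED file
#'
#' Standard BED (0-based half-open) with a name column.  A record named
#' \code{<gene>_window} is attached as the sub-window of gene
#' \code{<gene>} rather than forming a locus of its own.
#'
#' @param path BED file path.
#' @return A named list of \linkS4class{GeneLocus} objects.
#' @export
readBedLoci <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || any(is.na(gr$name)))
    stop(sprintf("BED parse error in '%s': every locus needs a name", path))
  isWin <- grepl("_window$", gr$name)
  genes <- gr[!isWin]
  wins <- gr[isWin]
  out <- lapply(seq_along(genes), function(i) {
    nm <- genes$name[i]
    wi <- which(wins$name == paste0(nm, "_window"))
    GeneLocus(nm, as.character(seqnames(genes))[i],
              BiocGenerics::start(genes)[i], BiocGenerics::end(genes)[i],
              windowStart = if (length(wi)) BiocGenerics::start(wins)[wi[1]]
                            else NULL,
              windowEnd = if (length(wi)) BiocGenerics::end(wins)[wi[1]]
                          else NULL)
  })
  names(out) <- genes$name
  out
}

#' @rdname readBedLoci
#' @param loci named list of \linkS4class{GeneLocus}.
#' @export
writeBedLoci <- function(loci, path) {
  rows <- lapply(loci, function(l) {
    d <- data.frame(chrom = as.character(seqnames(l)),
                    start = BiocGenerics::start(l) - 1L,
                    end = BiocGenerics::end(l), name = geneName(l))
    w <- locusWindow(l)
    if (length(w))
      d <- rbind(d, data.frame(chrom = as.character(seqnames(w)),
                               start = BiocGenerics::start(w) - 1L,
                               end = BiocGenerics::end(w),
                               name = paste0(geneName(l), "_window")))
    d
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- expression matrices -------------------------------------------------

.EXPR_ANNOT_COLS <- c("gene", "class", "isoform", "chrom", "biotype")

#' Read / write an FPKM expression table
#'
#' Tab-separated matrix: first column \code{feature_id}, optional
#' annotation columns (\code{gene}, \code{class}, \code{isoform},
#' \code{chrom}, \code{biotype}), then one numeric column per sample.
#' Negative or \code{NaN} values are rejected with the offending cell
#' named; feature and sample identifiers must be unique.
#'
#' @param path file path.
#' @return \code{readExpression} returns a
#'   \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{fpkm}; \code{writeExpression} returns \code{path} invisibly.
#' @export
readExpression <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (colnames(d)[1] != "feature_id")
    stop(sprintf("expression parse error in '%s': first column must be 'feature_id'", path))
  if (anyDuplicated(d$feature_id))
    stop(sprintf("expression parse error in '%s': duplicate feature_id", path))
  annot <- intersect(.EXPR_ANNOT_COLS, colnames(d))
  sampleCols <- setdiff(colnames(d), c("feature_id", annot))
  if (anyDuplicated(sampleCols))
    stop(sprintf("expression parse error in '%s': duplicate sample column", path))
  mat <- as.matrix(d[, sampleCols, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- d$feature_id
  bad <- which(is.nan(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("expression parse error in '%s': negative or NaN FPKM at feature '%s', sample '%s'",
                 path, rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  rowInfo <- DataFrame(feature_id = d$feature_id)
  for (a in annot) rowInfo[[a]] <- d[[a]]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat), rowData = rowInfo,
    colData = DataFrame(sample = sampleCols, row.names = sampleCols))
}

#' @rdname readExpression
#' @param se a \code{SummarizedExperiment} with assay \code{fpkm}.
#' @export
writeExpression <- function(se, path) {
  mat <- SummarizedExperiment::assay(se, "fpkm")
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  d <- data.frame(feature_id = rownames(mat), check.names = FALSE)
  for (a in intersect(.EXPR_ANNOT_COLS, colnames(rd))) d[[a]] <- rd[[a]]
  d <- cbind(d, as.data.frame(mat, check.names = FALSE))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sample metadata -----------------------------------------------------

#' Read / write the sample metadata table
#'
#' Tab-separated with columns \code{sample}, \code{tumor_type} and
#' optionally \code{patient} (defaulting to the sample id); sample
#' identifiers must be unique.
#'
#' @param path file path.
#' @return \code{readSamples} returns a data.frame; \code{writeSamples}
#'   returns \code{path} invisibly.
#' @export
readSamples <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t",
                  colClasses = "character")
  need <- c("sample", "tumor_type")
  if (!all(need %in% colnames(d)))
    stop(sprintf("sample-table parse error in '%s': missing column(s) %s",
                 path, paste(setdiff(need, colnames(d)), collapse = ", ")))
  if (anyDuplicated(d$sample))
    stop(sprintf("sample-table parse error in '%s': duplicate sample id", path))
  if (!"patient" %in% colnames(d)) d$patient <- d$sample
  d
}

#' @rdname readSamples
#' @param samples a data.frame with columns sample, tumor_type, patient.
#' @export
writeSamples <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- truth ledger --------------------------------------------------------

#' Read / write the simulator truth ledger (JSON)
#'
#' @param path file path.
#' @return \code{readTruth} returns the truth data.frame;
#'   \code{writeTruth} returns \code{path} invisibly.
#' @export
readTruth <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname readTruth
#' @param truth truth data.frame from \code{\link{simulateCohort}}.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", na = "null",
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# ---- YAML simulation config ----------------------------------------------

#' Read a simulation configuration from YAML
#'
#' The YAML keys mirror the \code{\link{simConfig}} arguments; the
#' \code{exprCoeffs} key is a mapping with \code{baselineByType},
#' \code{betaCN} and \code{betaDel}.  Unknown keys are a configuration
#' error naming the offending field.
#'
#' @param path YAML file path.
#' @return A \linkS4class{SimConfig}.
#' @export
readSimConfigYaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("invalid configuration: unknown field(s) %s",
                 paste(unknown, collapse = ", ")))
  if (!is.null(y$exprCoeffs))
    y$exprCoeffs <- expressionCoeffs(
      baselineByType = unlist(y$exprCoeffs$baselineByType),
      betaCN = y$exprCoeffs$betaCN, betaDel = y$exprCoeffs$betaDel)
  if (!is.null(y$tumorTypeWeights))
    y$tumorTypeWeights <- unlist(y$tumorTypeWeights)
  do.call(simConfig, y)
}
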