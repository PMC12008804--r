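#' @importFrom stats pnorm pt qt dhyper p.adjust lm confint coef
#'   model.matrix relevel t.test complete.cases setNames
#' @importFrom utils combn
NULL

# exact two-sided rank-sum p by enumeration of all nx-subsets of the
# pooled ranks; two-sidedness by symmetry of |W - E[W]| around the null
# center.  Used for combined n <= 12 where enumeration is cheap.
.rankSumExactP <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  E <- length(x) * (n + 1) / 2
  sets <- combn(n, length(x))
  S <- colSums(matrix(r[sets], nrow = length(x)))
  mean(abs(S - E) >= abs(W - E) - 1e-9)
}

#' Two-group rank-sum comparison of locus copy numbers
#'
#' Two-sided Wilcoxon rank-sum test: exact by enumeration of all group
#' assignments for combined n at most \code{exactMax}, tie-corrected
#' normal approximation otherwise.  Group means and medians are reported
#' alongside.  When every value in both groups is identical the statistic
#' sits at its null center and p = 1, with a zero-variance flag.
#'
#' @param carriers,noncarriers numeric vectors of per-sample locus copy
#'   numbers (or any two groups of finite values).
#' @param exactMax combined-size threshold below which the exact
#'   enumeration is used (default 12).
#' @return A \code{GroupComparison}: list with group summaries, rank-sum
#'   \code{statistic} (sum of ranks of the first group), \code{p_value},
#'   \code{test} (\code{"exact"} or \code{"normal_approx"}),
#'   \code{sidedness}, \code{zero_variance}.
#' @examples
#' compareLocusCN(c(1, 2, 3), c(4, 5, 6))$p_value  # exact, 0.1
#' @export
compareLocusCN <- function(carriers, noncarriers, exactMax = 12L) {
  stopifnot(length(carriers) >= 1, length(noncarriers) >= 1,
            all(is.finite(carriers)), all(is.finite(noncarriers)))
  nx <- length(carriers); ny <- length(noncarriers); n <- nx + ny
  r <- rank(c(carriers, noncarriers))
  W <- sum(r[seq_len(nx)])
  zeroVar <- length(unique(c(carriers, noncarriers))) == 1L
  if (zeroVar) {
    p <- 1; test <- "degenerate"
  } else if (n <= exactMax) {
    p <- .rankSumExactP(carriers, noncarriers); test <- "exact"
  } else {
    U <- W - nx * (nx + 1) / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - nx * ny / 2) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z)); test <- "normal_approx"
  }
  structure(list(groups = c("carriers", "noncarriers"),
                 n = c(nx, ny),
                 means = c(mean(carriers), mean(noncarriers)),
                 medians = c(stats::median(carriers),
                             stats::median(noncarriers)),
                 statistic = W, p_value = min(1, p), test = test,
                 sidedness = "two-sided", zero_variance = zeroVar),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("%s comparison (%s): p = %.4g [%s]\n",
              paste(x$groups, collapse = " vs "), x$sidedness, x$p_value,
              x$test))
  invisible(x)
}

#' Fisher's exact test for deletion/amplification co-occurrence
#'
#' Two-sided exact test on the 2x2 table of focal-deletion status against
#' amplification status, computed by enumerating the hypergeometric
#' support and summing the probabilities of all tables at most as likely
#' as the observed one.  The sample odds ratio is reported; when a cell
#' is zero a 0.5 continuity correction is applied to the odds ratio only,
#' and flagged.  A table with an all-zero margin carries no information
#' and yields p = 1.
#'
#' @param nAmpDel,nAmpNodel,nNoampDel,nNoampNodel non-negative integer
#'   cells: deletion carriers / non-carriers among amplified and
#'   non-amplified samples.
#' @return A \code{GroupComparison} with \code{odds_ratio},
#'   \code{continuity} flag, \code{p_value}.
#' @examples
#' cooccurrenceFisher(3, 1, 1, 3)$p_value  # 34/70
#' @export
cooccurrenceFisher <- function(nAmpDel, nAmpNodel, nNoampDel, nNoampNodel) {
  cells <- c(nAmpDel, nAmpNodel, nNoampDel, nNoampNodel)
  if (any(cells < 0)) stop("negative cell count")
  if (sum(cells) < 1) stop("empty table")
  a <- nAmpDel; b <- nAmpNodel; cc <- nNoampDel; d <- nNoampNodel
  m <- a + b; n2 <- cc + d; k <- a + cc
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    p <- 1
  } else {
    supp <- max(0, k - n2):min(k, m)
    probs <- dhyper(supp, m, n2, k)
    pObs <- dhyper(a, m, n2, k)
    p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  }
  continuity <- any(cells == 0)
  or <- if (continuity) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  structure(list(groups = c("amplified", "non-amplified"),
                 table = matrix(cells, 2, 2, byrow = TRUE,
                                dimnames = list(c("amp", "noamp"),
                                                c("del", "nodel"))),
                 odds_ratio = or, continuity = continuity,
                 statistic = a, p_value = min(1, p),
                 test = "fisher_exact", sidedness = "two-sided",
                 zero_variance = FALSE),
            class = "GroupComparison")
}

#' Copy-number-adjusted expression
#'
#' Rescales FPKM to the diploid state using the copy number of the
#' neighbor gene: \code{adjusted = fpkm * 2 / cn(neighbor)}.  The neighbor
#' is used because copy number within the target gene is variable by
#' definition in focal-deletion carriers.  Normalizing to diploid (x2/CN
#' rather than x1/CN) keeps adjusted and unadjusted values in the same
#' units; adjustment is the identity at CN 2.  Samples whose neighbor
#' copy number is missing or non-positive are dropped with a warning
#' naming them.
#'
#' @param expr a \code{SummarizedExperiment} with assay \code{fpkm}.
#' @param segments the cohort \linkS4class{CNSegments}.
#' @param neighbor the neighbor \linkS4class{GeneLocus}.
#' @return A \code{SummarizedExperiment} of the retained samples with the
#'   adjusted assay \code{fpkm} and a colData column
#'   \code{neighbor_cn}.
#' @export
cnAdjustedExpression <- function(expr, segments, neighbor) {
  samples <- colnames(expr)
  cn <- locusCN(segments, neighbor, samples)
  bad <- is.na(cn) | cn <= 0
  if (any(bad))
    warning(sprintf("dropping sample(s) with missing or non-positive neighbor copy number: %s",
                    paste(samples[bad], collapse = ", ")))
  keep <- !bad
  out <- expr[, keep]
  mat <- SummarizedExperiment::assay(out, "fpkm")
  mat <- sweep(mat, 2, 2 / cn[keep], `*`)
  SummarizedExperiment::assay(out, "fpkm") <- mat
  SummarizedExperiment::colData(out)$neighbor_cn <- unname(cn[keep])
  out
}

#' Fit the gene-dosage linear model
#'
#' Ordinary least-squares fit of target-gene FPKM on absolute copy
#' number, focal-deletion status and tumor type (reference level
#' \code{Other}), with 95\% confidence intervals from the t distribution.
#' Samples from the same patient are collapsed to per-patient means
#' BEFORE fitting (copy number averaged, deletion status OR-ed), so
#' multiply-profiled patients do not receive extra weight.
#'
#' @param fpkm numeric vector of target-gene FPKM per sample.
#' @param cn absolute locus copy number per sample.
#' @param delStatus logical focal-deletion carrier flag per sample.
#' @param tumorType character tumor type per sample.
#' @param patient patient identifier per sample (default: one sample per
#'   patient).
#' @param refLevel reference tumor type (default \code{"Other"}).
#' @return A \code{DosageModelFit}: list with \code{coefficients} (a
#'   data.frame: term, estimate, ci_lower, ci_upper), \code{sigma},
#'   \code{n}, and the underlying \code{lm} fit.
#' @export
fitDosageModel <- function(fpkm, cn, delStatus, tumorType,
                           patient = NULL, refLevel = "Other") {
  n0 <- length(fpkm)
  stopifnot(length(cn) == n0, length(delStatus) == n0,
            length(tumorType) == n0)
  if (is.null(patient)) patient <- paste0("p", seq_len(n0))
  d <- data.frame(fpkm = fpkm, cn = cn, del = as.logical(delStatus),
                  type = as.character(tumorType),
                  patient = as.character(patient))
  # per-patient collapsing before fitting
  u <- unique(d[c("patient", "type")])
  if (anyDuplicated(u$patient))
    stop(sprintf("patient '%s' has inconsistent tumor types",
                 u$patient[anyDuplicated(u$patient)]))
  grp <- factor(d$patient)
  cnt <- as.vector(table(grp))
  d <- data.frame(fpkm = as.vector(rowsum(d$fpkm, grp)) / cnt,
                  cn = as.vector(rowsum(d$cn, grp)) / cnt,
                  del = as.vector(rowsum(as.numeric(d$del), grp)) > 0,
                  type = u$type[match(levels(grp), u$patient)])
  if (length(unique(d$type)) < 2L)
    stop("at least two tumor-type levels are required")
  d$type <- factor(d$type)
  if (refLevel %in% levels(d$type)) d$type <- relevel(d$type, refLevel)
  X <- model.matrix(~ cn + del + type, d)
  if (qr(X)$rank < ncol(X)) {
    qx <- qr(X)
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")))
  }
  if (nrow(d) <= ncol(X))
    stop("more coefficients than patients")
  fit <- lm(fpkm ~ cn + del + type, data = d)
  ci <- confint(fit, level = 0.95)
  co <- data.frame(term = names(coef(fit)), estimate = unname(coef(fit)),
                   ci_lower = ci[, 1], ci_upper = ci[, 2],
                   row.names = NULL)
  structure(list(coefficients = co, sigma = summary(fit)$sigma,
                 n = nrow(d), fit = fit, ref_level = refLevel),
            class = "DosageModelFit")
}

#' @export
print.DosageModelFit <- function(x, ...) {
  cat(sprintf("Dosage linear model (n = %d patients, reference type %s)\n",
              x$n, x$ref_level))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Per-gene differential expression with Bonferroni and fold-change gates
#'
#' Fits an ordinary per-gene linear model on \code{log2(FPKM + 1)} with a
#' carrier indicator and tumor-type covariates (one shared design for all
#' genes, solved by a single QR decomposition).  The reported log2 fold
#' change is the carrier coefficient (the tumor-type-adjusted group
#' difference).  Bonferroni q = min(1, p * nGenes); a gene passes iff
#' q < \code{qCut} and |log2FC| >= \code{lfcCut}.  Empirical-Bayes
#' moderation and precision weighting are deliberately not applied: this
#' is a plain per-gene OLS test.  Zero-variance genes get p = 1, are
#' flagged, and never pass.  Testing is restricted to a provided gene
#' list (by contract, autosomal protein-coding genes).
#'
#' @param expr \code{SummarizedExperiment} with assay \code{fpkm}.
#' @param carrierFlags logical per-sample carrier status.
#' @param tumorType character per-sample tumor type (set \code{NULL} to
#'   fit the unadjusted model).
#' @param genes genes to test (default: all rows).
#' @param qCut,lfcCut pass thresholds: Bonferroni q below 0.1 and at
#'   least a 2-fold change (|log2FC| >= 1) by default.
#' @return A \code{data.frame} sorted by p: gene, log2fc, p, q, pass,
#'   zero_variance; thresholds in attributes.
#' @export
differentialExpression <- function(expr, carrierFlags, tumorType = NULL,
                                   genes = rownames(expr),
                                   qCut = 0.1, lfcCut = 1) {
  stopifnot(length(carrierFlags) == ncol(expr))
  if (sum(carrierFlags) < 2L || sum(!carrierFlags) < 2L)
    stop("need at least 2 carriers and 2 non-carriers")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop(sprintf("gene(s) not in expression table: %s",
                 paste(head(missing, 5), collapse = ", ")))
  Y <- log2(SummarizedExperiment::assay(expr, "fpkm")[genes, , drop = FALSE] + 1)
  df <- data.frame(carrier = as.numeric(carrierFlags))
  form <- ~carrier
  if (!is.null(tumorType)) {
    df$type <- factor(tumorType)
    form <- ~ carrier + type
  }
  X <- model.matrix(form, df)
  qx <- qr(X)
  resDf <- nrow(X) - qx$rank
  coefs <- qr.coef(qx, t(Y))             # p x nGenes
  resid <- t(Y) - X %*% coefs
  sigma2 <- colSums(resid^2) / resDf
  XtXinv <- solve(crossprod(X))
  seCar <- sqrt(sigma2 * XtXinv["carrier", "carrier"])
  lfc <- coefs["carrier", ]
  zeroVar <- sigma2 < 1e-12
  tstat <- ifelse(zeroVar, 0, lfc / seCar)
  p <- ifelse(zeroVar, 1, 2 * pt(-abs(tstat), resDf))
  q <- pmin(1, p * length(genes))
  out <- data.frame(gene = genes, log2fc = unname(lfc), p = unname(p),
                    q = unname(q),
                    pass = unname(q < qCut & abs(lfc) >= lfcCut & !zeroVar),
                    zero_variance = unname(zeroVar))
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(qCut = qCut, lfcCut = lfcCut,
                                  n_genes = length(genes))
  out
}

#' ORF-screen log fold change and isoform toxicity comparison
#'
#' \code{orfLfc} computes \code{log2((late + pc) / (early + pc))} from
#' barcode abundances at the early and late timepoints of a pooled
#' overexpression screen; a negative value indicates the construct
#' depleted over time, i.e. gene toxicity.  \code{orfIsoformCompare}
#' contrasts per-cell-line log fold changes of two isoforms with a paired
#' two-tailed t test.
#'
#' @param early,late non-negative abundance vectors.
#' @param pseudocount added to both abundances (default 0; with 0, a pair
#'   of zero abundances is undefined and an error).
#' @return \code{orfLfc}: numeric vector of log2 fold changes.
#' @examples
#' orfLfc(100, 25)  # -2: four-fold depletion, a growth deficit
#' @export
orfLfc <- function(early, late, pseudocount = 0) {
  stopifnot(length(early) == length(late), all(early >= 0), all(late >= 0),
            pseudocount >= 0)
  if (pseudocount == 0 && any(early == 0 & late == 0))
    stop("log fold change undefined: both abundances zero with pseudocount 0")
  log2((late + pseudocount) / (early + pseudocount))
}

#' @rdname orfLfc
#' @param lfcLong,lfcShort paired per-cell-line log2 fold changes of the
#'   long and short isoform constructs.
#' @return \code{orfIsoformCompare}: a \code{GroupComparison} (paired
#'   two-tailed t test; a negative mean difference short - long means the
#'   short isoform is more toxic).
#' @export
orfIsoformCompare <- function(lfcLong, lfcShort) {
  stopifnot(length(lfcLong) == length(lfcShort), length(lfcLong) >= 2)
  tt <- t.test(lfcShort, lfcLong, paired = TRUE)
  structure(list(groups = c("short", "long"),
                 n = c(length(lfcShort), length(lfcLong)),
                 means = c(mean(lfcShort), mean(lfcLong)),
                 medians = c(stats::median(lfcShort),
                             stats::median(lfcLong)),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, test = "paired_t",
                 sidedness = "two-sided", zero_variance = FALSE),
            class = "GroupComparison")
}
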