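# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately written as naive enumerations, independent of
# the package's own code paths.

# one sample with a flat amplification (totalAmp copies, minor 1) carrying
# an internal dip segment [delStart, delEnd] at the given inside state
ampDipSegments <- function(sample = "s1", chrom = "chrS",
                           ampStart = 1e6, ampEnd = 4e6,
                           delStart = 3.02e6, delEnd = 3.05e6,
                           totalAmp = 5, minorAmp = 1,
                           totalIn = 4, minorIn = 1,
                           genomeLength = 5e6) {
  CNSegments(rep(sample, 5), chrom,
             start = c(1, ampStart, delStart, delEnd + 1, ampEnd + 1),
             end = c(ampStart - 1, delStart - 1, delEnd, ampEnd,
                     genomeLength),
             total_cn = c(2, totalAmp, totalIn, totalAmp, 2),
             minor_cn = c(1, minorAmp, minorIn, minorAmp, 1))
}

# deletion-consistent junction pair bracketing [delStart, delEnd] (1-based)
deletionJunction <- function(sample = "s1", chrom = "chrS",
                             delStart = 3.02e6, delEnd = 3.05e6,
                             name = "jx1") {
  SVJunctions(sample, chrom, delStart - 1, "+", chrom, delEnd, "-",
              name = name)
}

# flat depth track with a dip of the given ratios over [delStart, delEnd]
dipDepthTrack <- function(sample = "s1", chrom = "chrS",
                          from = 2.9e6, to = 3.2e6,
                          delStart = 3.02e6, delEnd = 3.05e6,
                          flankRatio = 2.5, insideRatio = 1.5) {
  s <- seq(from, to, by = 200)
  e <- pmin(s + 199, to)
  mid <- (s + e) / 2
  r <- ifelse(mid >= delStart & mid <= delEnd, insideRatio, flankRatio)
  ReadDepthTrack(sample, chrom, s, e, r)
}

# the package's default target locus
targetLocus <- function() defaultGenomeLayout()@target
neighborLocus <- function() defaultGenomeLayout()@neighbor

# ---- brute-force oracles -------------------------------------------------

# two-sided rank-sum p by exhaustive assignment enumeration (naive loop)
bruteRankSumP <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_along(x)])
  ctr <- length(x) * (n + 1) / 2
  sets <- utils::combn(n, length(x))
  stats <- apply(sets, 2, function(ix) sum(r[ix]))
  sum(abs(stats - ctr) >= abs(obs - ctr) - 1e-9) / ncol(sets)
}

# two-sided Fisher p by enumerating tables with the observed margins,
# probabilities from log-factorials (not dhyper)
bruteFisherP <- function(a, b, c2, d) {
  r1 <- a + b; r2 <- c2 + d; k <- a + c2; n <- r1 + r2
  lp <- function(x) {
    lchoose(r1, x) + lchoose(r2, k - x) - lchoose(n, k)
  }
  supp <- max(0, k - r2):min(k, r1)
  probs <- exp(vapply(supp, lp, numeric(1)))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}

# one-sided binomial tail by enumerating all 2^n orderings
bruteBinomTailP <- function(nA, nB) {
  n <- nA + nB; k <- max(nA, nB)
  hits <- 0
  for (code in 0:(2^n - 1)) {
    ones <- sum(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (ones >= k) hits <- hits + 1
  }
  hits / 2^n
}

# base-by-base mean copy number over a locus (oracle for locusCN)
bruteLocusMeanCN <- function(starts, ends, cns, locusStart, locusEnd) {
  pos <- locusStart:locusEnd
  val <- rep(NA_real_, length(pos))
  for (i in seq_along(starts)) {
    hit <- pos >= starts[i] & pos <= ends[i]
    val[hit] <- cns[i]
  }
  mean(val, na.rm = TRUE)
}
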