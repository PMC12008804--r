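#' Derive a deterministic sub-stream seed from a master seed
#'
#' Stage-level randomness (expression emission, pipeline stages) uses
#' sub-seeds derived from one master seed so that a single integer
#' reproduces a whole run.  The derivation is a fixed affine map modulo
#' 2^31 - 1, keeping every derived seed in 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param stage stage index (integer).
#' @return An integer seed.
#' @export
subSeed <- function(seed, stage) {
  v <- ((as.numeric(seed) %% 2147483647) * 48271 +
          as.numeric(stage) * 9973) %% 2147483647
  as.integer(v)
}

# overlap-length-weighted mean of a per-segment value over a locus;
# uncovered bases are excluded from the weighting.  Plain arithmetic (no
# range machinery): this sits inside per-sample loops.
.weightedOverlapMean <- function(gr, values, locus) {
  ls <- BiocGenerics::start(locus)[1]; le <- BiocGenerics::end(locus)[1]
  w <- pmin(BiocGenerics::end(gr), le) - pmax(BiocGenerics::start(gr), ls) + 1
  keep <- w > 0 &
    as.character(seqnames(gr)) == as.character(seqnames(locus))[1]
  if (!any(keep)) return(NA_real_)
  sum(w[keep] * values[keep]) / sum(w[keep])
}
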