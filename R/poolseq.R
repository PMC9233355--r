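# Pooled-sequencing sampling noise at read-count level: the read-level
# pipeline (read simulation, alignment, variant calling) is abstracted into
# a binomial draw per locus, isolating the statistical effect of finite
# sequencing depth and per-read error on the allele-frequency track.

#' Simulate pooled-sequencing read counts from true allele frequencies
#'
#' Per locus, sequencing depth is either fixed or Poisson around
#' `meanDepth`, and the alt-allele read count is Binomial(depth, p') with
#' p' = AF * (1 - e) + (1 - AF) * e, where `e` is the per-read allele error
#' rate (a read reports the wrong allele with probability `e`).
#'
#' @param af an [AFTrack-class] of true pooled allele frequencies.
#' @param meanDepth mean reads per locus (>= 1).
#' @param depthModel `"poisson"` (default) or `"fixed"`.
#' @param errorRate per-read allele error rate in [0, 0.5).
#' @param seed optional RNG seed.
#' @return A [ReadCountTrack-class].
#' @export
simulateReadCounts <- function(af, meanDepth, depthModel = c("poisson", "fixed"),
                               errorRate = 0.001, seed = NULL) {
  stopifnot(is(af, "AFTrack"))
  depthModel <- match.arg(depthModel)
  .assert(meanDepth >= 1, "meanDepth must be >= 1")
  .assert(errorRate >= 0 && errorRate < 0.5, "errorRate must lie in [0, 0.5)")
  .set_seed(seed)
  df <- af@loci
  m <- nrow(df)
  depth <- if (depthModel == "fixed") rep.int(as.integer(round(meanDepth)), m)
           else stats::rpois(m, meanDepth)
  p <- df$af * (1 - errorRate) + (1 - df$af) * errorRate
  alt <- stats::rbinom(m, depth, p)
  new("ReadCountTrack",
      counts = data.frame(chrom = df$chrom, bp = df$bp,
                          depth = depth, alt = alt, stringsAsFactors = FALSE))
}

#' Estimate allele frequencies from pooled read counts
#'
#' AF = alt / depth per locus; loci below the minimum depth are dropped and
#' counted in the returned track's filter report (zero-depth loci always
#' drop, with a warning when `minDepth` would have kept them).
#'
#' @param rc a [ReadCountTrack-class].
#' @param minDepth minimum reads per locus (default 1).
#' @return An [AFTrack-class]; `filterReport$low_depth` counts dropped loci.
#' @export
afFromReadCounts <- function(rc, minDepth = 1) {
  stopifnot(is(rc, "ReadCountTrack"))
  df <- rc@counts
  if (minDepth < 1 && any(df$depth == 0))
    warning("zero-depth loci dropped despite minDepth < 1")
  keep <- df$depth >= max(minDepth, 1)
  out <- AFTrack(chrom = df$chrom[keep], bp = df$bp[keep],
                 af = df$alt[keep] / df$depth[keep])
  out@filterReport <- list(low_depth = sum(!keep))
  out
}
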