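#' Generate a synthetic reference genetic map
#'
#' Builds a multi-chromosome marker map with physical (bp) and genetic (cM)
#' coordinates to play the role of a reference ("true") map in simulations.
#' Markers are equally spaced in bp. The `"uniform"` profile spreads the
#' genetic length evenly over the physical axis; `"barley_like"` suppresses
#' recombination in the middle third of each chromosome (pericentromeric
#' pattern typical of large cereal genomes), placing at least 70% of the
#' genetic length in the two outer thirds.
#'
#' Defaults approximate a barley-scale genome: 7 chromosomes of 600 Mb and
#' 150 cM each, 1500 markers per chromosome.
#'
#' @param nChrom number of chromosomes.
#' @param markersPerChrom markers per chromosome (>= 2).
#' @param chromLenBp physical chromosome length in bp.
#' @param totalCm total genome genetic length in cM, divided equally over
#'   chromosomes.
#' @param profile `"barley_like"` (default) or `"uniform"`.
#' @param pericentromericWeight relative per-bp recombination intensity of
#'   the middle third under `"barley_like"` (outer thirds have weight 1).
#' @return A [GeneticMap-class] of kind `"true"`.
#' @examples
#' m <- makeSyntheticMap(1, 11, 1e8, 100, profile = "uniform")
#' markerTable(m)$pos   # 0, 10, ..., 100
#' @export
makeSyntheticMap <- function(nChrom = 7, markersPerChrom = 1500,
                             chromLenBp = 6e8, totalCm = 1050,
                             profile = c("barley_like", "uniform"),
                             pericentromericWeight = 0.15) {
  profile <- match.arg(profile)
  .assert(nChrom >= 1 && markersPerChrom >= 2, "need >= 1 chromosome with >= 2 markers")
  .assert(chromLenBp >= markersPerChrom, "chromosome too short for the requested marker count")
  .assert(totalCm > 0, "total genetic length must be positive")
  .assert(pericentromericWeight > 0 && pericentromericWeight <= 1,
          "pericentromericWeight must be in (0, 1]")

  cm_per_chrom <- totalCm / nChrom
  m <- markersPerChrom
  bp <- unique(round(seq(1, chromLenBp, length.out = m)))
  .assert(length(bp) == m, "marker bp positions collapsed; increase chromLenBp")

  mid <- (bp[-m] + bp[-1L]) / 2
  w <- if (profile == "uniform") rep(1, m - 1L)
       else ifelse(mid > chromLenBp / 3 & mid <= 2 * chromLenBp / 3,
                   pericentromericWeight, 1)
  inc <- diff(bp) * w
  pos <- c(0, cumsum(inc)) * (cm_per_chrom / sum(inc))

  GeneticMap(chrom = rep(paste0("chr", seq_len(nChrom)), each = m),
             bp = rep(bp, nChrom), pos = rep(pos, nChrom),
             units = "cM", kind = "true")
}
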