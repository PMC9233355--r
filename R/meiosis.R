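# Haldane (no-interference) meiosis: per chromosome, crossover counts are
# Poisson in the genetic length (Morgans), crossover positions uniform on the
# cM axis, and markers between the same crossovers share parental origin.

# origins for n gametes over one chromosome's marker cM vector (origin 0)
.meiosis_origins_chrom <- function(cm, n) {
  m <- length(cm)
  L <- cm[m]
  k <- stats::rpois(n, L / 100)           # cM -> Morgans
  start <- sample.int(2L, n, replace = TRUE) - 1L
  out <- matrix(start, n, m)              # zero-crossover gametes done
  for (i in which(k > 0L)) {
    xo <- sort(stats::runif(k[i], 0, L))
    out[i, ] <- (start[i] + findInterval(cm, xo)) %% 2L
  }
  list(origins = out, counts = k)
}

# n gametes over all chromosomes of a map data.frame (chrom, bp, pos/cM)
.meiosis_origins <- function(mapdf, n, poscol = "pos") {
  per <- .split_chrom(mapdf)
  res <- lapply(per, function(sub) .meiosis_origins_chrom(sub[[poscol]] - sub[[poscol]][1L], n))
  list(origins = do.call(cbind, lapply(res, `[[`, "origins")),
       counts = Reduce(`+`, lapply(res, `[[`, "counts")))
}

# one gamete per parent from n parents given as two haplotype matrices
.gametes_from_parents <- function(h1, h2, mapdf) {
  o <- .meiosis_origins(mapdf, nrow(h1))$origins
  g <- h1
  sel <- o == 1L
  g[sel] <- h2[sel]
  g
}

#' Simulate F1 gametes under Haldane meiosis
#'
#' Draws `n` gametes from an F1 individual of a cross between two fully
#' homozygous inbred parents: per chromosome the crossover count is
#' Poisson-distributed in the genetic length (Morgans), crossover positions
#' are uniform on the cM axis, the starting parent is Bernoulli(0.5), and
#' the parental origin switches at every crossover.
#'
#' @param map a [GeneticMap-class] giving marker cM positions.
#' @param n number of gametes.
#' @param seed optional RNG seed fixing all randomness.
#' @param returnCrossoverCounts attach the per-gamete total crossover count
#'   as attribute `"crossovers"`.
#' @return integer matrix (`n` x markers) of parent-of-origin in {0, 1}.
#' @export
simulateGametes <- function(map, n, seed = NULL, returnCrossoverCounts = FALSE) {
  stopifnot(is(map, "GeneticMap"))
  .assert(n >= 1, "n must be >= 1")
  .set_seed(seed)
  res <- .meiosis_origins(map@markers, n)
  out <- res$origins
  if (returnCrossoverCounts) attr(out, "crossovers") <- res$counts
  out
}

.genotype_matrix <- function(dosage, mapdf) {
  new("GenotypeMatrix",
      dosage = dosage,
      markers = data.frame(chrom = mapdf$chrom, bp = mapdf$bp, cM = mapdf$pos,
                           stringsAsFactors = FALSE))
}

#' Simulate an F2 population
#'
#' Each F2 individual is the sum of two independent F1 gametes
#' ([simulateGametes()]), giving a parent-2 allele dosage in {0, 1, 2} at
#' every marker. Expected pooled allele frequency at every locus is 0.5;
#' deviations are pure drift of the finite population.
#'
#' @param map a [GeneticMap-class].
#' @param n population size (number of F2 individuals).
#' @param seed optional RNG seed.
#' @return A [GenotypeMatrix-class].
#' @export
simulateF2 <- function(map, n, seed = NULL) {
  stopifnot(is(map, "GeneticMap"))
  .assert(n >= 1, "n must be >= 1")
  .set_seed(seed)
  o <- .meiosis_origins(map@markers, 2L * n)$origins
  odd <- seq(1L, 2L * n, by = 2L)
  .genotype_matrix(o[odd, , drop = FALSE] + o[odd + 1L, , drop = FALSE], map@markers)
}

#' Simulate a recombinant inbred line (RIL) population
#'
#' Starts from an F2 (one selfing generation after the F1) and applies
#' further generations of selfing with independent meioses. With
#' `selfingGenerations = Inf`, selfing is iterated until all loci are fixed
#' (at most `maxGenerations` rounds); any residual heterozygous locus is
#' then resolved by a fair coin per locus per individual, so dosages end in
#' {0, 2}. Inter-marker recombinant fractions then follow the
#' Haldane-Waddington expectation R = 2r / (1 + 2r), roughly doubling the
#' recombination events visible in an F2.
#'
#' @param map a [GeneticMap-class].
#' @param n population size.
#' @param selfingGenerations number of selfing generations counted from the
#'   F1 (1 = F2); `Inf` for fully inbred lines.
#' @param seed optional RNG seed.
#' @param maxGenerations cap on selfing rounds under `Inf`.
#' @return A [GenotypeMatrix-class].
#' @export
simulateRIL <- function(map, n, selfingGenerations = Inf, seed = NULL,
                        maxGenerations = 50L) {
  stopifnot(is(map, "GeneticMap"))
  .assert(n >= 1, "n must be >= 1")
  .assert(selfingGenerations >= 1, "selfingGenerations must be >= 1 (1 = F2)")
  .set_seed(seed)
  mapdf <- map@markers

  o <- .meiosis_origins(mapdf, 2L * n)$origins
  odd <- seq(1L, 2L * n, by = 2L)
  h1 <- o[odd, , drop = FALSE]            # F2 haplotype pairs
  h2 <- o[odd + 1L, , drop = FALSE]

  self_once <- function() {
    a <- .gametes_from_parents(h1, h2, mapdf)
    b <- .gametes_from_parents(h1, h2, mapdf)
    h1 <<- a; h2 <<- b
  }

  if (is.finite(selfingGenerations)) {
    for (g in seq_len(selfingGenerations - 1L)) self_once()
  } else {
    g <- 1L
    while (any(h1 != h2) && g < maxGenerations) { self_once(); g <- g + 1L }
    het <- h1 != h2                       # residual heterozygotes: fair coin
    if (any(het)) {
      coin <- as.integer(stats::runif(sum(het)) < 0.5)
      h1[het] <- coin; h2[het] <- coin
    }
  }
  .genotype_matrix(h1 + h2, mapdf)
}

#' Subsample markers to a genotyping depth
#'
#' Draws a uniform random subset (without replacement) of the map's markers,
#' preserving physical order; genetic positions are re-origined so the first
#' retained marker of each chromosome sits at 0 (map lengths then span the
#' retained markers, as for any estimated map). When `depth` equals the
#' available marker count the map is returned unchanged and no random number
#' is drawn.
#'
#' @param map a [GeneticMap-class].
#' @param depth number of markers to retain (2 <= depth <= nMarkers(map)).
#' @param seed optional RNG seed.
#' @return A [GeneticMap-class] with `depth` markers.
#' @export
subsampleMarkers <- function(map, depth, seed = NULL) {
  stopifnot(is(map, "GeneticMap"))
  m <- nMarkers(map)
  .assert(depth >= 2 && depth <= m, "depth must lie in [2, %d]", m)
  if (depth == m) return(map)
  .set_seed(seed)
  keep <- sort(sample.int(m, depth))
  df <- map@markers[keep, , drop = FALSE]
  for (ch in unique(df$chrom)) {
    i <- df$chrom == ch
    df$pos[i] <- df$pos[i] - df$pos[i][1L]
    if (sum(i) < 2L)
      warning(sprintf("chromosome %s retained < 2 markers at depth %d", ch, depth))
  }
  rownames(df) <- NULL
  new("GeneticMap", markers = df, units = map@units, kind = map@kind)
}

#' Pool individual genotypes into allele frequencies
#'
#' Discards individual information by computing, per marker, the pooled
#' frequency of the parent-2 allele over non-missing calls:
#' AF = sum(dosage) / (2 * non-missing count). Markers with no non-missing
#' call are excluded with a warning and counted in the track's filter report.
#'
#' @param g a [GenotypeMatrix-class].
#' @return An [AFTrack-class] with per-locus `af` and `missing_frac`.
#' @export
poolAlleleFreq <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- g@dosage
  nonmiss <- colSums(!is.na(d))
  af <- colSums(d, na.rm = TRUE) / (2 * nonmiss)
  keep <- nonmiss > 0L
  if (!all(keep))
    warning(sprintf("%d marker(s) with no non-missing call excluded", sum(!keep)))
  out <- AFTrack(chrom = g@markers$chrom[keep], bp = g@markers$bp[keep],
                 af = af[keep], missing_frac = 1 - nonmiss[keep] / nrow(d))
  if (!all(keep)) out@filterReport <- list(all_missing = sum(!keep))
  out
}
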