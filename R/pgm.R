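#' Filter an allele-frequency track for pool-map construction
#'
#' Applies the marker filters used before K computation, in this order:
#' loci with missing physical position; all rows of any duplicated
#' (chrom, bp) position; monomorphic loci (AF exactly 0 or 1); loci below
#' a minor-allele-frequency floor; loci whose missing fraction exceeds
#' `maxMissing` (strictly greater than, so exactly-at-threshold loci are
#' retained). Removal counts per reason are stored in the returned track's
#' `filterReport`.
#'
#' @param af an [AFTrack-class].
#' @param maxMissing maximum tolerated missing fraction (default 0.10).
#' @param minMaf minimum minor-allele frequency (default 0, i.e. off).
#' @param dropMonomorphic drop AF in {0, 1} (default TRUE).
#' @return A filtered [AFTrack-class].
#' @export
filterMarkers <- function(af, maxMissing = 0.10, minMaf = 0, dropMonomorphic = TRUE) {
  stopifnot(is(af, "AFTrack"))
  df <- af@loci
  report <- list()

  bad_pos <- is.na(df$bp)
  report$missing_position <- sum(bad_pos)
  df <- df[!bad_pos, , drop = FALSE]

  key <- paste(df$chrom, df$bp)
  dup <- key %in% key[duplicated(key)]    # every copy of a duplicated position goes
  report$duplicated_position <- sum(dup)
  df <- df[!dup, , drop = FALSE]

  if (dropMonomorphic) {
    mono <- df$af %in% c(0, 1)
    report$monomorphic <- sum(mono)
    df <- df[!mono, , drop = FALSE]
  }
  if (minMaf > 0) {
    low <- pmin(df$af, 1 - df$af) < minMaf
    report$low_maf <- sum(low)
    df <- df[!low, , drop = FALSE]
  }
  toomiss <- df$missing_frac > maxMissing
  report$high_missing <- sum(toomiss)
  df <- df[!toomiss, , drop = FALSE]

  if (nrow(df) == 0L) {
    worst <- names(report)[which.max(unlist(report))]
    stop(sprintf("no markers survive filtering (dominating filter: %s, %d loci)",
                 worst, max(unlist(report))), call. = FALSE)
  }
  rownames(df) <- NULL
  out <- new("AFTrack", loci = df)
  out@filterReport <- report
  out
}

#' Compute adjacent-pair K factors
#'
#' For each physically adjacent marker pair (M1, M2) on the same chromosome,
#' K = |AF1 - AF2| / log10(bp2 - bp1): the allele-frequency difference of
#' neighbouring loci, scaled by the decadic log of their physical distance,
#' is the relative local recombination signal of the pool. Pairs closer than
#' `minDistBp` (which would make the log non-positive at 1 bp) contribute a
#' zero-length increment and are flagged `dropped`.
#'
#' @param af a filtered, sorted [AFTrack-class] with >= 2 loci on at least
#'   one chromosome.
#' @param minDistBp minimum inter-marker distance in bp (default 2). For the
#'   coarser locus thinning sometimes advisable on very dense tracks see
#'   [thinMarkers()].
#' @return A raw [KPairSet-class].
#' @examples
#' af <- AFTrack("1", c(1e5, 2e5), c(0.52, 0.50))
#' markerTable(computeK(af))$K   # 0.02 / 5 = 0.004
#' @export
computeK <- function(af, minDistBp = 2) {
  stopifnot(is(af, "AFTrack"))
  .assert(minDistBp >= 2, "minDistBp must be >= 2 (log10 of 1 bp is 0)")
  df <- af@loci
  .assert(any(table(df$chrom) >= 2), "need >= 2 loci on at least one chromosome")
  per <- .split_chrom(df)
  pairs <- do.call(rbind, lapply(per, function(sub) {
    m <- nrow(sub)
    if (m < 2L) return(NULL)
    data.frame(chrom = sub$chrom[-m], left_bp = sub$bp[-m], right_bp = sub$bp[-1L],
               delta_af = abs(diff(sub$af)), dist_bp = diff(sub$bp),
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  pairs$dropped <- pairs$dist_bp < minDistBp
  pairs$K <- ifelse(pairs$dropped, 0, pairs$delta_af / log10(pairs$dist_bp))
  new("KPairSet", pairs = pairs,
      markers = df[, c("chrom", "bp", "af")],
      adjusted = FALSE, adjStart = NA_real_)
}

#' Thin a track to a minimum inter-locus distance
#'
#' Greedy left-to-right thinning: walking each chromosome in physical order,
#' a locus is kept only if it lies at least `minDistBp` beyond the last kept
#' locus. Useful on dense sequencing-derived tracks where very close pairs
#' carry more noise than recombination signal.
#'
#' @param af an [AFTrack-class].
#' @param minDistBp minimum distance between retained loci (bp).
#' @return A thinned [AFTrack-class].
#' @export
thinMarkers <- function(af, minDistBp) {
  stopifnot(is(af, "AFTrack"))
  .assert(minDistBp >= 1, "minDistBp must be >= 1")
  df <- af@loci
  keep <- unlist(lapply(.split_chrom(df), function(sub) {
    last <- -Inf
    vapply(sub$bp, function(p) {
      if (p - last >= minDistBp) { last <<- p; TRUE } else FALSE
    }, logical(1))
  }), use.names = FALSE)
  out <- new("AFTrack", loci = { d <- df[keep, , drop = FALSE]; rownames(d) <- NULL; d })
  out@filterReport <- c(af@filterReport, list(thinned = sum(!keep)))
  out
}

#' Accumulate K factors into a pool genetic map
#'
#' Marker positions are the cumulative sum of the adjacent-pair K values
#' along each chromosome (origin 0 at the first marker); the chromosome map
#' length is the last position and the genome length their sum. With
#' `useAdjusted = TRUE` the pairs must carry adjusted K' values
#' ([applyAdjustment()]) and the result is an nPGM in cM; otherwise a raw
#' PGM in unit-free K.
#'
#' @param pairs a [KPairSet-class].
#' @param useAdjusted build from adjusted K' (default FALSE).
#' @return A [GeneticMap-class] of kind `"pgm"` or `"npgm"`.
#' @export
buildPGM <- function(pairs, useAdjusted = FALSE) {
  stopifnot(is(pairs, "KPairSet"))
  if (useAdjusted && !pairs@adjusted)
    stop("useAdjusted = TRUE but the K pairs carry no adjustment; see applyAdjustment()",
         call. = FALSE)
  if (!useAdjusted && pairs@adjusted)
    stop("adjusted K pairs must be built with useAdjusted = TRUE (no mixing of scales)",
         call. = FALSE)
  mk <- pairs@markers
  pr <- pairs@pairs
  pos <- unlist(lapply(.split_chrom(mk), function(sub) {
    if (nrow(sub) < 2L) return(0)
    k <- pr$K[pr$chrom == sub$chrom[1L]]
    c(0, cumsum(k))
  }), use.names = FALSE)
  GeneticMap(chrom = mk$chrom, bp = mk$bp, pos = pos,
             units = if (useAdjusted) "cM" else "K",
             kind = if (useAdjusted) "npgm" else "pgm")
}
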