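# Two-point genetic map from individual F2 genotypes: per adjacent marker
# pair, the recombination fraction is the maximum-likelihood estimate under
# the F2 intercross model (EM over the nine dosage-pair classes, with the
# double-heterozygote phase ambiguity resolved in the E-step and a symmetric
# genotyping-error probability mixed into the emissions), then transformed
# to cM by Haldane's mapping function and accumulated along the chromosome.

.RF_RMAX <- 0.4999

# gamete haplotypes over two loci: (allele at M1, allele at M2);
# (0,0) and (1,1) parental, (0,1) and (1,0) recombinant
.rf_haps <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
.rf_rec <- c(0L, 1L, 1L, 0L)

# 16 ordered gamete-pair configs -> observed 9-class emission matrix and
# per-config recombinant-gamete count
.rf_tables <- function(error_prob) {
  cfg <- expand.grid(i = 1:4, j = 1:4)
  d1 <- .rf_haps[cfg$i, 1L] + .rf_haps[cfg$j, 1L]
  d2 <- .rf_haps[cfg$i, 2L] + .rf_haps[cfg$j, 2L]
  rec <- .rf_rec[cfg$i] + .rf_rec[cfg$j]
  emit1 <- function(obs, true) ifelse(obs == true, 1 - error_prob, error_prob / 2)
  M <- matrix(0, 16L, 9L)                     # M[c, o]: P(observed class o | config c)
  for (o1 in 0:2) for (o2 in 0:2)
    M[, o1 * 3L + o2 + 1L] <- emit1(o1, d1) * emit1(o2, d2)
  list(M = M, rec = rec, i = cfg$i, j = cfg$j)
}

# EM on a 9-vector of dosage-pair counts (class index = g1*3 + g2 + 1)
.rf_em <- function(counts9, error_prob, tol = 1e-9, max_iter = 2000L,
                   tb = .rf_tables(error_prob)) {
  n <- sum(counts9)
  r <- 0.25
  for (iter in seq_len(max_iter)) {
    p4 <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
    w <- p4[tb$i] * p4[tb$j]                  # config priors
    denom <- colSums(w * tb$M)                # P(observed class o | r)
    erec <- colSums(w * tb$rec * tb$M) / denom
    r_new <- sum(counts9 * erec) / (2 * n)
    r_new <- min(max(r_new, 0), .RF_RMAX)
    done <- abs(r_new - r) < tol
    r <- r_new
    if (done) break
  }
  p4 <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  denom <- colSums(p4[tb$i] * p4[tb$j] * tb$M)
  list(rhat = r, loglik = sum(counts9 * log(denom)))
}

#' Two-point recombination fractions between adjacent markers
#'
#' For every physically adjacent marker pair of an F2 dosage matrix,
#' estimates the maximum-likelihood recombination fraction via EM over the
#' nine joint dosage classes. `errorProb` enters as a symmetric per-locus
#' dosage misclassification probability in the emissions. Pairs with fewer
#' than `minInformative` jointly non-missing individuals are skipped
#' (`rhat = NA`) with a warning.
#'
#' @param g a [GenotypeMatrix-class] with markers in physical order.
#' @param errorProb genotyping-error probability (default 0.0001).
#' @param minInformative minimum jointly non-missing individuals per pair
#'   (default 10).
#' @return An [RfPairSet-class].
#' @export
estimateRfAdjacent <- function(g, errorProb = 1e-4, minInformative = 10L) {
  stopifnot(is(g, "GenotypeMatrix"))
  .assert(errorProb >= 0 && errorProb < 1, "errorProb must lie in [0, 1)")
  d <- g@dosage
  mk <- g@markers
  tb <- .rf_tables(errorProb)
  chrom_idx <- split(seq_len(nrow(mk)), factor(mk$chrom, levels = unique(mk$chrom)))
  np <- sum(pmax(lengths(chrom_idx) - 1L, 0L))
  chrom <- character(np); left <- right <- rhat <- ll <- numeric(np)
  n_inf <- integer(np)
  p <- 0L
  for (idx in chrom_idx) {
    m <- length(idx)
    if (m < 2L) next
    for (j in seq_len(m - 1L)) {
      p <- p + 1L
      g1 <- d[, idx[j]]; g2 <- d[, idx[j + 1L]]
      ok <- !is.na(g1) & !is.na(g2)
      chrom[p] <- mk$chrom[idx[j]]
      left[p] <- mk$bp[idx[j]]; right[p] <- mk$bp[idx[j + 1L]]
      n_inf[p] <- sum(ok)
      if (n_inf[p] < minInformative) {
        rhat[p] <- NA_real_; ll[p] <- NA_real_
        next
      }
      counts9 <- tabulate(g1[ok] * 3L + g2[ok] + 1L, nbins = 9L)
      em <- .rf_em(counts9, errorProb, tb = tb)
      rhat[p] <- em$rhat; ll[p] <- em$loglik
    }
  }
  skipped <- sum(is.na(rhat))
  if (skipped > 0L)
    warning(sprintf("%d interval(s) skipped with < %d jointly non-missing individuals",
                    skipped, minInformative))
  pairs <- data.frame(chrom = chrom, left_bp = left, right_bp = right,
                      rhat = rhat, n_informative = n_inf, loglik = ll,
                      stringsAsFactors = FALSE)
  new("RfPairSet", pairs = pairs,
      markers = mk[, c("chrom", "bp")], errorProb = errorProb)
}

#' Haldane mapping function
#'
#' d = -50 * ln(1 - 2r) centiMorgans, for recombination fractions
#' 0 <= r < 0.5 under no crossover interference.
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @param clamp if TRUE, values >= 0.5 are clamped to 0.4999 with a warning
#'   instead of raising an error.
#' @return map distance(s) in cM.
#' @export
haldaneDistance <- function(r, clamp = FALSE) {
  .assert(all(is.finite(r)) && all(r >= 0), "r must be finite and >= 0")
  if (any(r >= 0.5)) {
    if (!clamp) stop("recombination fraction >= 0.5 has infinite Haldane distance",
                     call. = FALSE)
    warning("recombination fraction(s) >= 0.5 clamped to 0.4999")
    r <- pmin(r, .RF_RMAX)
  }
  -50 * log(1 - 2 * r)
}

#' Inverse Haldane mapping function
#'
#' r = (1 - exp(-d / 50)) / 2 for distances d >= 0 cM; exact inverse of
#' [haldaneDistance()] on [0, 0.5).
#'
#' @param d map distance(s) in cM (>= 0).
#' @return recombination fraction(s).
#' @export
haldaneInverse <- function(d) {
  .assert(all(is.finite(d)) && all(d >= 0), "d must be finite and >= 0")
  (1 - exp(-d / 50)) / 2
}

#' Accumulate recombination fractions into a Haldane genetic map
#'
#' Transforms each adjacent-pair recombination fraction with Haldane's
#' mapping function and accumulates the distances along every chromosome
#' (origin 0 at the first marker). Skipped intervals (`rhat = NA`) are
#' interpolated as zero length with a warning.
#'
#' @param rf an [RfPairSet-class].
#' @return A [GeneticMap-class] of kind `"hgm"` in cM.
#' @export
buildHGM <- function(rf) {
  stopifnot(is(rf, "RfPairSet"))
  pr <- rf@pairs
  mk <- rf@markers
  if (any(is.na(pr$rhat)))
    warning(sprintf("%d skipped interval(s) treated as zero length", sum(is.na(pr$rhat))))
  pos <- unlist(lapply(.split_chrom(mk), function(sub) {
    if (nrow(sub) < 2L) return(0)
    r <- pr$rhat[pr$chrom == sub$chrom[1L]]
    d <- haldaneDistance(pmin(ifelse(is.na(r), 0, r), .RF_RMAX))
    c(0, cumsum(d))
  }), use.names = FALSE)
  GeneticMap(chrom = mk$chrom, bp = mk$bp, pos = pos, units = "cM", kind = "hgm")
}
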