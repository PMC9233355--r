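# Independent oracles, written against the model definitions only (never
# calling the package internals they are used to check).

# Two-locus F2 joint dosage-class probabilities by enumeration over ordered
# gamete pairs, with symmetric per-locus genotyping error eps.
oracle_f2_class_probs <- function(r, eps = 0) {
  haps <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  pg <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  p9 <- numeric(9)
  for (i in 1:4) for (j in 1:4) {
    d <- haps[[i]] + haps[[j]]
    for (o1 in 0:2) for (o2 in 0:2) {
      e1 <- if (o1 == d[1]) 1 - eps else eps / 2
      e2 <- if (o2 == d[2]) 1 - eps else eps / 2
      idx <- o1 * 3 + o2 + 1
      p9[idx] <- p9[idx] + pg[i] * pg[j] * e1 * e2
    }
  }
  p9
}

# Brute-force maximum-likelihood recombination fraction by grid scan.
oracle_rf_grid <- function(counts9, eps = 1e-4,
                           grid = seq(0.0005, 0.4995, by = 0.0005)) {
  ll <- vapply(grid, function(r) sum(counts9 * log(oracle_f2_class_probs(r, eps))),
               numeric(1))
  grid[which.max(ll)]
}

# Half-normal moments of |AF - 0.5| for a pooled F2 of n individuals
# (AF ~ Binomial(2n, 1/2) / 2n, normal approximation).
oracle_af_absdev <- function(n) {
  sigma <- 0.5 / sqrt(2 * n)
  list(mean = sigma * sqrt(2 / pi), sd = sigma * sqrt(1 - 2 / pi))
}

# Haldane closed forms.
oracle_haldane_rf <- function(d_morgan) (1 - exp(-2 * d_morgan)) / 2
oracle_hw_ril_rf <- function(r) 2 * r / (1 + 2 * r)

# Small deterministic map for cheap tests.
tiny_map <- function(markers = 11, cm = 100, bp = 1e8, chroms = 1) {
  makeSyntheticMap(chroms, markers, bp, cm * chroms, profile = "uniform")
}

# Count-matrix -> GenotypeMatrix on a 2-marker scaffold, for EM tests.
toy_geno <- function(counts9, bp = c(1e6, 2e6)) {
  cls <- rep(seq_len(9) - 1L, counts9)
  g1 <- cls %/% 3L
  g2 <- cls %% 3L
  new("GenotypeMatrix",
      dosage = cbind(as.integer(g1), as.integer(g2)),
      markers = data.frame(chrom = "1", bp = bp, cM = c(0, 1)))
}
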