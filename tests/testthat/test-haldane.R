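test_that("Haldane mapping function and its inverse are exact", {
  expect_equal(haldaneDistance(0), 0)
  expect_equal(haldaneDistance(0.1), -50 * log(0.8), tolerance = 1e-12)
  expect_equal(haldaneDistance(0.1), 11.157, tolerance = 1e-3)
  r <- seq(0, 0.49, by = 0.007)
  expect_equal(haldaneInverse(haldaneDistance(r)), r, tolerance = 1e-12)
  expect_error(haldaneDistance(0.5), "infinite")
  expect_warning(d <- haldaneDistance(0.5, clamp = TRUE), "clamped")
  expect_true(is.finite(d))
  expect_error(haldaneDistance(-0.1))
})

test_that("perfect cosegregation estimates a zero recombination fraction", {
  g <- toy_geno(c(25, 0, 0, 0, 50, 0, 0, 0, 25))
  rf <- estimateRfAdjacent(g)
  expect_lt(markerTable(rf)$rhat, 1e-4)
  expect_equal(markerTable(rf)$n_informative, 100L)
})

test_that("EM equals brute-force likelihood scan on dosage-pair tables", {
  # systematic toy: 100 homozygous individuals, 90 parental / 10 recombinant
  tables <- list(c(45, 0, 5, 0, 0, 0, 5, 0, 45))
  # random tables across the r range, generated from the enumeration oracle
  set.seed(77)
  for (r in c(0.02, 0.08, 0.15, 0.25, 0.35, 0.45)) {
    p <- oracle_f2_class_probs(r)
    for (n in c(20, 50))
      tables <- c(tables, list(as.vector(rmultinom(1, n, p))),
                  list(as.vector(rmultinom(1, n, p))))
  }
  # degenerate corners
  tables <- c(tables, list(c(50, 0, 0, 0, 0, 0, 0, 0, 50)),   # all parental
              list(c(0, 0, 25, 0, 0, 0, 25, 0, 0)),           # all double recombinant
              list(c(0, 0, 0, 0, 50, 0, 0, 0, 0)))            # all double het
  for (tb in tables) {
    rf <- markerTable(estimateRfAdjacent(toy_geno(tb)))$rhat
    oracle <- oracle_rf_grid(tb, eps = 1e-4)
    expect_lt(abs(rf - oracle), 1.5e-3,
              label = sprintf("|EM - grid| for table [%s]", paste(tb, collapse = ",")))
  }
})

test_that("EM recovers a known recombination fraction from simulated F2 data", {
  d_cm <- haldaneDistance(0.1)
  m <- GeneticMap("1", bp = c(1e6, 5e6), pos = c(0, d_cm))
  pop <- simulateF2(m, 2000, seed = 17)
  rhat <- markerTable(estimateRfAdjacent(pop))$rhat
  se <- sqrt(0.1 * 0.9 / (2 * 2000))
  expect_lt(abs(rhat - 0.1), 3 * se)
})

test_that("sparse intervals are skipped and interpolated as zero length", {
  d <- cbind(c(0L, 2L, rep(NA, 18L)), rep(1L, 20L), rep(c(0L, 2L), 10L))
  g <- new("GenotypeMatrix", dosage = d,
           markers = data.frame(chrom = "1", bp = c(10, 20, 30), cM = 0:2))
  expect_warning(rf <- estimateRfAdjacent(g, minInformative = 10), "skipped")
  pt <- markerTable(rf)
  expect_true(is.na(pt$rhat[1]))
  expect_false(is.na(pt$rhat[2]))
  expect_warning(hgm <- buildHGM(rf), "zero length")
  expect_equal(markerTable(hgm)$pos[2], 0)
})

test_that("the Haldane map accumulates per-pair distances per chromosome", {
  rf <- new("RfPairSet",
            pairs = data.frame(chrom = "1", left_bp = c(100, 200), right_bp = c(200, 300),
                               rhat = c(0, 0.1), n_informative = 50L,
                               loglik = NA_real_, stringsAsFactors = FALSE),
            markers = data.frame(chrom = "1", bp = c(100, 200, 300)),
            errorProb = 1e-4)
  hgm <- buildHGM(rf)
  expect_equal(markerTable(hgm)$pos, c(0, 0, -50 * log(0.8)), tolerance = 1e-6)
  rf0 <- rf; rf0@pairs$rhat <- c(0, 0)
  expect_equal(unname(mapLength(buildHGM(rf0))), 0)
})

test_that("Haldane distances are additive over adjacent independent intervals", {
  m <- GeneticMap("1", bp = c(1e6, 4e6, 9e6), pos = c(0, 15, 40))
  pop <- simulateF2(m, 3000, seed = 23)
  rf <- markerTable(estimateRfAdjacent(pop))
  d_ab <- haldaneDistance(rf$rhat[1]); d_bc <- haldaneDistance(rf$rhat[2])
  # direct A-C estimate from the same population
  g_ac <- new("GenotypeMatrix", dosage = dosageMatrix(pop)[, c(1, 3)],
              markers = pop@markers[c(1, 3), ])
  d_ac <- haldaneDistance(markerTable(estimateRfAdjacent(g_ac))$rhat)
  expect_lt(abs(d_ac - (d_ab + d_bc)), 1.5)   # cM, Monte-Carlo slack
})
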