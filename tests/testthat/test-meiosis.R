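test_that("crossover counts follow the Poisson mean of the map length", {
  m <- tiny_map(markers = 11, cm = 100)   # 1 Morgan
  g <- simulateGametes(m, 10000, seed = 11, returnCrossoverCounts = TRUE)
  k <- attr(g, "crossovers")
  expect_equal(mean(k), 1.0, tolerance = 3 * sd(k) / sqrt(length(k)) + 1e-9)
  expect_equal(dim(g), c(10000L, 11L))
  expect_true(all(g %in% 0:1))
})

test_that("gamete recombinant fractions match the Haldane closed form", {
  m <- tiny_map(markers = 11, cm = 100)
  g <- simulateGametes(m, 20000, seed = 42)
  # >= 10 marker pairs at distances 0.1 .. 1.0 Morgan from the first marker
  for (j in 2:11) {
    d <- (j - 1) * 0.1
    expected <- oracle_haldane_rf(d)
    obs <- mean(g[, 1] != g[, j])
    se <- sqrt(expected * (1 - expected) / nrow(g))
    expect_lt(abs(obs - expected), 3 * se + 1e-9)
  }
})

test_that("markers at identical genetic positions always share origin", {
  m <- GeneticMap(chrom = "1", bp = c(1, 100, 200, 300), pos = c(0, 10, 10, 25))
  g <- simulateGametes(m, 2000, seed = 3)
  expect_identical(g[, 2], g[, 3])
  expect_gt(mean(g[, 2] != g[, 4]), 0)   # non-zero distance does recombine
})

test_that("same seed and config reproduce a bit-identical population", {
  m <- tiny_map(markers = 31, cm = 120)
  a <- simulateF2(m, 40, seed = 7)
  b <- simulateF2(m, 40, seed = 7)
  expect_identical(dosageMatrix(a), dosageMatrix(b))
  c <- simulateF2(m, 40, seed = 8)
  expect_false(identical(dosageMatrix(a), dosageMatrix(c)))
})

test_that("F2 dosages are 0/1/2 with per-locus mean near 1", {
  m <- tiny_map(markers = 21, cm = 80)
  pop <- simulateF2(m, 5000, seed = 5)
  d <- dosageMatrix(pop)
  expect_true(all(d %in% 0:2))
  expect_equal(mean(colMeans(d)), 1.0, tolerance = 0.01)
})

test_that("pooled AF deviation from 0.5 shrinks monotonically with n", {
  m <- tiny_map(markers = 300, cm = 150, bp = 3e8)
  dev <- vapply(c(50, 200, 1000), function(n) {
    af <- poolAlleleFreq(simulateF2(m, n, seed = 100 + n))
    mean(abs(markerTable(af)$af - 0.5))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  # n = 50 against the half-normal approximation
  expect_equal(dev[1], oracle_af_absdev(50)$mean, tolerance = 0.2)
})

test_that("RIL with one selfing generation is exactly an F2", {
  m <- tiny_map(markers = 25, cm = 90)
  expect_identical(dosageMatrix(simulateRIL(m, 30, selfingGenerations = 1, seed = 9)),
                   dosageMatrix(simulateF2(m, 30, seed = 9)))
})

test_that("fully inbred RILs are fixed and recombine per Haldane-Waddington", {
  # two markers 20 cM apart
  m <- GeneticMap(chrom = "1", bp = c(1e6, 2e7), pos = c(0, 20))
  pop <- simulateRIL(m, 4000, selfingGenerations = Inf, seed = 13)
  d <- dosageMatrix(pop)
  expect_true(all(d %in% c(0L, 2L)))
  r <- oracle_haldane_rf(0.2)
  R <- oracle_hw_ril_rf(r)
  obs <- mean(d[, 1] != d[, 2])
  se <- sqrt(R * (1 - R) / nrow(d))
  expect_lt(abs(obs - R), 3 * se)
})

test_that("marker subsampling is uniform, ordered and identity at full depth", {
  m <- tiny_map(markers = 50, cm = 100, chroms = 2)
  full <- subsampleMarkers(m, nMarkers(m))
  expect_identical(markerTable(full), markerTable(m))
  s1 <- subsampleMarkers(m, 30, seed = 1)
  s2 <- subsampleMarkers(m, 30, seed = 2)
  expect_equal(nMarkers(s1), 30L)
  mt <- markerTable(s1)
  expect_false(is.unsorted(order(mt$chrom, mt$bp)))
  expect_false(identical(markerTable(s1)$bp, markerTable(s2)$bp))
  expect_true(all(mt$bp %in% markerTable(m)$bp))
  for (ch in chromosomes(s1)) expect_identical(mt$pos[mt$chrom == ch][1], 0)
  expect_error(subsampleMarkers(m, 1e5), "depth")
})

test_that("pooling computes AF over non-missing calls and flags empty loci", {
  gm <- new("GenotypeMatrix",
            dosage = cbind(c(0L, 1L, 2L), c(1L, 1L, 1L), c(0L, NA, 2L), c(NA, NA, NA)),
            markers = data.frame(chrom = "1", bp = c(10, 20, 30, 40), cM = c(0, 1, 2, 3)))
  expect_warning(af <- poolAlleleFreq(gm), "no non-missing")
  lt <- markerTable(af)
  expect_equal(nrow(lt), 3L)                       # all-missing marker excluded
  expect_equal(lt$af, c(0.5, 0.5, 0.5))            # (0+1+2)/6, all-het, (0+2)/4
  expect_equal(lt$missing_frac, c(0, 0, 1 / 3))
  expect_equal(af@filterReport$all_missing, 1L)
})
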