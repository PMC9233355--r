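test_that("per-interval RR is genetic over physical distance", {
  m <- GeneticMap("1", bp = c(1e6, 2e6, 3e6), pos = c(0, 1, 1))
  rr <- pairwiseRR(m)
  expect_equal(rr$rr, c(1, 0))
  expect_equal(rr$mid_bp, c(1.5e6, 2.5e6))
  u <- pairwiseRR(tiny_map(markers = 21, cm = 100))
  expect_equal(max(u$rr) - min(u$rr), 0, tolerance = 1e-9)
})

test_that("windows tile from the chromosome start at half-window slide", {
  m <- GeneticMap("1", bp = round(seq(1, 1e8, length.out = 51)), pos = seq(0, 100, by = 2))
  w <- markerTable(windowRR(m, windowMb = 50, slideFrac = 0.5, minPairs = 1))
  expect_equal(w$start_bp, c(0, 25e6, 50e6))
  expect_equal(w$end_bp - w$start_bp, rep(5e7, 3))
  expect_false(any(w$partial))
  # uniform map: every window at the uniform rate
  expect_equal(w$rr, rep(1, 3), tolerance = 1e-5)
  # trailing partial window appears when the tiling stops short of the end
  m2 <- GeneticMap("1", bp = round(seq(1, 1.1e8, length.out = 51)), pos = seq(0, 100, by = 2))
  w2 <- markerTable(windowRR(m2, windowMb = 50, slideFrac = 0.5, minPairs = 1))
  expect_equal(w2$start_bp, c(0, 25e6, 50e6, 75e6))
  expect_true(w2$partial[4])
})

test_that("window statistic is the median with a contributor minimum", {
  # three intervals with RR 1, 2, 10 inside one window
  m <- GeneticMap("1", bp = c(1e6, 2e6, 3e6, 4e6), pos = cumsum(c(0, 1, 2, 10)))
  w <- markerTable(windowRR(m, windowMb = 50, slideFrac = 1))
  expect_equal(w$rr[1], 2)
  expect_equal(w$n_pairs[1], 3L)
  # a single contributor is below the default minimum
  m1 <- GeneticMap("1", bp = c(1e6, 2e6), pos = c(0, 1))
  expect_true(is.na(markerTable(windowRR(m1, windowMb = 50))$rr[1]))
  expect_equal(markerTable(windowRR(m1, windowMb = 50, minPairs = 1))$rr[1], 1)
})

test_that("non-overlapping mean windows integrate back to the map length", {
  map <- makeSyntheticMap(1, 2000, 6e8, 150, profile = "barley_like")
  w <- markerTable(windowRR(map, windowMb = 50, slideFrac = 1, minPairs = 1,
                            stat = "mean"))
  total <- sum(w$rr * (w$end_bp - w$start_bp) / 1e6)
  expect_equal(total, 150, tolerance = 0.01)
})

test_that("track comparison reports correlations and RMSE on matched windows", {
  mk <- function(rr) new("RRWindowSet",
    windows = data.frame(chrom = "1", start_bp = (seq_along(rr) - 1) * 5e7,
                         end_bp = seq_along(rr) * 5e7, rr = rr,
                         n_pairs = 10L, partial = FALSE),
    windowMb = 50, slideFrac = 1, stat = "median")
  ident <- compareRR(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
  expect_equal(ident$pearson, 1)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$n, 3L)
  expect_equal(compareRR(mk(c(1, 2, 3)), mk(c(9, 5, 2)))$spearman, -1)
  expect_equal(compareRR(mk(c(1, 2, 3)), mk(c(1, 2, 5)))$rmse, sqrt(4 / 3),
               tolerance = 1e-12)
  # scale invariance: why adj_start never changes correlations
  sc <- compareRR(mk(c(1, 2, 3, 5)), mk(3.7 * c(1, 2, 3, 5)))
  expect_equal(sc$pearson, 1)
  expect_equal(sc$spearman, 1)
  expect_error(compareRR(mk(c(1, 2)), mk(c(1, 2))), "3")
  # NA windows are excluded pairwise
  a <- mk(c(1, 2, 3, NA)); b <- mk(c(1, NA, 3, 4))
  expect_error(compareRR(a, b), "3")
})

test_that("windowed RR correlations are invariant to the adjustment factor", {
  map <- tiny_map(markers = 500, cm = 150, bp = 5e8)
  af <- poolAlleleFreq(simulateF2(map, 300, seed = 41))
  k <- computeK(filterMarkers(af))
  w_raw <- windowRR(buildPGM(k), stat = "mean")
  w_adj <- windowRR(buildPGM(applyAdjustment(k, 57.3), useAdjusted = TRUE), stat = "mean")
  res <- compareRR(w_raw, w_adj)
  expect_equal(res$pearson, 1, tolerance = 1e-9)
  expect_equal(res$spearman, 1, tolerance = 1e-9)
})

test_that("parent effects are zero for flat designs and recovered exactly", {
  parents <- LETTERS[1:6]
  cross <- t(combn(parents, 2))
  flat <- data.frame(parent1 = cross[, 1], parent2 = cross[, 2], rr = 2.5)
  eff <- greEstimate(flat)
  expect_equal(eff$effect, rep(0, 6), tolerance = 1e-9)
  expect_equal(attr(eff, "mu"), 2.5, tolerance = 1e-9)

  true_eff <- c(A = 0.30, B = 0.10, C = 0.05, D = -0.05, E = -0.10, F = -0.30)
  dial <- data.frame(parent1 = cross[, 1], parent2 = cross[, 2],
                     rr = 1 + true_eff[cross[, 1]] + true_eff[cross[, 2]])
  est <- greEstimate(dial)
  expect_equal(est$effect[match(parents, est$parent)], unname(true_eff),
               tolerance = 1e-9)
  expect_equal(cor(est$effect[match(parents, est$parent)], unname(true_eff),
                   method = "spearman"), 1)
  expect_identical(est$parent[1], "A")   # ranking by decreasing effect
})

test_that("disconnected crossing designs are rejected", {
  bad <- data.frame(parent1 = c("A", "C"), parent2 = c("B", "D"), rr = c(1, 2))
  expect_error(greEstimate(bad), "disconnected")
  expect_error(greEstimate(data.frame(parent1 = "A", parent2 = "A", rr = 1)),
               "distinct")
})

test_that("window RMSE against truth shrinks with marker density", {
  map <- makeSyntheticMap(1, 3000, 6e8, 150, profile = "barley_like")
  rmse_at <- function(depth) {
    sub <- subsampleMarkers(map, depth, seed = depth)
    af <- poolAlleleFreq(simulateF2(sub, 500, seed = depth + 1))
    k <- computeK(filterMarkers(af))
    adj <- adjStartObserved(unname(mapLength(sub)), unname(mapLength(buildPGM(k))))
    w_est <- windowRR(buildPGM(applyAdjustment(k, adj), useAdjusted = TRUE),
                      stat = "mean", minPairs = 1)
    w_true <- windowRR(sub, stat = "mean", minPairs = 1)
    compareRR(w_true, w_est)$rmse
  }
  expect_gt(rmse_at(300), rmse_at(3000))
})
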