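eval_adj <- function(co, S, G)   # direct formula evaluation, kept inline
  co[1] * exp(co[2] * log2(S)) * exp(co[3] * log2(G)) + co[4] / sqrt(S)

make_grid <- function(co, depths = c(500, 1000, 2000, 5000, 10000),
                      sizes = c(50, 200, 1000, 4000), noise_sd = 0, seed = 1) {
  g <- expand.grid(n_snps = depths, n_genotypes = sizes)
  set.seed(seed)
  g$adj_start <- eval_adj(co, g$n_snps, g$n_genotypes) + rnorm(nrow(g), 0, noise_sd)
  g
}

test_that("observed adj_start is the reference-to-PGM length ratio", {
  expect_equal(adjStartObserved(1000, 10), 100)
  expect_equal(adjStartObserved(123.4, 123.4), 1)
  expect_error(adjStartObserved(1000, 0), "positive")
  expect_error(adjStartObserved(0, 3), "positive")
})

test_that("linear calibration recovers exact coefficients and its AIC convention", {
  g <- expand.grid(n_snps = c(500, 1000, 5000), n_genotypes = c(50, 500, 2000))
  g$adj_start <- 0.01 * g$n_snps + 0.02 * g$n_genotypes
  fit <- fitLinearAdjustment(g)
  expect_equal(unname(coef(fit)["a"]), 0.01, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["b"]), 0.02, tolerance = 1e-8)
  expect_equal(fit@fit$aic, 2 * 3 - 2 * fit@fit$loglik, tolerance = 1e-9)
  # degenerate designs are refused
  bad <- g; bad$n_snps <- 1000
  expect_error(fitLinearAdjustment(bad), "distinct")
  expect_error(fitLinearAdjustment(g[1:2, ]), "rows")
})

test_that("non-linear calibration recovers generating coefficients", {
  truth <- c(8000, -0.54, 0.35, 700)
  g <- make_grid(truth)
  fit <- fitNlsAdjustment(g)
  expect_equal(unname(coef(fit)), truth, tolerance = 1e-4)
  expect_equal(fit@fit$aic, 2 * 5 - 2 * fit@fit$loglik, tolerance = 1e-9)
  expect_true(fit@fit$converged)
  # single depth level cannot identify the depth terms
  bad <- make_grid(truth)[make_grid(truth)$n_snps == 500, ]
  expect_error(fitNlsAdjustment(bad), "distinct")
})

test_that("the shipped model carries the published constants verbatim", {
  m <- defaultAdjustmentModel()
  expect_identical(unname(coef(m)), c(7958.92, -0.5401, 0.3491, 691.0495))
  expect_identical(m@populationType, "F2")
  expect_identical(m@fit$source, "shipped")
})

test_that("prediction equals the closed-form evaluation and respects signs", {
  m <- defaultAdjustmentModel()
  # independent hand evaluation at the published constants
  expect_equal(predictAdjStart(m, 42077, 2000),
               eval_adj(c(7958.92, -0.5401, 0.3491, 691.0495), 42077, 2000),
               tolerance = 1e-12)
  expect_equal(predictAdjStart(m, 42077, 2000), 94.64, tolerance = 0.01)
  # beta < 0: decreasing in depth; gamma > 0: increasing in size
  depths <- c(500, 2000, 10000, 42077)
  expect_true(all(diff(vapply(depths, predictAdjStart, numeric(1),
                              model = m, nGenotypes = 500)) < 0))
  sizes <- c(50, 500, 5000)
  expect_true(all(diff(vapply(sizes, function(G)
    predictAdjStart(m, 10000, G), numeric(1))) > 0))
  expect_error(predictAdjStart(m, 1, 100), "nSnps")
})

test_that("an F2 model refuses RIL samples unless the doubling heuristic is invoked", {
  m <- defaultAdjustmentModel()
  expect_error(predictAdjStart(m, 5000, 100, populationType = "RIL"), "RIL")
  expect_equal(predictAdjStart(m, 5000, 100, populationType = "RIL", rilExpansion = TRUE),
               2 * predictAdjStart(m, 5000, 100))
})

test_that("adjusting by the observed ratio is a fixed point of the map length", {
  map <- tiny_map(markers = 400, cm = 150, bp = 4e8)
  af <- poolAlleleFreq(simulateF2(map, 200, seed = 31))
  k <- computeK(filterMarkers(af))
  raw_len <- unname(mapLength(buildPGM(k)))
  adj <- adjStartObserved(unname(mapLength(map)), raw_len)
  npgm <- buildPGM(applyAdjustment(k, adj), useAdjusted = TRUE)
  expect_equal(unname(mapLength(npgm)), unname(mapLength(map)), tolerance = 1e-9)
})

test_that("json round trip preserves an adjustment model", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- fitNlsAdjustment(make_grid(c(8000, -0.54, 0.35, 700), noise_sd = 1, seed = 3))
  writeModelJson(m, path)
  m2 <- readModelJson(path)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_identical(m2@populationType, m@populationType)
  expect_equal(m2@fit$aic, m@fit$aic, tolerance = 1e-9)
})
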