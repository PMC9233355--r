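# Calibration of raw pool-map length: the observed correction factor
# adj_start = ML_ref / ML_PGM is modelled as a function of genotyping depth
# (number of polymorphic loci) and population size, so pools with unknown
# reference maps can be rescaled from those two quantities alone.

.adj_formula <- adj_start ~ alpha * exp(beta * log2(n_snps)) *
  exp(gamma * log2(n_genotypes)) + theta / sqrt(n_snps)

.check_calibration_table <- function(tbl) {
  .assert(is.data.frame(tbl) &&
          all(c("n_snps", "n_genotypes", "adj_start") %in% colnames(tbl)),
          "calibration table needs columns n_snps, n_genotypes, adj_start")
  .assert(nrow(tbl) >= 3, "calibration needs >= 3 rows")
  .assert(length(unique(tbl$n_snps)) >= 2, "calibration needs >= 2 distinct genotyping depths")
  .assert(length(unique(tbl$n_genotypes)) >= 2, "calibration needs >= 2 distinct population sizes")
  .assert(all(tbl$adj_start > 0), "adj_start values must be positive")
}

#' Observed map-length correction factor
#'
#' adj_start = ML_ref / ML_PGM: the ratio of the reference map length (cM,
#' summed over chromosomes) to the raw pool-map length of the same sample.
#'
#' @param mlRef reference genome map length in cM (> 0).
#' @param mlPgm raw PGM genome length (> 0).
#' @return the scalar correction factor.
#' @export
adjStartObserved <- function(mlRef, mlPgm) {
  .assert(is.finite(mlRef) && mlRef > 0, "mlRef must be positive")
  .assert(is.finite(mlPgm) && mlPgm > 0,
          "mlPgm must be positive (degenerate raw PGM of length 0)")
  mlRef / mlPgm
}

#' Fit the linear calibration baseline
#'
#' No-intercept least squares adj_start = a * nSNPs + b * nGenotypes, kept
#' as the comparison baseline: its AIC/log-likelihood (Gaussian, k = 3 for
#' a, b and sigma) is what the non-linear model is judged against.
#'
#' @param tbl calibration table with columns `n_snps`, `n_genotypes`,
#'   `adj_start` (>= 3 rows, >= 2 distinct depths and sizes).
#' @return A [LinearAdjustmentModel-class].
#' @export
fitLinearAdjustment <- function(tbl) {
  .check_calibration_table(tbl)
  fit <- stats::lm(adj_start ~ 0 + n_snps + n_genotypes, data = tbl)
  co <- stats::coef(fit)
  .assert(all(is.finite(co)), "linear calibration is rank deficient")
  ll <- as.numeric(stats::logLik(fit))
  new("LinearAdjustmentModel", a = unname(co["n_snps"]), b = unname(co["n_genotypes"]),
      fit = list(loglik = ll, aic = stats::AIC(fit), n = nrow(tbl), k = 3L))
}

#' Fit the non-linear calibration model
#'
#' Levenberg-Marquardt least squares of
#' `adj_start = alpha * exp(beta * log2(nSNPs)) * exp(gamma * log2(nGenotypes))
#'  + theta / sqrt(nSNPs)`.
#' Initialisation: alpha = median(adj_start), beta = -0.5, gamma = 0.35,
#' theta = 0 — near the regime the model is designed for, which stabilises
#' this multi-modal surface. Non-converged fits are refused with the
#' best-so-far diagnostics in the error message. Log-likelihood and AIC use
#' the Gaussian maximum-likelihood sigma convention with k = 5.
#'
#' @param tbl calibration table as for [fitLinearAdjustment()].
#' @param init optional named list/vector of starting values
#'   (alpha, beta, gamma, theta).
#' @param maxIter maximum iterations (default 1000).
#' @param tol convergence tolerance on the scaled parameter change
#'   (default 1e-10).
#' @param populationType population type of the calibrated samples.
#' @return An [AdjustmentModel-class].
#' @export
fitNlsAdjustment <- function(tbl, init = NULL, maxIter = 10000, tol = 1e-10,
                             populationType = "F2") {
  .check_calibration_table(tbl)
  if (is.null(init))
    init <- list(alpha = stats::median(tbl$adj_start), beta = -0.5,
                 gamma = 0.35, theta = 0)
  # Levenberg-Marquardt, restarted from the last estimate until either the
  # optimizer reports convergence or the parameter change between restarts
  # falls below tol (the convergence criterion of record)
  start <- as.list(init)
  prev <- unlist(start)
  total <- 0L
  converged <- FALSE
  fit <- NULL
  repeat {
    refit <- tryCatch(withCallingHandlers(
      minpack.lm::nlsLM(.adj_formula, data = tbl, start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = min(maxIter, 1024), ptol = tol, ftol = tol,
                          maxfev = 100000)),
      warning = function(w) {     # iteration-cap notes are handled by the restart loop
        if (grepl("lmdif|lmder", conditionMessage(w))) invokeRestart("muffleWarning")
      }),
      error = function(e) e)
    if (inherits(refit, "error")) {
      if (is.null(fit))
        stop(sprintf("non-linear calibration failed: %s",
                     conditionMessage(refit)), call. = FALSE)
      # a singular gradient on restart means the previous fit is stationary
      converged <- TRUE
      break
    }
    fit <- refit
    total <- total + fit$convInfo$finIter
    co_now <- stats::coef(fit)
    if (isTRUE(fit$convInfo$isConv) ||
        max(abs(co_now - prev) / pmax(abs(prev), 1e-12)) < tol) {
      converged <- TRUE
      break
    }
    if (total >= maxIter) break
    prev <- co_now
    start <- as.list(co_now)
  }
  if (!converged)
    stop(sprintf("non-linear calibration did not converge after %d iterations (best RSS %.6g)",
                 total, sum(stats::resid(fit)^2)), call. = FALSE)
  co <- stats::coef(fit)
  .assert(all(is.finite(co)), "non-linear calibration produced non-finite coefficients")
  pred <- stats::fitted(fit)
  .assert(all(pred > 0), "fitted adjustment is non-positive on the calibration grid")
  ll <- as.numeric(stats::logLik(fit))
  new("AdjustmentModel",
      alpha = unname(co["alpha"]), beta = unname(co["beta"]),
      gamma = unname(co["gamma"]), theta = unname(co["theta"]),
      populationType = populationType,
      fit = list(loglik = ll, aic = stats::AIC(fit), n = nrow(tbl), k = 5L,
                 sigma = sqrt(mean(stats::resid(fit)^2)), converged = TRUE))
}

#' The shipped F2 calibration model
#'
#' Coefficients of the non-linear adjustment calibrated on 1260 simulated F2
#' populations pooled from SNP-array-style genotyping (depths 500 to 42,077
#' loci, sizes 50 to 10,000 individuals):
#' alpha = 7958.92, beta = -0.5401, gamma = 0.3491, theta = 691.0495.
#' Valid for F2 pools only; RIL maps are expanded roughly two-fold and need
#' either a population-type-specific recalibration or the explicit
#' Haldane-Waddington doubling heuristic (see [predictAdjStart()]).
#'
#' @return An [AdjustmentModel-class] with `fit$source = "shipped"`.
#' @export
defaultAdjustmentModel <- function() {
  new("AdjustmentModel", alpha = 7958.92, beta = -0.5401, gamma = 0.3491,
      theta = 691.0495, populationType = "F2",
      fit = list(source = "shipped"))
}

#' Predict the correction factor for a sample
#'
#' Evaluates the non-linear model at the sample's genotyping depth and
#' population size. An F2-calibrated model refuses RIL samples unless
#' `rilExpansion = TRUE`, which applies the documented Haldane-Waddington
#' heuristic of doubling the predicted factor (fully inbred lines accumulate
#' about twice the recombination events of an F2).
#'
#' @param model an [AdjustmentModel-class].
#' @param nSnps genotyping depth: count of polymorphic loci (>= 2).
#' @param nGenotypes pooled population size (>= 1).
#' @param populationType population type of the sample (`"F2"` or `"RIL"`).
#' @param rilExpansion opt-in x2 heuristic for RIL samples under an
#'   F2-calibrated model.
#' @return positive scalar adj_start.
#' @export
predictAdjStart <- function(model, nSnps, nGenotypes, populationType = "F2",
                            rilExpansion = FALSE) {
  stopifnot(is(model, "AdjustmentModel"))
  .assert(nSnps >= 2, "nSnps must be >= 2")
  .assert(nGenotypes >= 1, "nGenotypes must be >= 1")
  .assert(populationType %in% c("F2", "RIL"), "populationType must be 'F2' or 'RIL'")
  factor <- 1
  if (populationType != model@populationType) {
    if (populationType == "RIL" && model@populationType == "F2") {
      if (!rilExpansion)
        stop(paste("model was calibrated on F2 populations; refusing a RIL sample.",
                   "Recalibrate for RIL or opt in to the x2 Haldane-Waddington",
                   "heuristic with rilExpansion = TRUE"), call. = FALSE)
      factor <- 2
    } else {
      stop(sprintf("model population type '%s' does not match sample type '%s'",
                   model@populationType, populationType), call. = FALSE)
    }
  }
  adj <- model@alpha * exp(model@beta * log2(nSnps)) *
    exp(model@gamma * log2(nGenotypes)) + model@theta / sqrt(nSnps)
  adj <- factor * adj
  .assert(is.finite(adj) && adj > 0,
          "predicted adjustment is non-positive: sample outside the calibrated domain")
  adj
}

#' Rescale K factors by a correction factor
#'
#' K' = K * adj_start for every adjacent pair; the nPGM built from K' has
#' genome length adj_start times the raw length. Pure rescaling: windowed
#' recombination-rate correlations are unaffected by the choice of
#' adj_start.
#'
#' @param pairs a raw [KPairSet-class].
#' @param adjStart positive correction factor.
#' @return An adjusted [KPairSet-class] (K holds K', in cM).
#' @export
applyAdjustment <- function(pairs, adjStart) {
  stopifnot(is(pairs, "KPairSet"))
  .assert(is.finite(adjStart) && adjStart > 0, "adjStart must be positive")
  if (pairs@adjusted) stop("K pairs are already adjusted", call. = FALSE)
  pr <- pairs@pairs
  pr$K <- pr$K * adjStart
  new("KPairSet", pairs = pr, markers = pairs@markers,
      adjusted = TRUE, adjStart = adjStart)
}

#' Simulate a calibration grid of pooled F2 samples
#'
#' For every combination of genotyping depth and population size (times
#' `reps` replicates with derived seeds), simulates an F2 population from
#' the reference map, subsamples markers, pools allele frequencies, builds
#' the raw PGM and records the observed correction factor
#' adj_start = ML_ref / ML_PGM. A fresh marker subset is drawn per replicate
#' except at full depth.
#'
#' @param map the reference [GeneticMap-class] ("true" map).
#' @param depths vector of genotyping depths (each <= nMarkers(map)).
#' @param sizes vector of population sizes.
#' @param reps replicates per grid point.
#' @param seed top-level seed; per-sample seeds are derived from it.
#' @param keepSamples also return, per sample, the marker-level table
#'   (chrom, bp, true cM, raw PGM position) needed for per-marker
#'   position-ratio assessments.
#' @return list with `table` (one row per sample: `n_snps`, `n_genotypes`,
#'   `rep`, `ml_pgm`, `adj_start`) and, if requested, `samples` (list of
#'   marker tables) and `mlRef`.
#' @export
simulateCalibrationGrid <- function(map, depths, sizes, reps = 5, seed = NULL,
                                    keepSamples = FALSE) {
  stopifnot(is(map, "GeneticMap"))
  mlRef <- mapLength(map)
  grid <- expand.grid(rep = seq_len(reps), n_genotypes = sizes, n_snps = depths)
  rows <- vector("list", nrow(grid))
  samples <- if (keepSamples) vector("list", nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    d <- grid$n_snps[i]; n <- grid$n_genotypes[i]
    s <- .derive_seed(seed, i)
    sub <- subsampleMarkers(map, d, seed = s)
    pop <- simulateF2(sub, n, seed = .derive_seed(seed, i + nrow(grid)))
    af <- poolAlleleFreq(pop)
    k <- computeK(af)
    pgm <- buildPGM(k)
    ml <- mapLength(pgm)
    rows[[i]] <- data.frame(n_snps = d, n_genotypes = n, rep = grid$rep[i],
                            ml_pgm = ml, adj_start = adjStartObserved(mlRef, ml))
    if (keepSamples) {
      mt <- markerTable(pgm)
      samples[[i]] <- data.frame(chrom = mt$chrom, bp = mt$bp,
                                 true_cM = markerTable(sub)$pos,
                                 pgm_pos = mt$pos,
                                 n_snps = d, n_genotypes = n,
                                 stringsAsFactors = FALSE)
    }
  }
  out <- list(table = do.call(rbind, rows), mlRef = mlRef)
  if (keepSamples) out$samples <- samples
  out
}

#' Calibrate the adjustment model on a simulation grid
#'
#' Convenience wrapper: [simulateCalibrationGrid()] followed by
#' [fitNlsAdjustment()] and [fitLinearAdjustment()] on the observed
#' correction factors. The non-linear fit is the model of record; the
#' linear fit is returned for the AIC/log-likelihood comparison.
#'
#' @inheritParams simulateCalibrationGrid
#' @return list with `model` ([AdjustmentModel-class]), `linear`
#'   ([LinearAdjustmentModel-class]), `table`, `mlRef` and (if
#'   `keepSamples`) `samples`.
#' @export
calibrateAdjustment <- function(map, depths, sizes, reps = 5, seed = NULL,
                                keepSamples = FALSE) {
  grid <- simulateCalibrationGrid(map, depths, sizes, reps, seed, keepSamples)
  model <- fitNlsAdjustment(grid$table)
  linear <- fitLinearAdjustment(grid$table)
  c(list(model = model, linear = linear), grid)
}
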