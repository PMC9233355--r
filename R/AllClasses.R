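#' @import methods
NULL

.required_cols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    return(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  NULL
}

.check_marker_order <- function(df, poscol = NULL) {
  msgs <- character(0)
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (any(is.na(sub$bp)))
      msgs <- c(msgs, sprintf("chromosome %s has missing bp positions", ch))
    else {
      if (is.unsorted(sub$bp, strictly = TRUE))
        msgs <- c(msgs, sprintf("chromosome %s: bp not strictly increasing", ch))
      if (!is.null(poscol)) {
        p <- sub[[poscol]]
        if (any(is.na(p)) || is.unsorted(p))
          msgs <- c(msgs, sprintf("chromosome %s: %s not non-decreasing", ch, poscol))
        else if (length(p) && abs(p[1L]) > 1e-9)
          msgs <- c(msgs, sprintf("chromosome %s: first %s must be 0", ch, poscol))
      }
    }
  }
  msgs
}

#' GeneticMap: ordered markers with physical and genetic coordinates
#'
#' A per-chromosome ordered table of markers carrying a physical position
#' (1-based bp) and a cumulative genetic position. The `kind` slot records
#' how the map was obtained: `"true"` (reference/consensus role, cM),
#' `"pgm"` (raw pool genetic map, unit-free K), `"npgm"` (adjusted pool
#' genetic map, cM) or `"hgm"` (two-point Haldane map, cM).
#'
#' @slot markers data.frame with columns `chrom`, `bp`, `pos`.
#' @slot units `"cM"` or `"K"` (raw, uncalibrated pool-map units).
#' @slot kind one of `"true"`, `"pgm"`, `"npgm"`, `"hgm"`.
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(markers = "data.frame", units = "character", kind = "character"),
  prototype(markers = data.frame(chrom = character(), bp = numeric(), pos = numeric()),
            units = "cM", kind = "true"))

setValidity("GeneticMap", function(object) {
  df <- object@markers
  msg <- .required_cols(df, c("chrom", "bp", "pos"), "GeneticMap@markers")
  if (!is.null(msg)) return(msg)
  if (!object@units %in% c("cM", "K")) return("units must be 'cM' or 'K'")
  if (!object@kind %in% c("true", "pgm", "npgm", "hgm"))
    return("kind must be one of 'true', 'pgm', 'npgm', 'hgm'")
  if (any(!is.finite(df$pos)) || any(df$pos < 0))
    return("genetic positions must be finite and non-negative")
  msgs <- .check_marker_order(df, "pos")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GeneticMap
#'
#' Rows are sorted canonically by (chrom, bp); validity (strictly increasing
#' bp, non-decreasing genetic position starting at 0 per chromosome) is
#' enforced.
#'
#' @param chrom chromosome identifiers.
#' @param bp 1-based physical positions (bp).
#' @param pos cumulative genetic positions (cM, or raw K units for PGMs).
#' @param units,kind see [GeneticMap-class].
#' @return A [GeneticMap-class] object.
#' @export
GeneticMap <- function(chrom, bp, pos, units = "cM", kind = "true") {
  df <- data.frame(chrom = as.character(chrom), bp = as.numeric(bp),
                   pos = as.numeric(pos), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  new("GeneticMap", markers = df, units = units, kind = kind)
}

#' AFTrack: pooled allele frequencies at physical positions
#'
#' The sole genetic input of the pool-map estimator: one consistently
#' polarized allele frequency per polymorphic locus. Polarization must be
#' consistent along the genome (simulations: the parent-2 allele; VCF input:
#' the ALT allele); folding to minor-allele frequency would corrupt the
#' frequency differences the estimator relies on.
#'
#' @slot loci data.frame with columns `chrom`, `bp`, `af` and `missing_frac`.
#' @slot filterReport named list of per-reason removal counts (filled by
#'   [filterMarkers()]).
#' @exportClass AFTrack
setClass("AFTrack",
  representation(loci = "data.frame", filterReport = "list"),
  prototype(loci = data.frame(chrom = character(), bp = numeric(),
                              af = numeric(), missing_frac = numeric()),
            filterReport = list()))

setValidity("AFTrack", function(object) {
  df <- object@loci
  msg <- .required_cols(df, c("chrom", "bp", "af", "missing_frac"), "AFTrack@loci")
  if (!is.null(msg)) return(msg)
  ok <- is.finite(df$af)
  if (any(!ok)) return("allele frequencies must be finite")
  if (any(df$af < 0 | df$af > 1)) return("allele frequencies must lie in [0, 1]")
  if (any(df$missing_frac < 0 | df$missing_frac > 1))
    return("missing_frac must lie in [0, 1]")
  TRUE
})

#' Construct an AFTrack
#'
#' @param chrom,bp,af,missing_frac per-locus columns; rows are sorted by
#'   (chrom, bp). Duplicated positions are allowed here and handled by
#'   [filterMarkers()].
#' @return An [AFTrack-class] object.
#' @export
AFTrack <- function(chrom, bp, af, missing_frac = 0) {
  df <- data.frame(chrom = as.character(chrom), bp = as.numeric(bp),
                   af = as.numeric(af),
                   missing_frac = rep_len(as.numeric(missing_frac), length(af)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  new("AFTrack", loci = df)
}

#' GenotypeMatrix: individuals x markers dosages
#'
#' Dosage of the parent-2 allele in {0, 1, 2} (NA = missing call), columns
#' in physical marker order, with the marker coordinates of the underlying
#' map subset attached.
#'
#' @slot dosage integer matrix, individuals in rows, markers in columns.
#' @slot markers data.frame with columns `chrom`, `bp`, `cM` matching the
#'   columns of `dosage`.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosage = "matrix", markers = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- .required_cols(object@markers, c("chrom", "bp", "cM"), "GenotypeMatrix@markers")
  if (!is.null(msg)) return(msg)
  if (ncol(object@dosage) != nrow(object@markers))
    return("dosage columns must match marker rows")
  v <- object@dosage
  if (!all(v[!is.na(v)] %in% c(0L, 1L, 2L)))
    return("dosages must be 0, 1, 2 or NA")
  msgs <- .check_marker_order(object@markers)
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' KPairSet: adjacent-pair K factors
#'
#' For every physically adjacent marker pair on a chromosome,
#' K = |dAF| / log10(dDist); raw K values are unit-free and become cM-scaled
#' K' after multiplication with the adjustment factor.
#'
#' @slot pairs data.frame with columns `chrom`, `left_bp`, `right_bp`,
#'   `delta_af`, `dist_bp`, `K` (pairs dropped by the minimum-distance guard
#'   are kept with `K = 0` and flagged in `dropped`).
#' @slot markers data.frame (`chrom`, `bp`, `af`) of all contributing
#'   markers, including single-marker chromosomes that yield no pair.
#' @slot adjusted logical: has the adjustment factor been applied.
#' @slot adjStart the applied adjustment factor (NA while raw).
#' @exportClass KPairSet
setClass("KPairSet",
  representation(pairs = "data.frame", markers = "data.frame",
                 adjusted = "logical", adjStart = "numeric"),
  prototype(adjusted = FALSE, adjStart = NA_real_))

setValidity("KPairSet", function(object) {
  msg <- .required_cols(object@pairs,
                        c("chrom", "left_bp", "right_bp", "delta_af", "dist_bp", "K", "dropped"),
                        "KPairSet@pairs")
  if (!is.null(msg)) return(msg)
  if (any(object@pairs$K < 0, na.rm = TRUE)) return("K values must be non-negative")
  TRUE
})

#' ReadCountTrack: pooled-sequencing allele counts per locus
#'
#' @slot counts data.frame with columns `chrom`, `bp`, `depth`, `alt`.
#' @exportClass ReadCountTrack
setClass("ReadCountTrack", representation(counts = "data.frame"))

setValidity("ReadCountTrack", function(object) {
  msg <- .required_cols(object@counts, c("chrom", "bp", "depth", "alt"), "ReadCountTrack@counts")
  if (!is.null(msg)) return(msg)
  df <- object@counts
  if (any(df$alt < 0 | df$alt > df$depth)) return("alt counts must lie in [0, depth]")
  TRUE
})

#' AdjustmentModel: non-linear map-length calibration
#'
#' The correction factor `adj_start` that rescales a raw pool genetic map to
#' centiMorgans is modelled as
#' `alpha * exp(beta * log2(nSNPs)) * exp(gamma * log2(nGenotypes)) +
#'  theta / sqrt(nSNPs)`.
#'
#' @slot alpha,beta,gamma,theta model coefficients.
#' @slot populationType population type the calibration was fitted on
#'   (`"F2"` or `"RIL"`).
#' @slot fit list of fit diagnostics (`loglik`, `aic`, `n`, `converged`,
#'   `sigma`; `source = "shipped"` for the packaged default).
#' @exportClass AdjustmentModel
setClass("AdjustmentModel",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 theta = "numeric", populationType = "character", fit = "list"))

setValidity("AdjustmentModel", function(object) {
  co <- c(object@alpha, object@beta, object@gamma, object@theta)
  if (length(co) != 4L || any(!is.finite(co))) return("coefficients must be four finite numbers")
  if (!object@populationType %in% c("F2", "RIL")) return("populationType must be 'F2' or 'RIL'")
  TRUE
})

#' LinearAdjustmentModel: no-intercept linear calibration baseline
#'
#' `adj_start = a * nSNPs + b * nGenotypes`, retained only as the model
#' comparison baseline (AIC / log-likelihood) for the non-linear model.
#'
#' @slot a,b coefficients.
#' @slot fit list of diagnostics (`loglik`, `aic`, `n`).
#' @exportClass LinearAdjustmentModel
setClass("LinearAdjustmentModel",
  representation(a = "numeric", b = "numeric", fit = "list"))

#' RfPairSet: adjacent-pair recombination fractions
#'
#' Two-point maximum-likelihood recombination fractions between physically
#' adjacent markers of an F2 intercross, estimated by EM over the nine
#' dosage-pair classes with a symmetric genotyping-error probability.
#'
#' @slot pairs data.frame with columns `chrom`, `left_bp`, `right_bp`,
#'   `rhat`, `n_informative`, `loglik` (`rhat` NA when an interval was
#'   skipped for lack of jointly non-missing individuals).
#' @slot markers data.frame (`chrom`, `bp`) of the underlying markers.
#' @slot errorProb genotyping-error probability used in the emissions.
#' @exportClass RfPairSet
setClass("RfPairSet",
  representation(pairs = "data.frame", markers = "data.frame", errorProb = "numeric"))

#' RRWindowSet: sliding-window recombination rates
#'
#' @slot windows data.frame with columns `chrom`, `start_bp` (0-based window
#'   start; windows are half-open, BED-compatible), `end_bp`, `rr`
#'   (cM/Mb, NA when fewer than `minPairs` intervals contribute), `n_pairs`,
#'   `partial` (terminal window shorter than the configured size).
#' @slot windowMb,slideFrac,stat the windowing configuration.
#' @exportClass RRWindowSet
setClass("RRWindowSet",
  representation(windows = "data.frame", windowMb = "numeric",
                 slideFrac = "numeric", stat = "character"))

setValidity("RRWindowSet", function(object) {
  msg <- .required_cols(object@windows,
                        c("chrom", "start_bp", "end_bp", "rr", "n_pairs"),
                        "RRWindowSet@windows")
  if (!is.null(msg)) return(msg)
  if (any(object@windows$rr < 0, na.rm = TRUE)) return("rr must be non-negative or NA")
  TRUE
})
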