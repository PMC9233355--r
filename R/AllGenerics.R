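#' Marker table of a map-like object
#'
#' @param x a [GeneticMap-class], [AFTrack-class], [GenotypeMatrix-class],
#'   [KPairSet-class], [ReadCountTrack-class], [RfPairSet-class] or
#'   [RRWindowSet-class] object.
#' @return data.frame of the object's per-marker / per-pair / per-window rows.
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname markerTable
#' @export
setMethod("markerTable", "GeneticMap", function(x) x@markers)
#' @rdname markerTable
#' @export
setMethod("markerTable", "AFTrack", function(x) x@loci)
#' @rdname markerTable
#' @export
setMethod("markerTable", "GenotypeMatrix", function(x) x@markers)
#' @rdname markerTable
#' @export
setMethod("markerTable", "KPairSet", function(x) x@pairs)
#' @rdname markerTable
#' @export
setMethod("markerTable", "ReadCountTrack", function(x) x@counts)
#' @rdname markerTable
#' @export
setMethod("markerTable", "RfPairSet", function(x) x@pairs)
#' @rdname markerTable
#' @export
setMethod("markerTable", "RRWindowSet", function(x) x@windows)

#' Number of markers (loci) in an object
#' @param x a map-like object.
#' @return integer count.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname nMarkers
#' @export
setMethod("nMarkers", "GeneticMap", function(x) nrow(x@markers))
#' @rdname nMarkers
#' @export
setMethod("nMarkers", "AFTrack", function(x) nrow(x@loci))
#' @rdname nMarkers
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@dosage))

#' Chromosome identifiers of an object
#' @param x a map-like object.
#' @return character vector of chromosome ids in canonical order.
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname chromosomes
#' @export
setMethod("chromosomes", "GeneticMap", function(x) unique(x@markers$chrom))
#' @rdname chromosomes
#' @export
setMethod("chromosomes", "AFTrack", function(x) unique(x@loci$chrom))

#' Genetic map length
#'
#' Per-chromosome map length is the genetic position of the last marker of
#' the chromosome (chromosome origins are 0); the genome length is their sum.
#'
#' @param x a [GeneticMap-class].
#' @param by `"genome"` (scalar sum) or `"chromosome"` (named vector).
#' @return numeric map length(s), in the object's `units`.
#' @export
setGeneric("mapLength", function(x, by = c("genome", "chromosome")) standardGeneric("mapLength"))

#' @rdname mapLength
#' @export
setMethod("mapLength", "GeneticMap", function(x, by = c("genome", "chromosome")) {
  by <- match.arg(by)
  per <- vapply(split(x@markers$pos, x@markers$chrom), function(p) max(p) - min(p), numeric(1))
  per <- per[unique(x@markers$chrom)]
  if (by == "genome") sum(per) else per
})

#' Dosage matrix of a GenotypeMatrix
#' @param x a [GenotypeMatrix-class].
#' @return integer matrix (individuals x markers).
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))
#' @rdname dosageMatrix
#' @export
setMethod("dosageMatrix", "GenotypeMatrix", function(x) x@dosage)

#' Coefficients of calibration models
#' @param object an [AdjustmentModel-class] or [LinearAdjustmentModel-class].
#' @param ... unused.
#' @return named numeric vector of coefficients.
#' @export
setMethod("coef", "AdjustmentModel", function(object, ...)
  c(alpha = object@alpha, beta = object@beta, gamma = object@gamma, theta = object@theta))
#' @rdname coef-AdjustmentModel-method
#' @export
setMethod("coef", "LinearAdjustmentModel", function(object, ...)
  c(a = object@a, b = object@b))

setMethod("show", "GeneticMap", function(object) {
  per <- mapLength(object, "chromosome")
  cat(sprintf("GeneticMap [%s] | %d markers on %d chromosome(s) | length %.4g %s\n",
              object@kind, nrow(object@markers), length(per), sum(per), object@units))
})

setMethod("show", "AFTrack", function(object) {
  cat(sprintf("AFTrack | %d loci on %d chromosome(s)\n",
              nrow(object@loci), length(unique(object@loci$chrom))))
  if (length(object@filterReport)) {
    fr <- object@filterReport
    cat("  filters:", paste(sprintf("%s=%d", names(fr), unlist(fr)), collapse = ", "), "\n")
  }
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix | %d individuals x %d markers | %.2f%% missing\n",
              nrow(object@dosage), ncol(object@dosage),
              100 * mean(is.na(object@dosage))))
})

setMethod("show", "KPairSet", function(object) {
  cat(sprintf("KPairSet | %d adjacent pairs (%d dropped by distance guard) | %s\n",
              nrow(object@pairs), sum(object@pairs$dropped),
              if (object@adjusted) sprintf("adjusted (adj_start = %.4g)", object@adjStart)
              else "raw"))
})

setMethod("show", "AdjustmentModel", function(object) {
  cat(sprintf(paste0("AdjustmentModel (%s): adj_start = %.6g * exp(%.6g * log2(S))",
                     " * exp(%.6g * log2(G)) + %.6g / sqrt(S)\n"),
              object@populationType, object@alpha, object@beta, object@gamma, object@theta))
  if (!is.null(object@fit$aic))
    cat(sprintf("  fit: logLik = %.4g, AIC = %.4g, n = %d\n",
                object@fit$loglik, object@fit$aic, object@fit$n))
  if (identical(object@fit$source, "shipped"))
    cat("  shipped coefficients (F2, SNP-array-pool calibration)\n")
})

setMethod("show", "RRWindowSet", function(object) {
  w <- object@windows
  cat(sprintf("RRWindowSet | %d windows (%d with RR) | %g Mb, slide %g, %s\n",
              nrow(w), sum(!is.na(w$rr)), object@windowMb, object@slideFrac, object@stat))
})

setMethod("show", "ReadCountTrack", function(object) {
  cat(sprintf("ReadCountTrack | %d loci | mean depth %.1f\n",
              nrow(object@counts), mean(object@counts$depth)))
})

setMethod("show", "RfPairSet", function(object) {
  p <- object@pairs
  cat(sprintf("RfPairSet | %d adjacent pairs (%d estimated) | error prob %g\n",
              nrow(p), sum(!is.na(p$rhat)), object@errorProb))
})
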