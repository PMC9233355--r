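#' Per-interval recombination rates of a genetic map
#'
#' For every adjacent marker interval, RR = d(cM) / d(Mb): the genetic
#' distance divided by the physical distance in megabases. The interval is
#' anchored at its bp midpoint for window assignment.
#'
#' @param map a [GeneticMap-class] in cM (a raw PGM in K units is accepted;
#'   the resulting "rates" are then relative, which leaves downstream
#'   correlations unchanged).
#' @return data.frame with columns `chrom`, `left_bp`, `right_bp`, `mid_bp`,
#'   `d_cm`, `d_mb`, `rr`.
#' @export
pairwiseRR <- function(map) {
  stopifnot(is(map, "GeneticMap"))
  df <- map@markers
  .assert(any(table(df$chrom) >= 2), "need >= 2 markers on at least one chromosome")
  out <- do.call(rbind, lapply(.split_chrom(df), function(sub) {
    m <- nrow(sub)
    if (m < 2L) return(NULL)
    data.frame(chrom = sub$chrom[-m], left_bp = sub$bp[-m], right_bp = sub$bp[-1L],
               mid_bp = (sub$bp[-m] + sub$bp[-1L]) / 2,
               d_cm = diff(sub$pos), d_mb = diff(sub$bp) / 1e6,
               stringsAsFactors = FALSE)
  }))
  out$rr <- out$d_cm / out$d_mb
  rownames(out) <- NULL
  out
}

#' Sliding-window recombination rates
#'
#' Windows of `windowMb` megabases tile each chromosome from its start with
#' a step of `slideFrac * windowMb`. An interval contributes to every window
#' containing its anchor (bp midpoint by default); the window RR is the
#' median (or mean) of its contributors, and windows with fewer than
#' `minPairs` contributors report NA. Reported `start_bp` is the 0-based
#' window start, so windows are half-open and BED-compatible; terminal
#' windows extending past the chromosome end are retained and flagged
#' `partial`.
#'
#' @param intervals per-interval table from [pairwiseRR()], or a
#'   [GeneticMap-class] (converted internally).
#' @param windowMb window size in Mb (default 50).
#' @param slideFrac slide as a fraction of the window size (default 0.5).
#' @param minPairs minimum contributing intervals per window (default 2).
#' @param stat `"median"` (default) or `"mean"`.
#' @param chromLengths optional named vector of chromosome lengths in bp;
#'   inferred from the last marker otherwise.
#' @param anchor `"midpoint"` (default) assigns an interval by its bp
#'   midpoint; `"left"` by its left marker.
#' @return An [RRWindowSet-class].
#' @export
windowRR <- function(intervals, windowMb = 50, slideFrac = 0.5, minPairs = 2,
                     stat = c("median", "mean"), chromLengths = NULL,
                     anchor = c("midpoint", "left")) {
  if (is(intervals, "GeneticMap")) intervals <- pairwiseRR(intervals)
  stat <- match.arg(stat)
  anchor <- match.arg(anchor)
  .assert(windowMb > 0, "windowMb must be positive")
  .assert(slideFrac > 0 && slideFrac <= 1, "slideFrac must lie in (0, 1]")
  wbp <- windowMb * 1e6
  step <- slideFrac * wbp
  agg <- match.fun(stat)

  res <- lapply(.split_chrom(intervals), function(sub) {
    ch <- sub$chrom[1L]
    len <- if (!is.null(chromLengths) && ch %in% names(chromLengths))
      chromLengths[[ch]] else max(sub$right_bp)
    # complete windows, plus one trailing partial window if the complete
    # tiling stops short of the chromosome end
    last_complete <- floor(max(0, len - wbp) / step) * step
    starts <- seq(0, last_complete, by = step)
    if (last_complete + wbp < len) starts <- c(starts, last_complete + step)
    a <- if (anchor == "midpoint") sub$mid_bp else sub$left_bp
    rows <- lapply(starts, function(s) {
      inwin <- a > s & a <= s + wbp
      n <- sum(inwin)
      data.frame(chrom = ch, start_bp = s, end_bp = s + wbp,
                 rr = if (n >= minPairs) agg(sub$rr[inwin]) else NA_real_,
                 n_pairs = n, partial = s + wbp > len,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  w <- do.call(rbind, res)
  rownames(w) <- NULL
  new("RRWindowSet", windows = w, windowMb = windowMb,
      slideFrac = slideFrac, stat = stat)
}

#' Compare two windowed recombination-rate tracks
#'
#' Matches windows by (chrom, start), drops pairs where either side is NA,
#' and reports sample Pearson and Spearman correlations, the root mean
#' square difference, and the number of matched windows.
#'
#' @param a,b [RRWindowSet-class] objects on the same windowing grid.
#' @return list with `pearson`, `spearman`, `rmse`, `n`.
#' @export
compareRR <- function(a, b) {
  stopifnot(is(a, "RRWindowSet"), is(b, "RRWindowSet"))
  m <- merge(a@windows[, c("chrom", "start_bp", "rr")],
             b@windows[, c("chrom", "start_bp", "rr")],
             by = c("chrom", "start_bp"), suffixes = c("_a", "_b"))
  m <- m[!is.na(m$rr_a) & !is.na(m$rr_b), , drop = FALSE]
  .assert(nrow(m) >= 3, "fewer than 3 matched windows with RR on both sides")
  list(pearson = stats::cor(m$rr_a, m$rr_b, method = "pearson"),
       spearman = stats::cor(m$rr_a, m$rr_b, method = "spearman"),
       rmse = sqrt(mean((m$rr_a - m$rr_b)^2)),
       n = nrow(m))
}
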