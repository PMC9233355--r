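# Per-parent general recombination effect (GRE) across a crossing design.
# Deliberately a plain fixed-effects least-squares model, NOT the G-BLUP
# used for the published barley GRE values: each population's genome-wide
# recombination rate is modelled as an overall mean plus the additive
# effects of its two parents, with a sum-to-zero constraint on the effects.

.design_connected <- function(p1, p2) {
  parents <- unique(c(p1, p2))
  seen <- parents[1L]
  repeat {
    grow <- unique(c(p2[p1 %in% seen], p1[p2 %in% seen]))
    grow <- setdiff(grow, seen)
    if (!length(grow)) break
    seen <- c(seen, grow)
  }
  length(seen) == length(parents)
}

#' General recombination effect of parental lines
#'
#' Fits `rr = mu + effect(parent1) + effect(parent2)` by least squares over
#' a set of biparental populations, with the parent effects constrained to
#' sum to zero (solved via the KKT system of the constrained normal
#' equations). A positive effect marks a parent whose crosses show elevated
#' genome-wide recombination. This is a main-effects stand-in for the
#' published G-BLUP definition of the GRE and is labelled as such in the
#' output.
#'
#' @param populations data.frame with columns `parent1`, `parent2`, `rr`
#'   (genome-wide RR or map length per population); parents must be
#'   distinct within a population and the crossing design connected.
#' @return data.frame (`parent`, `effect`, `rank`), ranked by decreasing
#'   effect; attributes `mu` (overall mean) and `model`
#'   (`"main-effects-LS"`).
#' @export
greEstimate <- function(populations) {
  .assert(is.data.frame(populations) &&
          all(c("parent1", "parent2", "rr") %in% colnames(populations)),
          "populations needs columns parent1, parent2, rr")
  p1 <- as.character(populations$parent1)
  p2 <- as.character(populations$parent2)
  y <- populations$rr
  .assert(all(p1 != p2), "each population must link two distinct parents")
  .assert(all(is.finite(y)), "rr values must be finite")
  .assert(.design_connected(p1, p2), "crossing design is disconnected")

  parents <- sort(unique(c(p1, p2)))
  np <- length(parents)
  Z <- matrix(0, length(y), np, dimnames = list(NULL, parents))
  Z[cbind(seq_along(y), match(p1, parents))] <- 1
  Z[cbind(seq_along(y), match(p2, parents))] <- 1
  X <- cbind(mu = 1, Z)

  # constrained LS: minimise ||y - X b|| subject to sum of effects = 0
  C <- matrix(c(0, rep(1, np)), nrow = 1)
  kkt <- rbind(cbind(crossprod(X), t(C)), cbind(C, 0))
  sol <- solve(kkt, c(crossprod(X, y), 0))
  b <- sol[seq_len(np + 1L)]

  out <- data.frame(parent = parents, effect = unname(b[-1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$effect), , drop = FALSE]
  out$rank <- seq_len(np)
  rownames(out) <- NULL
  attr(out, "mu") <- unname(b[1L])
  attr(out, "model") <- "main-effects-LS"
  out
}
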