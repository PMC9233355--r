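# internal helpers: argument checks and seed handling

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# one top-level seed; per-replicate streams derived deterministically and
# kept below 2^31
.derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 1000003 * as.double(index)) %% 2147483647)
}

.set_seed <- function(seed) {
  if (!is.null(seed)) {
    .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "seed must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

.split_chrom <- function(df) split(df, factor(df$chrom, levels = unique(df$chrom)))
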