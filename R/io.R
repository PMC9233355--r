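# Plain-text interchange: tab-separated tracks with mandatory headers and
# '#' comment lines recording tool version, command and seed. Numeric
# columns are written at 6 significant digits.

.tool_meta <- function(command = NULL, seed = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("recombPool")),
                  error = function(e) "dev")
  meta <- sprintf("recombPool %s", ver)
  if (!is.null(command)) meta <- c(meta, sprintf("command: %s", command))
  if (!is.null(seed)) meta <- c(meta, sprintf("seed: %s", seed))
  meta
}

.write_tsv <- function(df, path, meta = character(), col.names = TRUE) {
  # coordinates and counts stay exact integers; fractional columns at 6
  # significant digits, never in scientific notation
  fmt <- function(x) {
    if (!is.numeric(x)) return(x)
    whole <- all(is.na(x) | x == round(x))
    if (!whole) x <- signif(x, 6)
    format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }
  df[] <- lapply(df, fmt)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
  invisible(path)
}

.read_tsv <- function(path, expected) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(expected, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing or invalid header (expected column(s): %s)",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  df
}

.check_no_dup_pos <- function(df, path) {
  key <- paste(df$chrom, df$pos_bp)
  d <- which(duplicated(key))
  if (length(d))
    stop(sprintf("%s: duplicated (chrom, pos_bp) row, first offender: %s at %s (row %d)",
                 path, df$chrom[d[1L]], format(df$pos_bp[d[1L]], scientific = FALSE),
                 d[1L]), call. = FALSE)
}

#' Read / write genetic map TSV
#'
#' Format: tab-separated with header `chrom  pos_bp  cM` (cM-scaled maps) or
#' `chrom  pos_bp  map_pos` (raw pool maps in K units); 1-based bp; `#`
#' comment lines allowed. Reading rejects files without a header, duplicated
#' (chrom, pos_bp) rows (first offender reported), and non-monotone genetic
#' positions (offending chromosome named).
#'
#' @param path file path.
#' @param kind map kind to stamp on the result (see [GeneticMap-class]).
#' @return [readMapTsv()]: a [GeneticMap-class].
#' @export
readMapTsv <- function(path, kind = "true") {
  df <- utils::read.delim(path, comment.char = "#", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  .assert("chrom" %in% colnames(df) && "pos_bp" %in% colnames(df),
          "%s: missing or invalid header (expected chrom, pos_bp, cM|map_pos)", path)
  poscol <- intersect(c("cM", "map_pos", "map_pos_cM"), colnames(df))
  .assert(length(poscol) >= 1, "%s: no genetic position column (cM or map_pos)", path)
  poscol <- poscol[1L]
  .check_no_dup_pos(df, path)
  for (ch in unique(df$chrom)) {
    p <- df[[poscol]][df$chrom == ch][order(df$pos_bp[df$chrom == ch])]
    if (is.unsorted(p))
      stop(sprintf("%s: genetic positions non-monotone on chromosome %s", path, ch),
           call. = FALSE)
  }
  pos <- df[[poscol]]
  units <- if (poscol == "map_pos") "K" else "cM"
  # re-origin defensively: stored maps may carry a global, not per-chromosome, origin
  gm <- data.frame(chrom = as.character(df$chrom), bp = df$pos_bp, pos = pos)
  gm <- gm[order(gm$chrom, gm$bp), , drop = FALSE]
  for (ch in unique(gm$chrom)) {
    i <- gm$chrom == ch
    gm$pos[i] <- gm$pos[i] - gm$pos[i][1L]
  }
  GeneticMap(gm$chrom, gm$bp, gm$pos, units = units, kind = kind)
}

#' @rdname readMapTsv
#' @param map a [GeneticMap-class] to write.
#' @param command,seed optional provenance recorded as `#` comments.
#' @export
writeMapTsv <- function(map, path, command = NULL, seed = NULL) {
  stopifnot(is(map, "GeneticMap"))
  df <- map@markers
  out <- data.frame(chrom = df$chrom, pos_bp = df$bp, pos = df$pos)
  colnames(out)[3L] <- if (map@units == "cM") "cM" else "map_pos"
  .write_tsv(out, path, .tool_meta(command, seed))
}

#' Read / write allele-frequency TSV
#'
#' Format: `chrom  pos_bp  af  [missing_frac]`, tab-separated with header.
#' Duplicated positions are tolerated on read (they are the business of
#' [filterMarkers()]); allele frequencies must lie in [0, 1].
#'
#' @param path file path.
#' @return [readAfTsv()]: an [AFTrack-class].
#' @export
readAfTsv <- function(path) {
  df <- .read_tsv(path, c("chrom", "pos_bp", "af"))
  .assert(all(is.finite(df$af)) && all(df$af >= 0 & df$af <= 1),
          "%s: allele frequencies must lie in [0, 1]", path)
  AFTrack(chrom = df$chrom, bp = df$pos_bp, af = df$af,
          missing_frac = if ("missing_frac" %in% colnames(df)) df$missing_frac else 0)
}

#' @rdname readAfTsv
#' @param af an [AFTrack-class] to write.
#' @param command,seed optional provenance recorded as `#` comments.
#' @export
writeAfTsv <- function(af, path, command = NULL, seed = NULL) {
  stopifnot(is(af, "AFTrack"))
  df <- af@loci
  .write_tsv(data.frame(chrom = df$chrom, pos_bp = df$bp, af = df$af,
                        missing_frac = df$missing_frac),
             path, .tool_meta(command, seed))
}

#' Read / write read-count TSV
#'
#' Format: `chrom  pos_bp  depth  alt_count`.
#'
#' @param path file path.
#' @return [readReadCountsTsv()]: a [ReadCountTrack-class].
#' @export
readReadCountsTsv <- function(path) {
  df <- .read_tsv(path, c("chrom", "pos_bp", "depth", "alt_count"))
  new("ReadCountTrack",
      counts = data.frame(chrom = as.character(df$chrom), bp = df$pos_bp,
                          depth = df$depth, alt = df$alt_count,
                          stringsAsFactors = FALSE))
}

#' @rdname readReadCountsTsv
#' @param rc a [ReadCountTrack-class] to write.
#' @param command,seed optional provenance comments.
#' @export
writeReadCountsTsv <- function(rc, path, command = NULL, seed = NULL) {
  stopifnot(is(rc, "ReadCountTrack"))
  df <- rc@counts
  .write_tsv(data.frame(chrom = df$chrom, pos_bp = df$bp, depth = df$depth,
                        alt_count = df$alt),
             path, .tool_meta(command, seed))
}

#' Read / write windowed recombination rates
#'
#' Format: `chrom  start_bp  end_bp  rr_cM_per_MB  n_pairs`, with `start_bp`
#' the 0-based half-open window start; `bed = TRUE` writes the same rows
#' headerless as BED3+2.
#'
#' @param path file path.
#' @return [readWindowsTsv()]: an [RRWindowSet-class].
#' @export
readWindowsTsv <- function(path) {
  df <- .read_tsv(path, c("chrom", "start_bp", "end_bp", "rr_cM_per_MB", "n_pairs"))
  w <- data.frame(chrom = as.character(df$chrom), start_bp = df$start_bp,
                  end_bp = df$end_bp, rr = df$rr_cM_per_MB, n_pairs = df$n_pairs,
                  partial = FALSE, stringsAsFactors = FALSE)
  wmb <- (w$end_bp[1L] - w$start_bp[1L]) / 1e6
  starts <- sort(unique(w$start_bp))
  slide <- if (length(starts) > 1L) (starts[2L] - starts[1L]) / (wmb * 1e6) else 1
  new("RRWindowSet", windows = w, windowMb = wmb, slideFrac = slide, stat = "median")
}

#' @rdname readWindowsTsv
#' @param w an [RRWindowSet-class] to write.
#' @param bed write headerless BED-style output.
#' @param command,seed optional provenance comments.
#' @export
writeWindowsTsv <- function(w, path, bed = FALSE, command = NULL, seed = NULL) {
  stopifnot(is(w, "RRWindowSet"))
  df <- w@windows
  out <- data.frame(chrom = df$chrom, start_bp = df$start_bp, end_bp = df$end_bp,
                    rr_cM_per_MB = df$rr, n_pairs = df$n_pairs)
  .write_tsv(out, path,
             meta = if (bed) character() else .tool_meta(command, seed),
             col.names = !bed)
}

#' Write / read an adjustment model as JSON
#'
#' JSON object `{alpha, beta, gamma, theta, population_type, fit: {...}}`,
#' the interchange format between `calibrate` and `estimate`.
#'
#' @param model an [AdjustmentModel-class].
#' @param path file path.
#' @export
writeModelJson <- function(model, path) {
  stopifnot(is(model, "AdjustmentModel"))
  obj <- list(alpha = model@alpha, beta = model@beta, gamma = model@gamma,
              theta = model@theta, population_type = model@populationType,
              fit = model@fit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeModelJson
#' @return [readModelJson()]: an [AdjustmentModel-class].
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  .assert(all(c("alpha", "beta", "gamma", "theta") %in% names(obj)),
          "%s: not an adjustment model JSON", path)
  new("AdjustmentModel", alpha = as.numeric(obj$alpha), beta = as.numeric(obj$beta),
      gamma = as.numeric(obj$gamma), theta = as.numeric(obj$theta),
      populationType = if (!is.null(obj$population_type)) obj$population_type else "F2",
      fit = if (!is.null(obj$fit)) as.list(obj$fit) else list())
}

#' Pooled allele frequencies from a VCF
#'
#' Reads biallelic SNP records and derives the pooled ALT-allele frequency
#' from per-sample allele depths (FORMAT/AD summed over all samples), or,
#' where AD is absent, from the INFO/AF field. Multiallelic and indel
#' records are skipped and counted, as are records below the total-depth
#' minimum. Positions are 1-based as in the VCF; the file must be
#' coordinate-sorted.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param minDepth minimum summed allele depth per record (default 1;
#'   ignored for AF-only records without DP).
#' @param allelePolicy `"alt"` (default): frequency of the ALT allele.
#'   `"ref"`: frequency of the REF allele. Polarization must be consistent
#'   genome-wide; see [AFTrack-class].
#' @return An [AFTrack-class]; `filterReport` counts skipped records.
#' @export
readAfFromVcf <- function(path, minDepth = 1, allelePolicy = c("alt", "ref")) {
  allelePolicy <- match.arg(allelePolicy)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx)))      # single-record files come back as a bare vector
    fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  .assert(nrow(fix) > 0, "%s: no records", path)
  pos <- as.numeric(fix$POS)
  for (ch in unique(fix$CHROM))
    if (is.unsorted(pos[fix$CHROM == ch]))
      stop(sprintf("%s: unsorted VCF (chromosome %s)", path, ch), call. = FALSE)

  snp <- !grepl(",", fix$ALT, fixed = TRUE) & nchar(fix$REF) == 1L &
    nchar(fix$ALT) == 1L & fix$ALT %in% c("A", "C", "G", "T")
  report <- list(multiallelic_or_indel = sum(!snp))

  af <- rep(NA_real_, nrow(fix))
  depth <- rep(NA_real_, nrow(fix))
  af_done <- FALSE
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  if (!is.null(ad) && !all(is.na(ad))) {
    ref_d <- vcfR::masplit(ad, record = 1L, sort = FALSE)
    alt_d <- vcfR::masplit(ad, record = 2L, sort = FALSE)
    ref_s <- rowSums(ref_d, na.rm = TRUE)
    alt_s <- rowSums(alt_d, na.rm = TRUE)
    depth <- ref_s + alt_s
    af <- ifelse(depth > 0, alt_s / depth, NA_real_)
    af_done <- TRUE
  }
  if (!af_done) {
    info_af <- suppressWarnings(vcfR::extract.info(v, element = "AF", as.numeric = TRUE))
    info_dp <- suppressWarnings(vcfR::extract.info(v, element = "DP", as.numeric = TRUE))
    if (all(is.na(info_af))) {
      first_bad <- which(snp)[1L]
      stop(sprintf("%s: neither FORMAT/AD nor INFO/AF available (record %s:%s)",
                   path, fix$CHROM[first_bad], fix$POS[first_bad]), call. = FALSE)
    }
    af <- info_af
    depth <- if (!all(is.na(info_dp))) info_dp else rep(Inf, nrow(fix))
  }

  deep <- !is.na(depth) & depth >= minDepth
  report$low_depth <- sum(snp & !deep)
  keep <- snp & deep & !is.na(af)
  .assert(any(keep), "%s: no biallelic SNP records pass the filters", path)
  if (allelePolicy == "ref") af <- 1 - af
  out <- AFTrack(chrom = fix$CHROM[keep], bp = pos[keep], af = af[keep])
  out@filterReport <- report
  out
}
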