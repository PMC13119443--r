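# ---------------------------------------------------------------------------
# Variant-call qualification thresholds
# ---------------------------------------------------------------------------

#' Call-qualification thresholds
#'
#' The panel-wide gate applied to every candidate variant call before it
#' reaches the diplotype engine: the VCF site quality must exceed
#' `min_quality` and the read depth must exceed `min_depth`. Both
#' comparisons are strict, so a call at quality exactly 42 or depth
#' exactly 30 fails.
#'
#' @param min_quality Site quality threshold (exclusive), default 42.
#' @param min_depth Read-depth threshold (exclusive), default 30.
#' @return An object of class `qual_thresholds`.
#' @export
qual_thresholds <- function(min_quality = 42, min_depth = 30) {
  stopifnot(min_quality > 0, min_depth > 0)
  structure(list(min_quality = min_quality, min_depth = min_depth),
            class = "qual_thresholds")
}

empty_calls <- function() {
  data.frame(key = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), zygosity = character(),
             quality = numeric(), depth = integer(),
             filter_flagged = logical(), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# VCF reading
# ---------------------------------------------------------------------------

#' Read variant calls from a single-sample VCF
#'
#' Parses a VCF 4.2 file into a flat table of candidate variant calls.
#' Multi-allelic records are split into one call per alternate allele;
#' zygosity is derived from the diploid genotype (`0/1` or `1/0` -> het,
#' `1/1` -> hom; haploid/hemizygous single-index genotypes map to hom so
#' X-linked genes still fit the diploid profile matcher). Records with
#' reference or missing genotype emit no call. Site quality comes from
#' QUAL; depth from FORMAT/DP, with INFO/DP as fallback. Records whose
#' FILTER is neither PASS nor "." are parsed but flagged; qualification
#' does not look at FILTER. Records lacking a usable GT are collected as
#' record-level errors (attribute `"errors"`), not fatal.
#'
#' @param path Path to a single-sample VCF (plain or bgzipped).
#' @param region_filter Optional `panel_config`; calls outside all panel
#'   regions are dropped.
#' @return A data.frame of calls (columns `key`, `chrom`, `pos`, `ref`,
#'   `alt`, `zygosity`, `quality`, `depth`, `filter_flagged`) with
#'   attribute `errors` (character vector of per-record problems).
#' @export
read_vcf_calls <- function(path, region_filter = NULL) {
  if (!file.exists(path)) {
    stop("VCF not found: ", path, call. = FALSE)
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  n_rec <- nrow(fix)
  if (n_rec == 0L) {
    out <- empty_calls()
    attr(out, "errors") <- character(0)
    return(out)
  }
  if (is.null(gt) || ncol(gt) < 2L) {
    stop("VCF has no genotype columns; a single-sample VCF is required",
         call. = FALSE)
  }
  if (ncol(gt) > 2L) {
    stop(sprintf("multi-sample VCF (%d samples); one sample per file",
                 ncol(gt) - 1L), call. = FALSE)
  }
  errors <- character(0)
  rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    chrom <- fix[i, "CHROM"]
    pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    alt_field <- fix[i, "ALT"]
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    filt <- fix[i, "FILTER"]
    flagged <- !(is.na(filt) || filt %in% c("PASS", "."))
    fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1]]
    vals <- strsplit(gt[i, 2L], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx) || gt_idx > length(vals)) {
      errors <- c(errors, sprintf("%s:%d missing GT field", chrom, pos))
      next
    }
    gt_str <- vals[gt_idx]
    alleles <- strsplit(gt_str, "[/|]")[[1]]
    if (any(alleles == ".") || !all(grepl("^[0-9]+$", alleles))) {
      next  # no-call genotype: no call emitted
    }
    alleles <- as.integer(alleles)
    if (length(alleles) > 2L) {
      errors <- c(errors, sprintf("%s:%d non-diploid GT '%s'", chrom, pos,
                                  gt_str))
      next
    }
    depth <- NA_integer_
    dp_idx <- match("DP", fmt)
    if (!is.na(dp_idx) && dp_idx <= length(vals)) {
      depth <- suppressWarnings(as.integer(vals[dp_idx]))
    }
    if (is.na(depth)) {
      info_dp <- sub("^.*?DP=([0-9]+).*$", "\\1", paste0(";", fix[i, "INFO"]))
      depth <- suppressWarnings(as.integer(info_dp))
    }
    if (is.na(depth)) depth <- 0L
    alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      n_copies <- sum(alleles == ai)
      if (n_copies == 0L) next
      zyg <- if (length(alleles) == 1L) "hom"
             else if (n_copies == 2L) "hom" else "het"
      key <- tryCatch(variant_key(chrom, pos, ref, alts[ai]),
                      error = function(e) NA_character_)
      if (is.na(key)) {
        errors <- c(errors, sprintf("%s:%d unparseable alleles %s>%s",
                                    chrom, pos, ref, alts[ai]))
        next
      }
      parsed <- parse_variant_key(key)
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, chrom = parsed$chrom, pos = parsed$pos, ref = parsed$ref,
        alt = parsed$alt, zygosity = zyg,
        quality = if (is.na(qual)) 0 else qual, depth = depth,
        filter_flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty_calls()
  if (!is.null(region_filter)) {
    stopifnot(inherits(region_filter, "panel_config"))
    keep <- vapply(seq_len(nrow(out)), function(i) {
      any(region_filter$chrom == out$chrom[i] &
            region_filter$start <= out$pos[i] &
            region_filter$end >= out$pos[i])
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

# ---------------------------------------------------------------------------
# Qualification
# ---------------------------------------------------------------------------

#' Qualify variant calls against quality/coverage thresholds
#'
#' Partitions the parsed calls into passing calls and rejected calls.
#' A call passes iff `quality > min_quality` **and** `depth > min_depth`;
#' rejected calls carry the reason (`quality`, `depth` or `both`).
#'
#' @param calls Data.frame from [read_vcf_calls()].
#' @param thresholds A [qual_thresholds()].
#' @param sample Sample identifier carried into the result.
#' @return An object of class `qualified_callset`: list with elements
#'   `sample`, `calls` (passing) and `rejected` (with `reason` column).
#' @export
qualify <- function(calls, thresholds = qual_thresholds(),
                    sample = "sample") {
  stopifnot(inherits(thresholds, "qual_thresholds"))
  if (nrow(calls) == 0L) {
    rej <- empty_calls()
    rej$reason <- character(0)
    return(structure(list(sample = sample, calls = empty_calls(),
                          rejected = rej), class = "qualified_callset"))
  }
  q_ok <- calls$quality > thresholds$min_quality
  d_ok <- calls$depth > thresholds$min_depth
  pass <- q_ok & d_ok
  rejected <- calls[!pass, , drop = FALSE]
  reason <- ifelse(!q_ok[!pass] & !d_ok[!pass], "both",
                   ifelse(!q_ok[!pass], "quality", "depth"))
  rejected$reason <- reason
  passing <- calls[pass, , drop = FALSE]
  rownames(passing) <- NULL
  rownames(rejected) <- NULL
  attr(passing, "errors") <- NULL
  structure(list(sample = sample, calls = passing, rejected = rejected),
            class = "qualified_callset")
}

#' @export
print.qualified_callset <- function(x, ...) {
  cat(sprintf("<qualified_callset> sample=%s: %d passing, %d rejected\n",
              x$sample, nrow(x$calls), nrow(x$rejected)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Coverage tables
# ---------------------------------------------------------------------------

#' Read a per-base coverage table
#'
#' COV-TSV dialect: header `sample  chrom  pos  depth`, 1-based
#' positions, one row per covered base. Duplicate positions and negative
#' depths are rejected.
#'
#' @param path Path to a COV-TSV file.
#' @return An object of class `coverage_profile`: data.frame with
#'   columns `chrom`, `pos`, `depth` and attribute `sample`.
#' @export
read_coverage <- function(path) {
  rows <- read_tsv_strict(path, c("sample", "chrom", "pos", "depth"))
  pos <- parse_int_col(rows$pos, path, rows$.line, "pos")
  depth <- parse_int_col(rows$depth, path, rows$.line, "depth")
  if (any(depth < 0L)) {
    i <- which(depth < 0L)[1L]
    stop(sprintf("%s line %d: negative depth", path, rows$.line[i]),
         call. = FALSE)
  }
  key <- paste(rows$chrom, pos)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("%s: duplicate position %s", path, dup), call. = FALSE)
  }
  sample <- if (nrow(rows)) rows$sample[1L] else "sample"
  out <- data.frame(chrom = rows$chrom, pos = pos, depth = depth,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  coverage_profile(out, sample)
}

#' Construct a coverage profile from a depth table
#'
#' @param depths Data.frame with columns `chrom`, `pos`, `depth`.
#' @param sample Sample identifier.
#' @return A `coverage_profile`.
#' @export
coverage_profile <- function(depths, sample = "sample") {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depths)),
            all(depths$depth >= 0))
  out <- depths[, c("chrom", "pos", "depth")]
  attr(out, "sample") <- sample
  class(out) <- c("coverage_profile", "data.frame")
  out
}

#' Write a coverage profile in COV-TSV dialect
#'
#' @param cov A `coverage_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(cov, path) {
  stopifnot(inherits(cov, "coverage_profile"))
  sample <- attr(cov, "sample")
  lines <- c("sample\tchrom\tpos\tdepth",
             paste(sample, cov$chrom, cov$pos, cov$depth, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
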