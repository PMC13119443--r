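# ---------------------------------------------------------------------------
# Variant keys
# ---------------------------------------------------------------------------

#' Build normalized variant keys
#'
#' A variant key is the canonical string `chrom:pos:ref:alt` identifying one
#' sequence change. Alleles are upper-cased and reduced to their minimal
#' representation: shared trailing bases are trimmed first, then shared
#' leading bases (advancing `pos`), always retaining at least one base on
#' each side so that indels keep their single-base anchor. Keys built from
#' different spellings of the same change therefore compare equal, which is
#' what allele-definition matching relies on.
#'
#' @param chrom Chromosome name (character).
#' @param pos 1-based position (integer-like, >= 1).
#' @param ref Reference bases, non-empty `ACGT` string.
#' @param alt Alternate bases, non-empty `ACGT` string; must differ from
#'   `ref` after normalization.
#' @return Character vector of `chrom:pos:ref:alt` keys.
#' @examples
#' variant_key("chr10", 96541616, "G", "A")
#' variant_key("chr1", 100, "TGGG", "TGG")   # right-trimmed to chr1:100:TG:T
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant position must be a positive integer", call. = FALSE)
  }
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt))) {
    stop("ref and alt must be non-empty ACGT strings", call. = FALSE)
  }
  out <- character(n)
  for (i in seq_len(n)) {
    v <- normalize_alleles(pos[i], ref[i], alt[i])
    if (v$ref == v$alt) {
      stop(sprintf("ref and alt are identical after normalization at %s:%d",
                   chrom[i], pos[i]), call. = FALSE)
    }
    out[i] <- paste(chrom[i], v$pos, v$ref, v$alt, sep = ":")
  }
  out
}

# Minimal representation: trim shared suffix, then shared prefix, keeping a
# 1-base anchor on both alleles.
normalize_alleles <- function(pos, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Split a variant key back into its fields
#'
#' @param key Character vector of `chrom:pos:ref:alt` keys.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed variant key: ", paste(key[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
    ref = vapply(parts, `[[`, character(1), 3L),
    alt = vapply(parts, `[[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Panel configuration
# ---------------------------------------------------------------------------

PANEL_CATEGORIES <- c("priority", "secondary", "candidate")
PANEL_STRATEGIES <- c("full", "haplotype", "hotspot")

#' Load a panel gene catalog
#'
#' Reads the tab-separated panel configuration (header
#' `gene  category  chrom  start  end  strategy`, 1-based inclusive
#' coordinates). Each row describes one targeted gene: its evidence
#' category (`priority`, `secondary` or `candidate`) and its capture
#' strategy (`full` coding region, direct `haplotype` capture, or
#' `hotspot` positions only).
#'
#' @param path Path to a PANEL-TSV file.
#' @return A data.frame of class `panel_config` with one row per gene.
#' @seealso [panel_config_path()] for the packaged catalog.
#' @export
load_panel_config <- function(path) {
  rows <- read_tsv_strict(path, c("gene", "category", "chrom", "start",
                                  "end", "strategy"))
  if (nrow(rows) == 0L) {
    return(empty_panel())
  }
  rows$start <- parse_int_col(rows$start, path, rows$.line, "start")
  rows$end <- parse_int_col(rows$end, path, rows$.line, "end")
  bad <- !(rows$category %in% PANEL_CATEGORIES)
  if (any(bad)) {
    stop(sprintf("%s line %d: unknown category '%s'", path,
                 rows$.line[bad][1L], rows$category[bad][1L]), call. = FALSE)
  }
  bad <- !(rows$strategy %in% PANEL_STRATEGIES)
  if (any(bad)) {
    stop(sprintf("%s line %d: unknown strategy '%s'", path,
                 rows$.line[bad][1L], rows$strategy[bad][1L]), call. = FALSE)
  }
  if (any(rows$start > rows$end)) {
    i <- which(rows$start > rows$end)[1L]
    stop(sprintf("%s line %d: start > end for gene %s", path, rows$.line[i],
                 rows$gene[i]), call. = FALSE)
  }
  if (anyDuplicated(rows$gene)) {
    dup <- rows$gene[duplicated(rows$gene)][1L]
    stop(sprintf("duplicate gene symbol in panel config: %s", dup),
         call. = FALSE)
  }
  rows$.line <- NULL
  class(rows) <- c("panel_config", "data.frame")
  rows
}

empty_panel <- function() {
  out <- data.frame(gene = character(), category = character(),
                    chrom = character(), start = integer(), end = integer(),
                    strategy = character(), stringsAsFactors = FALSE)
  class(out) <- c("panel_config", "data.frame")
  out
}

#' Path to the packaged panel catalog
#'
#' The shipped catalog transcribes the panel's published priority and
#' secondary gene lists (21 and 10 genes respectively) with approximate
#' GRCh37 gene spans; candidate genes are region placeholders without
#' allele definitions.
#'
#' @return File path inside the installed package.
#' @export
panel_config_path <- function() {
  system.file("extdata", "panel.tsv", package = "pgxpanel", mustWork = TRUE)
}

# ---------------------------------------------------------------------------
# Allele-definition database
# ---------------------------------------------------------------------------

#' Load a star-allele definition database
#'
#' Reads an allele--variant translation table (header
#' `gene  allele  defining_variants`; `defining_variants` is a ";"-joined
#' list of `chrom:pos:ref:alt` tokens, or the literal "." for the
#' reference allele). Every gene must carry exactly one allele with an
#' empty defining set, named `*1`: the reference haplotype.
#'
#' @param path Path to an ALLELE-TSV file.
#' @return An object of class `allele_db`: a data.frame with columns
#'   `gene`, `allele` and list-column `defining` (character vectors of
#'   normalized variant keys).
#' @seealso [definition_positions()], [write_allele_db()],
#'   [allele_db_path()].
#' @export
load_allele_db <- function(path) {
  rows <- read_tsv_strict(path, c("gene", "allele", "defining_variants"))
  defining <- lapply(seq_len(nrow(rows)), function(i) {
    parse_defining(rows$defining_variants[i], path, rows$.line[i])
  })
  db <- data.frame(gene = rows$gene, allele = rows$allele,
                   stringsAsFactors = FALSE)
  db$defining <- defining
  key <- paste(db$gene, db$allele, sep = "\t")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (gene, allele) row: ", gsub("\t", " ", dup),
         call. = FALSE)
  }
  for (g in unique(db$gene)) {
    sub <- db[db$gene == g, ]
    empties <- sub$allele[vapply(sub$defining, length, integer(1)) == 0L]
    if (!identical(empties, "*1")) {
      stop(sprintf(paste0("gene %s must have exactly one empty-definition ",
                          "allele and it must be named *1"), g),
           call. = FALSE)
    }
  }
  class(db) <- c("allele_db", "data.frame")
  db
}

parse_defining <- function(x, path, line) {
  x <- trimws(x)
  if (identical(x, ".")) {
    return(character(0))
  }
  tokens <- strsplit(x, ";", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop(sprintf("%s line %d: empty defining_variants field (use '.')",
                 path, line), call. = FALSE)
  }
  parts <- parse_variant_key(tokens)
  sort(unique(variant_key(parts$chrom, parts$pos, parts$ref, parts$alt)))
}

#' Write an allele database in ALLELE-TSV dialect
#'
#' Inverse of [load_allele_db()]; rows are written in (gene, allele)
#' order so the round trip is reproducible.
#'
#' @param db An `allele_db`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_allele_db <- function(db, path) {
  stopifnot(inherits(db, "allele_db"))
  ord <- order(db$gene, db$allele)
  defs <- vapply(db$defining[ord], function(v) {
    if (length(v) == 0L) "." else paste(sort(v), collapse = ";")
  }, character(1))
  lines <- c("gene\tallele\tdefining_variants",
             paste(db$gene[ord], db$allele[ord], defs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Defining-variant positions of a gene
#'
#' The union of all variant keys appearing in any star-allele definition
#' of `gene`. These are the positions at which the diplotype engine reads
#' the sample's zygosity profile; passing calls elsewhere in the gene are
#' routed to the rare-variant path instead.
#'
#' @param db An `allele_db`.
#' @param gene Gene symbol.
#' @return Sorted character vector of variant keys (possibly empty).
#' @export
definition_positions <- function(db, gene) {
  stopifnot(inherits(db, "allele_db"))
  sort(unique(unlist(db$defining[db$gene == gene], use.names = FALSE)))
}

#' Alleles defined for one gene
#'
#' @param db An `allele_db`.
#' @param gene Gene symbol.
#' @return Named list allele name -> character vector of defining keys.
#' @export
gene_alleles <- function(db, gene) {
  stopifnot(inherits(db, "allele_db"))
  sub <- db[db$gene == gene, ]
  stats::setNames(sub$defining, sub$allele)
}

#' Path to the packaged toy allele-definition database
#'
#' A small transcribed subset of consensus star-allele definitions for a
#' handful of core pharmacogenes, sufficient to exercise every analysis
#' path. It is a synthetic teaching subset, not a release of any
#' nomenclature database.
#'
#' @return File path inside the installed package.
#' @export
allele_db_path <- function() {
  system.file("extdata", "allele_db.tsv", package = "pgxpanel",
              mustWork = TRUE)
}

#' Cross-validate an allele database against a panel catalog
#'
#' Report-only consistency check: lists defining variants lying outside
#' their gene's panel region and alleles whose gene is absent from the
#' panel. An empty report means the pair is consistent.
#'
#' @param db An `allele_db`.
#' @param panel A `panel_config`.
#' @return A data.frame with columns `gene`, `allele`, `finding`,
#'   `detail`; zero rows when valid.
#' @export
validate_db <- function(db, panel) {
  stopifnot(inherits(db, "allele_db"), inherits(panel, "panel_config"))
  findings <- list()
  for (i in seq_len(nrow(db))) {
    g <- db$gene[i]
    row <- panel[panel$gene == g, ]
    if (nrow(row) == 0L) {
      if (length(db$defining[[i]]) == 0L) next
      findings[[length(findings) + 1L]] <- data.frame(
        gene = g, allele = db$allele[i], finding = "gene_not_in_panel",
        detail = "", stringsAsFactors = FALSE)
      next
    }
    for (v in db$defining[[i]]) {
      p <- parse_variant_key(v)
      inside <- p$chrom == row$chrom && p$pos >= row$start &&
        p$pos <= row$end
      if (!inside) {
        findings[[length(findings) + 1L]] <- data.frame(
          gene = g, allele = db$allele[i],
          finding = "variant_outside_region", detail = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(gene = character(), allele = character(),
                      finding = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

# ---------------------------------------------------------------------------
# shared TSV plumbing
# ---------------------------------------------------------------------------

# Strict TSV reader: exact header, no quoting, keeps source line numbers in
# a ".line" column for error messages.
read_tsv_strict <- function(path, columns) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop(path, ": empty file (header required)", call. = FALSE)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (!identical(header, columns)) {
    stop(sprintf("%s: expected header '%s', found '%s'", path,
                 paste(columns, collapse = "\t"), lines[1L]), call. = FALSE)
  }
  body <- lines[-1L]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  line_no <- (seq_along(lines)[-1L])[keep]
  if (length(body) == 0L) {
    out <- as.data.frame(stats::setNames(
      replicate(length(columns), character(0), simplify = FALSE), columns),
      stringsAsFactors = FALSE)
    out$.line <- integer(0)
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf != length(columns))) {
    i <- which(nf != length(columns))[1L]
    stop(sprintf("%s line %d: expected %d tab-separated fields, found %d",
                 path, line_no[i], length(columns), nf[i]), call. = FALSE)
  }
  out <- as.data.frame(stats::setNames(lapply(seq_along(columns), function(j) {
    vapply(fields, `[[`, character(1), j)
  }), columns), stringsAsFactors = FALSE)
  out$.line <- line_no
  out
}

parse_int_col <- function(x, path, line_no, name) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) {
    i <- which(is.na(v))[1L]
    stop(sprintf("%s line %d: field '%s' is not an integer: '%s'", path,
                 line_no[i], name, x[i]), call. = FALSE)
  }
  v
}
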