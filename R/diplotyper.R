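# ---------------------------------------------------------------------------
# Deterministic star-allele diplotyping.
#
# The engine compares the sample's observed zygosity profile, restricted to
# the gene's definition positions, against the expected profile of every
# unordered allele pair (including self-pairs). A pair is a candidate only
# on a perfect match: same variant keys, same zygosities, nothing left
# unexplained. No probabilistic scoring, no frequency tie-breaking.
# ---------------------------------------------------------------------------

#' Expected zygosity profile of an allele pair
#'
#' For two star alleles of the same gene with defining sets `D_a` and
#' `D_b`, the expected profile over `D_a` union `D_b` is `hom` where both
#' alleles carry the variant and `het` where only one does.
#'
#' @param def_a,def_b Character vectors of defining variant keys (as
#'   stored in an `allele_db`); the empty vector is the reference allele.
#' @return Named character vector (sorted by key) with values `"het"` /
#'   `"hom"`; empty for the reference self-pair.
#' @export
expected_profile <- function(def_a, def_b) {
  u <- sort(union(def_a, def_b))
  if (length(u) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  both <- u %in% def_a & u %in% def_b
  stats::setNames(ifelse(both, "hom", "het"), u)
}

#' Observed zygosity profile of a sample at one gene
#'
#' Splits the passing calls falling inside the gene region into the
#' profile at definition positions (consumed by the matcher) and the
#' off-definition remainder (surfaced for rare-variant review; it never
#' vetoes the diplotype).
#'
#' @param gene_row One row of a `panel_config` (the gene's region).
#' @param qcs A `qualified_callset`.
#' @param db An `allele_db`.
#' @return List with `profile` (named zygosity vector keyed by variant
#'   key) and `off_definition` (data.frame of passing in-region calls at
#'   non-definition positions).
#' @export
observed_profile <- function(gene_row, qcs, db) {
  stopifnot(inherits(qcs, "qualified_callset"), inherits(db, "allele_db"))
  calls <- qcs$calls
  in_region <- calls$chrom == gene_row$chrom & calls$pos >= gene_row$start &
    calls$pos <= gene_row$end
  calls <- calls[in_region, , drop = FALSE]
  defs <- definition_positions(db, gene_row$gene)
  on_def <- calls$key %in% defs
  prof_calls <- calls[on_def, , drop = FALSE]
  prof_calls <- prof_calls[order(prof_calls$key), , drop = FALSE]
  profile <- stats::setNames(prof_calls$zygosity, prof_calls$key)
  off <- calls[!on_def, , drop = FALSE]
  rownames(off) <- NULL
  list(profile = profile, off_definition = off)
}

profiles_equal <- function(a, b) {
  identical(sort(names(a)), sort(names(b))) &&
    identical(unname(a[sort(names(a))]), unname(b[sort(names(b))]))
}

#' Call the star-allele diplotype of one gene
#'
#' Enumerates all unordered pairs of the gene's alleles (self-pairs
#' included) and retains those whose expected profile matches the
#' observed profile exactly. One candidate -> `assigned`; several ->
#' `ambiguous` (the unphased cis/trans case short reads cannot resolve);
#' none -> `no_call`, which also covers an unexplained passing variant at
#' a definition position.
#'
#' @param gene Gene symbol (must be present in `db` and `panel`).
#' @param qcs A `qualified_callset`.
#' @param db An `allele_db`.
#' @param panel A `panel_config`.
#' @return An object of class `diplotype_call`: list with `gene`,
#'   `status`, `candidates` (list of sorted length-2 character vectors,
#'   ordered deterministically), `observed` and `off_definition`.
#' @export
call_diplotype <- function(gene, qcs, db, panel) {
  gene_row <- panel[panel$gene == gene, ]
  if (nrow(gene_row) != 1L) {
    stop("gene not in panel: ", gene, call. = FALSE)
  }
  alleles <- gene_alleles(db, gene)
  if (length(alleles) == 0L) {
    stop("gene has no allele definitions: ", gene, call. = FALSE)
  }
  obs <- observed_profile(gene_row, qcs, db)
  nm <- names(alleles)
  candidates <- list()
  for (i in seq_along(nm)) {
    for (j in i:length(nm)) {
      exp_prof <- expected_profile(alleles[[i]], alleles[[j]])
      if (profiles_equal(exp_prof, obs$profile)) {
        candidates[[length(candidates) + 1L]] <- sort(c(nm[i], nm[j]))
      }
    }
  }
  candidates <- candidates[order(vapply(candidates, paste,
                                        character(1), collapse = "/"))]
  status <- if (length(candidates) == 1L) "assigned"
            else if (length(candidates) > 1L) "ambiguous" else "no_call"
  structure(list(gene = gene, status = status, candidates = candidates,
                 observed = obs$profile,
                 off_definition = obs$off_definition),
            class = "diplotype_call")
}

#' @export
print.diplotype_call <- function(x, ...) {
  shown <- if (length(x$candidates)) {
    paste(vapply(x$candidates, paste, character(1), collapse = "/"),
          collapse = ", ")
  } else "-"
  cat(sprintf("<diplotype_call> %s: %s [%s]\n", x$gene, shown, x$status))
  invisible(x)
}

#' Call diplotypes for every gene with allele definitions
#'
#' Genes present in the panel but absent from the allele database (e.g.
#' candidate placeholders) are skipped with a message.
#'
#' @inheritParams call_diplotype
#' @return Named list of `diplotype_call`, one per database gene, in
#'   panel order.
#' @export
call_all <- function(qcs, db, panel) {
  genes <- panel$gene[panel$gene %in% unique(db$gene)]
  skipped <- setdiff(panel$gene, genes)
  if (length(skipped)) {
    message("skipping genes without allele definitions: ",
            paste(skipped, collapse = ", "))
  }
  stats::setNames(lapply(genes, call_diplotype, qcs = qcs, db = db,
                         panel = panel), genes)
}

#' Serialize diplotype calls to a stable JSON report
#'
#' Field order and candidate order are deterministic, so identical inputs
#' produce byte-identical reports.
#'
#' @param calls Named list from [call_all()] (or a single
#'   `diplotype_call`).
#' @param sample Sample identifier written into the report.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
diplotype_report_json <- function(calls, sample = "sample", path = NULL) {
  if (inherits(calls, "diplotype_call")) {
    calls <- stats::setNames(list(calls), calls$gene)
  }
  body <- lapply(calls, function(dc) {
    list(
      gene = dc$gene,
      status = dc$status,
      candidates = lapply(dc$candidates, function(p)
        list(allele_a = p[1L], allele_b = p[2L])),
      observed = as.list(dc$observed),
      off_definition = if (nrow(dc$off_definition)) {
        lapply(seq_len(nrow(dc$off_definition)), function(i)
          list(key = dc$off_definition$key[i],
               zygosity = dc$off_definition$zygosity[i],
               quality = dc$off_definition$quality[i],
               depth = dc$off_definition$depth[i]))
      } else list()
    )
  })
  out <- jsonlite::toJSON(list(sample = sample, genes = body),
                          auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(as.character(out)))
  }
  as.character(out)
}
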