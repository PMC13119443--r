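# ---------------------------------------------------------------------------
# Rare-variant prioritization.
#
# A multi-step cascade over annotated calls: (i) rarity across population
# frequency databases, (ii) call quality, (iii) predicted-impact
# consequence class, (iv) at least one line of supporting evidence from an
# in-silico predictor or a non-benign ClinVar assertion (truncating
# classes carry that support intrinsically). Every variant receives a
# full audit-trail verdict.
# ---------------------------------------------------------------------------

AF_SOURCES <- c("gnomad_af", "kg_af", "g5k_af", "dbsnp_af")
CONSEQUENCES <- c("missense", "frameshift", "stop_gained", "splice",
                  "synonymous", "intronic", "other")

#' Rare-variant filter configuration
#'
#' Defaults encode the pipeline's prioritization policy: a variant is
#' rare below 1% in every available population database; depth must be
#' at least 30 (inclusive here, unlike the strict `>30` used for call
#' qualification; both rules are implemented verbatim and documented
#' side by side); the damaging consequence classes are non-synonymous
#' coding, truncating and splice changes; predictor support means DANN
#' at or above `dann_min`, a damaging FATHMM/MutationTaster label, or a
#' non-benign ClinVar assertion. Label vocabularies are configuration
#' because the underlying tools publish no universal cut-offs.
#'
#' @param max_maf Maximum minor allele frequency (exclusive), default
#'   0.01.
#' @param min_depth Minimum depth (inclusive), default 30.
#' @param min_quality Site quality threshold (exclusive), default 42 --
#'   the same quality gate used panel-wide.
#' @param damaging_consequences Consequence tokens that pass step (iii).
#' @param dann_min DANN score counted as supportive, default 0.9.
#' @param damaging_labels FATHMM/MutationTaster labels counted as
#'   supportive.
#' @param benign_clinvar_labels ClinVar labels that do **not** count as
#'   supportive.
#' @return An object of class `rare_filter_config`.
#' @export
rare_filter_config <- function(max_maf = 0.01,
                               min_depth = 30,
                               min_quality = 42,
                               damaging_consequences = c("missense",
                                                         "frameshift",
                                                         "stop_gained",
                                                         "splice"),
                               dann_min = 0.9,
                               damaging_labels = c("D", "damaging",
                                                   "deleterious",
                                                   "disease_causing"),
                               benign_clinvar_labels = c("Benign",
                                                         "Likely_benign",
                                                         "Benign/Likely_benign")) {
  stopifnot(max_maf > 0, max_maf < 1, min_depth > 0)
  structure(list(max_maf = max_maf, min_depth = min_depth,
                 min_quality = min_quality,
                 damaging_consequences = damaging_consequences,
                 dann_min = dann_min, damaging_labels = damaging_labels,
                 benign_clinvar_labels = benign_clinvar_labels),
            class = "rare_filter_config")
}

#' Apply the rare-variant prioritization cascade
#'
#' A variant is retained iff all four steps hold: every available
#' population frequency is below `max_maf` (absent sources are ignored;
#' a variant absent from every database counts as rare), depth and
#' quality pass, the consequence is in the damaging set, and at least
#' one supportive evidence line exists -- except frameshift and
#' stop-gained variants, which satisfy the evidence step intrinsically.
#'
#' @param variants Data.frame of annotated variants: columns `key`,
#'   `zygosity`, `quality`, `depth`, the frequency columns `gnomad_af`,
#'   `kg_af`, `g5k_af`, `dbsnp_af`, plus `consequence`, `dann`,
#'   `fathmm`, `mutation_taster`, `clinvar` (use `NA` for absent
#'   annotations). Built by [annotate_from_vcf_info()] or directly.
#' @param cfg A [rare_filter_config()].
#' @return List with `retained` (subset of `variants`) and `audit`
#'   (one row per input variant: per-step verdicts, terminal `retained`
#'   flag, `first_failed_step` of `"rare"`, `"quality"`,
#'   `"consequence"`, `"evidence"` or `"-"`).
#' @export
filter_rare <- function(variants, cfg = rare_filter_config()) {
  stopifnot(inherits(cfg, "rare_filter_config"))
  n <- nrow(variants)
  step_rare <- logical(n)
  step_quality <- logical(n)
  step_consequence <- logical(n)
  step_evidence <- logical(n)
  for (i in seq_len(n)) {
    afs <- unlist(variants[i, AF_SOURCES])
    afs <- afs[!is.na(afs)]
    step_rare[i] <- length(afs) == 0L || max(afs) < cfg$max_maf
    step_quality[i] <- !is.na(variants$depth[i]) &&
      variants$depth[i] >= cfg$min_depth &&
      !is.na(variants$quality[i]) &&
      variants$quality[i] > cfg$min_quality
    cons <- variants$consequence[i]
    step_consequence[i] <- !is.na(cons) &&
      cons %in% cfg$damaging_consequences
    intrinsic <- !is.na(cons) && cons %in% c("frameshift", "stop_gained")
    dann_ok <- !is.na(variants$dann[i]) && variants$dann[i] >= cfg$dann_min
    fathmm_ok <- !is.na(variants$fathmm[i]) &&
      tolower(variants$fathmm[i]) %in% tolower(cfg$damaging_labels)
    mt_ok <- !is.na(variants$mutation_taster[i]) &&
      tolower(variants$mutation_taster[i]) %in% tolower(cfg$damaging_labels)
    clinvar_ok <- !is.na(variants$clinvar[i]) &&
      !(variants$clinvar[i] %in% cfg$benign_clinvar_labels)
    step_evidence[i] <- intrinsic || dann_ok || fathmm_ok || mt_ok ||
      clinvar_ok
  }
  retained <- step_rare & step_quality & step_consequence & step_evidence
  first_failed <- rep("-", n)
  first_failed[!step_evidence] <- "evidence"
  first_failed[!step_consequence] <- "consequence"
  first_failed[!step_quality] <- "quality"
  first_failed[!step_rare] <- "rare"
  audit <- data.frame(
    key = variants$key, rare = step_rare, quality = step_quality,
    consequence = step_consequence, evidence = step_evidence,
    retained = retained, first_failed_step = first_failed,
    stringsAsFactors = FALSE)
  kept <- variants[retained, , drop = FALSE]
  rownames(kept) <- NULL
  list(retained = kept, audit = audit)
}

#' Annotate variant calls from VCF INFO fields
#'
#' Reads annotation INFO keys from a VCF and joins them onto the given
#' calls by variant key. Recognized keys: `GNOMAD_AF`, `KG_AF`,
#' `G5K_AF`, `DBSNP_AF` (floats), `CSQ` (consequence token), `DANN`
#' (float), `FATHMM`, `MT`, `CLNSIG` (strings). Absent keys map to `NA`
#' -- never to a default -- and malformed numeric fields are collected
#' as record-level errors (attribute `errors`) while the variant is
#' kept with the affected annotation absent.
#'
#' @param calls Data.frame of calls (from [read_vcf_calls()] or a
#'   `qualified_callset`'s `calls` element).
#' @param path Path to the annotated VCF.
#' @return Data.frame of annotated variants suitable for
#'   [filter_rare()], with attribute `errors`.
#' @export
annotate_from_vcf_info <- function(calls, path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  errors <- character(0)
  info_key <- character(nrow(fix))
  ann <- vector("list", nrow(fix))
  num_field <- function(kv, name, chrom, pos) {
    if (!(name %in% names(kv))) return(NA_real_)
    x <- suppressWarnings(as.numeric(kv[[name]]))
    if (is.na(x)) {
      errors <<- c(errors, sprintf("%s:%s malformed %s='%s'", chrom, pos,
                                   name, kv[[name]]))
    }
    x
  }
  for (i in seq_len(nrow(fix))) {
    info <- fix[i, "INFO"]
    kv <- list()
    if (!is.na(info) && nzchar(info) && info != ".") {
      for (tok in strsplit(info, ";", fixed = TRUE)[[1]]) {
        eq <- regexpr("=", tok, fixed = TRUE)
        if (eq > 0) {
          kv[[substr(tok, 1, eq - 1)]] <- substr(tok, eq + 1, nchar(tok))
        } else {
          kv[[tok]] <- TRUE
        }
      }
    }
    alt1 <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]][1L]
    info_key[i] <- tryCatch(
      variant_key(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                  fix[i, "REF"], alt1),
      error = function(e) NA_character_)
    chrom <- fix[i, "CHROM"]
    pos <- fix[i, "POS"]
    str_field <- function(name) {
      if (!(name %in% names(kv))) NA_character_
      else as.character(kv[[name]])
    }
    ann[[i]] <- list(
      gnomad_af = num_field(kv, "GNOMAD_AF", chrom, pos),
      kg_af = num_field(kv, "KG_AF", chrom, pos),
      g5k_af = num_field(kv, "G5K_AF", chrom, pos),
      dbsnp_af = num_field(kv, "DBSNP_AF", chrom, pos),
      consequence = str_field("CSQ"),
      dann = num_field(kv, "DANN", chrom, pos),
      fathmm = str_field("FATHMM"),
      mutation_taster = str_field("MT"),
      clinvar = str_field("CLNSIG"))
  }
  out <- calls
  for (col in c("gnomad_af", "kg_af", "g5k_af", "dbsnp_af", "dann")) {
    out[[col]] <- rep(NA_real_, nrow(out))
  }
  for (col in c("consequence", "fathmm", "mutation_taster", "clinvar")) {
    out[[col]] <- rep(NA_character_, nrow(out))
  }
  idx <- match(out$key, info_key)
  for (r in seq_len(nrow(out))) {
    j <- idx[r]
    if (is.na(j)) next
    a <- ann[[j]]
    for (col in names(a)) {
      out[[col]][r] <- a[[col]]
    }
  }
  attr(out, "errors") <- errors
  out
}

#' Write the retained rare variants and their audit trail
#'
#' @param result List from [filter_rare()].
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @return Invisibly, the JSON string.
#' @export
write_rare_report <- function(result, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(result$audit, path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  js <- jsonlite::toJSON(list(retained = result$retained,
                              audit = result$audit),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path_json)) writeLines(js, path_json)
  invisible(as.character(js))
}
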