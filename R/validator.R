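# ---------------------------------------------------------------------------
# Concordance against reference-material truth sets, nomenclature
# harmonization, and analytical performance metrics.
# ---------------------------------------------------------------------------

COMPARISON_CATEGORIES <- c("concordant", "test_only_allele",
                           "reference_only_allele", "discordant")

#' Compare diplotype tables allele by allele
#'
#' Truth and test tables (`sample`, `gene`, `allele1`, `allele2`) are
#' matched per (sample, gene) as unordered multisets: exact name matches
#' are consumed first, remaining alleles are paired by sub-allele base
#' name (`*2.001` with `*2`) and then positionally, and each resulting
#' truth/test allele pair is categorized. `test_only_allele` marks a test allele not present in
#' the reference nomenclature (the truth set's known allele names);
#' `reference_only_allele` marks a truth allele absent from the test
#' allele database; everything else is `discordant`. One output row is
#' one allele-level comparison, so every (sample, gene) contributes two
#' rows.
#'
#' @param truth,test Data.frames with columns `sample`, `gene`,
#'   `allele1`, `allele2`.
#' @param db The test pipeline's `allele_db`.
#' @param reference_nomenclature Named list gene -> character vector of
#'   star-allele names known to the reference dataset.
#' @return Data.frame of class `allele_comparisons` with columns
#'   `sample`, `gene`, `reference_allele`, `test_allele`, `category`.
#' @export
compare_allele_calls <- function(truth, test, db, reference_nomenclature) {
  need <- c("sample", "gene", "allele1", "allele2")
  stopifnot(all(need %in% names(truth)), all(need %in% names(test)),
            inherits(db, "allele_db"))
  tk <- paste(truth$sample, truth$gene)
  ek <- paste(test$sample, test$gene)
  only <- c(setdiff(tk, ek), setdiff(ek, tk))
  if (length(only)) {
    stop("(sample, gene) present in only one table: ",
         paste(unique(only), collapse = "; "), call. = FALSE)
  }
  if (anyDuplicated(tk) || anyDuplicated(ek)) {
    stop("duplicate (sample, gene) rows in diplotype table", call. = FALSE)
  }
  rows <- list()
  for (i in order(tk)) {
    j <- match(tk[i], ek)
    t_all <- sort(c(truth$allele1[i], truth$allele2[i]))
    e_all <- sort(c(test$allele1[j], test$allele2[j]))
    # consume exact name matches first
    t_left <- t_all
    e_left <- e_all
    for (a in t_all) {
      hit <- match(a, e_left)
      if (!is.na(hit) && a %in% t_left) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = truth$sample[i], gene = truth$gene[i],
          reference_allele = a, test_allele = a, category = "concordant",
          stringsAsFactors = FALSE)
        t_left <- t_left[-match(a, t_left)]
        e_left <- e_left[-hit]
      }
    }
    # pair leftovers by sub-allele base name first (e.g. *2.001 with
    # *2, the typical definition-version discrepancy), then
    # positionally over the sorted remainder
    gene <- truth$gene[i]
    known_ref <- reference_nomenclature[[gene]]
    db_alleles <- db$allele[db$gene == gene]
    base_name <- function(a) sub("\\..*$", "", a)
    pairs <- list()
    k <- 1L
    while (k <= length(e_left)) {
      hit <- match(base_name(e_left[k]), base_name(t_left))
      if (!is.na(hit)) {
        pairs[[length(pairs) + 1L]] <- c(t_left[hit], e_left[k])
        t_left <- t_left[-hit]
        e_left <- e_left[-k]
      } else {
        k <- k + 1L
      }
    }
    for (k in seq_along(t_left)) {
      pairs[[length(pairs) + 1L]] <- c(t_left[k], e_left[k])
    }
    for (pr in pairs) {
      ta <- pr[1L]
      ea <- pr[2L]
      category <- if (!is.null(known_ref) && !(ea %in% known_ref)) {
        "test_only_allele"
      } else if (!(ta %in% db_alleles)) {
        "reference_only_allele"
      } else {
        "discordant"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = truth$sample[i], gene = gene, reference_allele = ta,
        test_allele = ea, category = category, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("allele_comparisons", "data.frame")
  out
}

lookup_defining <- function(tab, gene, allele) {
  if (inherits(tab, "allele_db")) {
    i <- which(tab$gene == gene & tab$allele == allele)
    if (length(i) == 1L) return(tab$defining[[i]])
    return(NULL)
  }
  i <- which(tab$gene == gene & tab$allele == allele)
  if (length(i) == 1L) return(tab$defining[[i]])
  NULL
}

#' Load a legacy-nomenclature map
#'
#' Same dialect as the allele database (`gene  allele
#' defining_variants`) but without the `*1` requirement: it records the
#' defining-variant content of legacy or reference-dataset allele names
#' so that harmonization can compare names by content.
#'
#' @param path Path to the TSV.
#' @return Data.frame with `gene`, `allele` and list-column `defining`.
#' @export
load_legacy_map <- function(path) {
  rows <- read_tsv_strict(path, c("gene", "allele", "defining_variants"))
  defining <- lapply(seq_len(nrow(rows)), function(i) {
    parse_defining(rows$defining_variants[i], path, rows$.line[i])
  })
  out <- data.frame(gene = rows$gene, allele = rows$allele,
                    stringsAsFactors = FALSE)
  out$defining <- defining
  out
}

#' Harmonize nomenclature-driven discrepancies
#'
#' Reference datasets often rest on older allele-definition releases, so
#' a call can disagree in name while agreeing in variant content. For
#' each `test_only_allele` or `reference_only_allele` comparison, the
#' test allele's defining set (from `db`) is compared with the reference
#' allele's defining set (from `legacy_map`); a name missing from its
#' table leaves the comparison unchanged with a warning. The comparison
#' is upgraded to `concordant` iff the two sets are identical. Discordant comparisons are never upgraded, and no other
#' category changes, so harmonization can only raise concordance and
#' never alters the number of comparisons.
#'
#' @param comparisons An `allele_comparisons` table.
#' @param db The test pipeline's `allele_db`.
#' @param legacy_map Table from [load_legacy_map()] (or `allele_db`).
#' @return The updated `allele_comparisons` table with attribute
#'   `harmonized = TRUE`.
#' @export
harmonize <- function(comparisons, db, legacy_map) {
  stopifnot(inherits(comparisons, "allele_comparisons"))
  out <- comparisons
  for (i in seq_len(nrow(out))) {
    cat_i <- out$category[i]
    if (!(cat_i %in% c("test_only_allele", "reference_only_allele"))) next
    g <- out$gene[i]
    test_set <- lookup_defining(db, g, out$test_allele[i])
    ref_set <- lookup_defining(legacy_map, g, out$reference_allele[i])
    if (is.null(test_set) || is.null(ref_set)) {
      warning(sprintf("no definition available to harmonize %s %s vs %s",
                      g, out$reference_allele[i], out$test_allele[i]),
              call. = FALSE)
      next
    }
    if (setequal(test_set, ref_set)) {
      out$category[i] <- "concordant"
    }
  }
  attr(out, "harmonized") <- TRUE
  out
}

# round half-up at `digits` decimals (matches printed report precision)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize allele-level concordance
#'
#' @param comparisons An `allele_comparisons` table (non-empty).
#' @return An object of class `concordance_report`: list with `total`,
#'   `counts` (named, one per category), `concordance_pct` (half-up, one
#'   decimal), `concordance_fraction` (raw) and `harmonized`.
#' @export
concordance <- function(comparisons) {
  stopifnot(inherits(comparisons, "allele_comparisons"))
  if (nrow(comparisons) == 0L) {
    stop("empty comparison list", call. = FALSE)
  }
  counts <- vapply(COMPARISON_CATEGORIES, function(cc)
    sum(comparisons$category == cc), integer(1))
  total <- nrow(comparisons)
  frac <- counts[["concordant"]] / total
  structure(list(total = total, counts = counts,
                 concordance_pct = round_half_up(100 * frac, 1),
                 concordance_fraction = frac,
                 harmonized = isTRUE(attr(comparisons, "harmonized"))),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d allele calls, %.1f%% concordant%s\n",
              x$total, x$concordance_pct,
              if (x$harmonized) " (harmonized)" else ""))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Confusion counts and performance metrics
# ---------------------------------------------------------------------------

#' Position-wise confusion counts against a variant truth set
#'
#' TP: truth variants reported passing with matching zygosity. FN: truth
#' variants absent, rejected, or called with the wrong zygosity. FP:
#' passing calls not matching any truth variant. TN: targeted reference
#' positions carrying no truth variant and no passing call (the
#' position-wise footprint that gives agreement metrics their large
#' negative denominator).
#'
#' @param qcs A `qualified_callset`.
#' @param truth Data.frame with columns `key`, `zygosity`, restricted to
#'   the target.
#' @param target Data.frame of regions (`chrom`, `start`, `end`,
#'   1-based inclusive) defining the evaluated footprint.
#' @return List of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_vs_truth <- function(qcs, truth, target) {
  stopifnot(inherits(qcs, "qualified_callset"),
            all(c("key", "zygosity") %in% names(truth)),
            all(c("chrom", "start", "end") %in% names(target)))
  calls <- qcs$calls
  in_target <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      any(target$chrom == chrom[i] & target$start <= pos[i] &
            target$end >= pos[i])
    }, logical(1))
  }
  if (nrow(calls)) {
    keep <- in_target(calls$chrom, calls$pos)
    calls <- calls[keep, , drop = FALSE]
  }
  truth_sig <- paste(truth$key, truth$zygosity)
  call_sig <- paste(calls$key, calls$zygosity)
  tp <- sum(truth_sig %in% call_sig)
  fn <- nrow(truth) - tp
  fp <- sum(!(call_sig %in% truth_sig))
  total_bases <- sum(target$end - target$start + 1)
  touched <- unique(c(
    if (nrow(truth)) paste(parse_variant_key(truth$key)$chrom,
                           parse_variant_key(truth$key)$pos),
    if (nrow(calls)) paste(calls$chrom, calls$pos)))
  tn <- total_bases - length(touched)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

pct_or_na <- function(num, den) {
  if (den <= 0) return(NA_real_)
  100 * num / den
}

#' Analytical performance metrics from confusion counts
#'
#' Standard agreement metrics for assay validation: accuracy
#' (tp+tn)/(tp+tn+fp+fn), PPA (sensitivity) tp/(tp+fn), NPA
#' (specificity) tn/(tn+fp) and PPV tp/(tp+fp), all as percentages. A
#' metric whose denominator is zero is reported `NA` (undefined), never
#' coerced to 0.
#'
#' @param c A `confusion_counts`.
#' @return List of class `performance_report` with `accuracy_pct`,
#'   `ppa_pct`, `npa_pct`, `ppv_pct`.
#' @export
performance <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  structure(list(
    accuracy_pct = pct_or_na(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn),
    ppa_pct = pct_or_na(c$tp, c$tp + c$fn),
    npa_pct = pct_or_na(c$tn, c$tn + c$fp),
    ppv_pct = pct_or_na(c$tp, c$tp + c$fp)
  ), class = "performance_report")
}

#' Replicate agreement (repeatability / reproducibility)
#'
#' For every unordered pair of replicates in the requested grouping,
#' agreement is the share of the union of passing variant keys on which
#' both replicates agree in key and zygosity; the metric is the mean
#' over pairs, as a percentage. `within_run` pairs (same `run` metadata)
#' give repeatability; `across_runs` pairs give reproducibility.
#'
#' @param replicates List of `qualified_callset`s, each carrying a `run`
#'   attribute (set by [simulate_replicates()] or manually via
#'   `attr(x, "run")`).
#' @param grouping `"within_run"` or `"across_runs"`.
#' @return Mean pairwise agreement in percent.
#' @export
replicate_agreement <- function(replicates,
                                grouping = c("within_run", "across_runs")) {
  grouping <- match.arg(grouping)
  if (length(replicates) < 2L) {
    stop("at least two replicates are required", call. = FALSE)
  }
  runs <- vapply(replicates, function(r) {
    run <- attr(r, "run")
    if (is.null(run)) "run1" else as.character(run)
  }, character(1))
  pair_agreement <- function(a, b) {
    sig_a <- stats::setNames(a$calls$zygosity, a$calls$key)
    sig_b <- stats::setNames(b$calls$zygosity, b$calls$key)
    u <- union(names(sig_a), names(sig_b))
    if (length(u) == 0L) return(100)
    shared <- intersect(names(sig_a), names(sig_b))
    agree <- sum(sig_a[shared] == sig_b[shared])
    100 * agree / length(u)
  }
  vals <- numeric(0)
  n <- length(replicates)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same <- runs[i] == runs[j]
      if ((grouping == "within_run") == same) {
        vals <- c(vals, pair_agreement(replicates[[i]], replicates[[j]]))
      }
    }
  }
  if (length(vals) == 0L) {
    stop("no replicate pairs in grouping ", grouping, call. = FALSE)
  }
  mean(vals)
}

#' Per-gene coverage summary
#'
#' Mean depth and percentage of targeted bases at depth >= 30 for each
#' panel gene; positions absent from the profile count as depth 0.
#'
#' @param cov A `coverage_profile`.
#' @param panel A `panel_config`.
#' @param min_depth Depth threshold for the percentage column
#'   (default 30).
#' @return Data.frame with columns `gene`, `mean_depth`,
#'   `pct_bases_ge_30x`.
#' @export
coverage_summary <- function(cov, panel, min_depth = 30) {
  stopifnot(inherits(cov, "coverage_profile"),
            inherits(panel, "panel_config"))
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    pos <- seq.int(panel$start[i], panel$end[i])
    d <- depth_lookup(cov, rep(panel$chrom[i], length(pos)), pos)
    data.frame(gene = panel$gene[i], mean_depth = mean(d),
               pct_bases_ge_30x = 100 * mean(d >= min_depth),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
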