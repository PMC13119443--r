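# Shared in-code fixtures: everything is generated at test time; no
# binary files.

# build an allele_db directly from a named list
#   toy_db(CYP2C19 = list(`*1` = character(0), `*2` = "chr10:96541616:G:A"))
toy_db <- function(...) {
  genes <- list(...)
  rows <- list()
  for (g in names(genes)) {
    for (a in names(genes[[g]])) {
      rows[[length(rows) + 1L]] <- list(gene = g, allele = a,
                                        defining = sort(unname(genes[[g]][[a]])))
    }
  }
  db <- data.frame(gene = vapply(rows, `[[`, character(1), "gene"),
                   allele = vapply(rows, `[[`, character(1), "allele"),
                   stringsAsFactors = FALSE)
  db$defining <- lapply(rows, function(r) as.character(r$defining))
  class(db) <- c("allele_db", "data.frame")
  db
}

toy_panel <- function(genes = "GENE1", chrom = "chr1", start = 1L,
                      end = 10000L, category = "priority",
                      strategy = "full") {
  n <- length(genes)
  out <- data.frame(gene = genes, category = rep_len(category, n),
                    chrom = rep_len(chrom, n),
                    start = as.integer(rep_len(start, n)),
                    end = as.integer(rep_len(end, n)),
                    strategy = rep_len(strategy, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("panel_config", "data.frame")
  out
}

# minimal hand-written VCF
write_test_vcf <- function(records, path, sample = "S1",
                           extra_header = character(0)) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    extra_header,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, qual = 99, filter = "PASS",
                     info = "DP=100", format = "GT:DP", sample = "0/1:100") {
  paste(chrom, pos, ".", ref, alt, qual, filter, info, format, sample,
        sep = "\t")
}

make_calls <- function(keys, zygosity = "het", quality = 99,
                       depth = 100L) {
  if (length(keys) == 0L) return(pgxpanel:::empty_calls())
  parsed <- parse_variant_key(keys)
  data.frame(key = keys, chrom = parsed$chrom, pos = parsed$pos,
             ref = parsed$ref, alt = parsed$alt,
             zygosity = rep_len(zygosity, length(keys)),
             quality = rep_len(quality, length(keys)),
             depth = as.integer(rep_len(depth, length(keys))),
             filter_flagged = FALSE, stringsAsFactors = FALSE)
}

make_qcs <- function(keys, zygosity = "het", sample = "S1", ...) {
  qualify(make_calls(keys, zygosity, ...), qual_thresholds(),
          sample = sample)
}

# random toy allele database for property tests: <= 6 alleles over <= 5
# definition variants on one gene
random_toy_db <- function(gene = "G", n_alleles = 4L, n_vars = 4L) {
  vars <- variant_key("chr1", 100L + 10L * seq_len(n_vars), "A", "G")
  # only 2^n_vars distinct defining sets exist (incl. the empty one)
  n_alleles <- min(n_alleles, 2L^n_vars)
  alleles <- list(`*1` = character(0))
  k <- 2L
  while (length(alleles) < n_alleles) {
    pick <- sort(sample(vars, sample.int(n_vars, 1L)))
    if (any(vapply(alleles, identical, logical(1), pick))) next
    alleles[[paste0("*", k)]] <- pick
    k <- k + 1L
  }
  args <- list(alleles)
  names(args) <- gene
  do.call(toy_db, args)
}

# independent brute-force diplotype oracle: enumerate all unordered
# allele pairs and match profiles by explicit set logic (no shared code
# with the engine's candidate loop beyond expected_profile's definition,
# which is re-derived here from plain set operations)
oracle_candidates <- function(db, gene, observed) {
  alleles <- gene_alleles(db, gene)
  nm <- names(alleles)
  out <- list()
  for (i in seq_along(nm)) {
    for (j in i:length(nm)) {
      da <- alleles[[i]]
      db_ <- alleles[[j]]
      u <- sort(unique(c(da, db_)))
      exp_z <- vapply(u, function(v) {
        if (v %in% da && v %in% db_) "hom" else "het"
      }, character(1))
      same <- length(u) == length(observed) &&
        all(sort(u) == sort(names(observed))) &&
        all(exp_z[sort(names(observed))] ==
              observed[sort(names(observed))])
      if (length(u) == 0L && length(observed) == 0L) same <- TRUE
      if (same) out[[length(out) + 1L]] <- sort(c(nm[i], nm[j]))
    }
  }
  out[order(vapply(out, paste, character(1), collapse = "/"))]
}
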