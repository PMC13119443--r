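diplo_tab <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[1], gene = r[2], allele1 = r[3], allele2 = r[4],
               stringsAsFactors = FALSE)))
}

test_that("allele comparison matches unordered pairs and categorizes leftovers", {
  db <- toy_db(G = list(`*1` = character(0), `*2` = "chr1:100:A:G",
                        `*2.001` = "chr1:100:A:G"))
  nomen <- list(G = c("*1", "*2", "*36"))

  # order-insensitive exact matching
  comps <- compare_allele_calls(diplo_tab(c("S1", "G", "*1", "*2")),
                                diplo_tab(c("S1", "G", "*2", "*1")),
                                db, nomen)
  expect_equal(nrow(comps), 2L)
  expect_true(all(comps$category == "concordant"))

  # test reports a sub-allele unknown to the reference nomenclature
  comps <- compare_allele_calls(diplo_tab(c("S1", "G", "*1", "*2")),
                                diplo_tab(c("S1", "G", "*1", "*2.001")),
                                db, nomen)
  expect_setequal(comps$category, c("concordant", "test_only_allele"))

  # truth uses an allele the test database lacks
  comps <- compare_allele_calls(diplo_tab(c("S1", "G", "*1", "*36")),
                                diplo_tab(c("S1", "G", "*1", "*1")),
                                db, nomen)
  expect_setequal(comps$category, c("concordant",
                                    "reference_only_allele"))

  # both known, different -> discordant
  comps <- compare_allele_calls(diplo_tab(c("S1", "G", "*1", "*1")),
                                diplo_tab(c("S1", "G", "*1", "*2")),
                                db, nomen)
  expect_setequal(comps$category, c("concordant", "discordant"))

  # mismatched sample universes are an error
  expect_error(
    compare_allele_calls(diplo_tab(c("S1", "G", "*1", "*1")),
                         diplo_tab(c("S2", "G", "*1", "*1")), db, nomen),
    "only one table")
})

test_that("harmonization upgrades by variant content and only that", {
  db <- toy_db(G = list(`*1` = character(0), `*2` = "chr1:100:A:G",
                        `*2.001` = "chr1:100:A:G",
                        `*4` = "chr1:300:C:T"))
  legacy <- data.frame(gene = "G", allele = "*2",
                       stringsAsFactors = FALSE)
  legacy$defining <- list("chr1:100:A:G")
  nomen <- list(G = c("*1", "*2", "*4"))

  comps <- compare_allele_calls(diplo_tab(c("S1", "G", "*2", "*4")),
                                diplo_tab(c("S1", "G", "*2.001", "*1")),
                                db, nomen)
  expect_setequal(comps$category, c("test_only_allele", "discordant"))
  harm <- harmonize(comps, db, legacy)
  # *2.001 vs *2 share content -> concordant; *4 vs *1 is a real miss
  expect_setequal(harm$category, c("concordant", "discordant"))
  expect_equal(nrow(harm), nrow(comps))

  # a legacy name with different content is not upgraded
  legacy2 <- legacy
  legacy2$defining <- list("chr1:999:A:G")
  harm2 <- harmonize(comps, db, legacy2)
  expect_setequal(harm2$category, c("test_only_allele", "discordant"))

  # missing legacy entry leaves the row unchanged with a warning
  legacy3 <- legacy[0, ]
  expect_warning(harm3 <- harmonize(comps, db, legacy3), "harmonize")
  expect_identical(harm3$category, comps$category)
})

test_that("harmonization is monotone and conserves the comparison count", {
  fx <- build_getrm_fixture()
  pre <- concordance(fx$comparisons)
  post <- concordance(harmonize(fx$comparisons, fx$db, fx$legacy_map))
  expect_gte(post$concordance_pct, pre$concordance_pct)
  expect_equal(post$total, pre$total)
})

test_that("concordance arithmetic reproduces half-up one-decimal reporting", {
  mk <- function(n_conc, n_disc) {
    df <- data.frame(
      sample = "S", gene = "G", reference_allele = "*1",
      test_allele = c(rep("*1", n_conc), rep("*2", n_disc)),
      category = c(rep("concordant", n_conc), rep("discordant", n_disc)),
      stringsAsFactors = FALSE)
    class(df) <- c("allele_comparisons", "data.frame")
    df
  }
  expect_equal(concordance(mk(228, 22))$concordance_pct, 91.2)
  expect_equal(concordance(mk(10, 0))$concordance_pct, 100)
  expect_equal(concordance(mk(0, 10))$concordance_pct, 0)
  expect_equal(concordance(mk(1, 2))$concordance_fraction, 1 / 3)
  none <- mk(1, 0)[0, ]
  class(none) <- c("allele_comparisons", "data.frame")
  expect_error(concordance(none), "empty")
})

test_that("confusion counts follow the position-wise footprint", {
  target <- data.frame(chrom = "chr1", start = 1L, end = 10L)
  truth <- data.frame(key = c("chr1:2:A:G", "chr1:5:C:T"),
                      zygosity = c("het", "hom"),
                      stringsAsFactors = FALSE)

  # identical callset: no false calls
  qcs <- make_qcs(truth$key, zygosity = truth$zygosity)
  conf <- confusion_vs_truth(qcs, truth, target)
  expect_equal(conf$fp, 0L)
  expect_equal(conf$fn, 0L)
  expect_equal(conf$tp, 2L)
  expect_equal(conf$tn, 8L)

  # 1 of 2 truth variants called, plus 1 extra call -> tp=1 fn=1 fp=1 tn=7
  qcs <- make_qcs(c("chr1:2:A:G", "chr1:9:G:A"))
  conf <- confusion_vs_truth(qcs, truth, target)
  expect_equal(unclass(conf)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 7L))

  # a truth variant rejected for depth counts as a false negative
  calls <- rbind(make_calls("chr1:2:A:G", depth = 100),
                 make_calls("chr1:5:C:T", zygosity = "hom", depth = 10))
  conf <- confusion_vs_truth(qualify(calls), truth, target)
  expect_equal(conf$tp, 1L)
  expect_equal(conf$fn, 1L)
})

test_that("performance metrics use standard formulas and NA for undefined", {
  mk <- function(tp, tn, fp, fn)
    structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
              class = "confusion_counts")
  p <- performance(mk(999, 0, 0, 1))
  expect_equal(p$ppa_pct, 99.9)
  expect_equal(p$ppv_pct, 100)
  p <- performance(mk(10, 90, 0, 0))
  expect_equal(p$accuracy_pct, 100)
  expect_equal(p$npa_pct, 100)
  p <- performance(mk(0, 5, 0, 5))
  expect_equal(p$ppa_pct, 0)
  expect_true(is.na(p$ppv_pct))     # tp + fp = 0
  p <- performance(mk(0, 0, 0, 0))
  expect_true(all(is.na(unlist(p))))
  # self-comparison gives 100% across defined metrics
  target <- data.frame(chrom = "chr1", start = 1L, end = 100L)
  truth <- data.frame(key = "chr1:2:A:G", zygosity = "het",
                      stringsAsFactors = FALSE)
  p <- performance(confusion_vs_truth(make_qcs(truth$key), truth,
                                      target))
  expect_equal(unlist(p), c(accuracy_pct = 100, ppa_pct = 100,
                            npa_pct = 100, ppv_pct = 100))
})

test_that("replicate agreement averages pairwise union agreement", {
  keys <- variant_key("chr1", 1:100 * 10L, "A", "G")
  r1 <- make_qcs(keys); attr(r1, "run") <- "run1"
  r2 <- make_qcs(keys); attr(r2, "run") <- "run1"
  expect_equal(replicate_agreement(list(r1, r2), "within_run"), 100)

  # pair sharing 99 of 100 union calls
  r3 <- make_qcs(keys[-1]); attr(r3, "run") <- "run1"
  expect_equal(replicate_agreement(list(r1, r3), "within_run"), 99)

  # three identical + one missing-one-call: mean over all 6 pairs
  r4 <- make_qcs(keys); attr(r4, "run") <- "run1"
  reps <- list(r1, r2, r4, r3)
  manual <- mean(c(100, 100, 99, 100, 99, 99))
  expect_equal(replicate_agreement(reps, "within_run"), manual)

  # permutation invariance
  expect_equal(replicate_agreement(rev(reps), "within_run"), manual)

  # grouping: across-run pairs only
  attr(r3, "run") <- "run2"
  expect_equal(replicate_agreement(list(r1, r2, r3), "across_runs"), 99)
  expect_equal(replicate_agreement(list(r1, r2, r3), "within_run"), 100)

  expect_error(replicate_agreement(list(r1), "within_run"),
               "at least two")
})

test_that("coverage summary computes per-gene depth and 30x share", {
  panel <- toy_panel("G", "chr1", 1L, 10L)
  cov <- coverage_profile(data.frame(chrom = "chr1", pos = 1:10,
                                     depth = 100L), "S1")
  s <- coverage_summary(cov, panel)
  expect_equal(s$mean_depth, 100)
  expect_equal(s$pct_bases_ge_30x, 100)

  cov <- coverage_profile(data.frame(chrom = "chr1", pos = 1:10,
                                     depth = c(rep(10L, 5), rep(50L, 5))),
                          "S1")
  s <- coverage_summary(cov, panel)
  expect_equal(s$mean_depth, 30)
  expect_equal(s$pct_bases_ge_30x, 50)

  # gene absent from the profile counts as depth 0 everywhere
  panel2 <- rbind(panel, toy_panel("H", "chr9", 1L, 10L))
  class(panel2) <- c("panel_config", "data.frame")
  s <- coverage_summary(cov, panel2)
  expect_equal(s$mean_depth[s$gene == "H"], 0)
  expect_equal(s$pct_bases_ge_30x[s$gene == "H"], 0)
})
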