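model <- load_gene_model_2d6()

test_that("gene model loads with nine ordered exons and paralog masks", {
  expect_s3_class(model, "gene_model_2d6")
  expect_equal(model$exons$segment, paste0("exon", 1:9))
  expect_equal(nrow(model$upstream), 1L)
  expect_gte(nrow(model$paralogs), 2L)
  # minus strand: exon 1 carries the highest genomic coordinate
  expect_true(model$exons$start[1] > model$exons$start[9])
})

test_that("paralog filter removes homolog and low-mapq reads only", {
  p <- model$paralogs[1, ]
  reads <- data.frame(
    chrom = "chr22",
    start = c(p$start + 10L, model$exons$start[5], model$exons$start[5],
              p$start - 20000L),
    end = c(p$start + 160L, model$exons$start[5] + 150L,
            model$exons$start[5] + 150L, p$start - 19850L),
    mapping_quality = c(60L, 60L, 5L, 60L))
  kept <- filter_paralog_alignments(reads, model, min_mapq = 20L)
  # read 1: midpoint in paralog; read 3: low mapq; reads 2 and 4 survive
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$mapping_quality >= 20L))
  expect_error(
    filter_paralog_alignments(
      data.frame(chrom = "chr22", start = 10L, end = 5L,
                 mapping_quality = 60L), model),
    "start < end")
})

test_that("hand-filtered mixed read set matches the two-rule result", {
  set.seed(5)
  n <- 40L
  reads <- data.frame(
    chrom = "chr22",
    start = sample(seq(42520000L, 42550000L), n),
    mapping_quality = sample(0:60, n, replace = TRUE))
  reads$end <- reads$start + 150L
  kept <- filter_paralog_alignments(reads, model, min_mapq = 30L)
  mid <- floor((reads$start + reads$end) / 2)
  manual <- rep(TRUE, n)
  for (i in seq_len(nrow(model$paralogs))) {
    pr <- model$paralogs[i, ]
    manual <- manual & !(mid >= pr$start & mid <= pr$end)
  }
  manual <- manual & reads$mapping_quality >= 30L
  expect_equal(nrow(kept), sum(manual))
})

test_that("pileup depth equals brute-force interval stabbing", {
  e5 <- model$exons[5, ]
  reads <- data.frame(chrom = "chr22",
                      start = c(e5$start, e5$start + 5L),
                      end = c(e5$start + 9L, e5$start + 14L),
                      mapping_quality = 60L)
  cov <- depth_from_reads(reads, model)
  d <- function(pos) cov$depth[cov$chrom == "chr22" & cov$pos == pos]
  expect_equal(d(e5$start), 1L)
  expect_equal(d(e5$start + 5L), 2L)   # overlap
  expect_equal(d(e5$start + 12L), 1L)
  expect_equal(d(e5$start + 20L), 0L)

  set.seed(9)
  rnd <- data.frame(chrom = "chr22",
                    start = sample(seq(e5$start - 50L, e5$end), 30L,
                                   replace = TRUE))
  rnd$end <- rnd$start + sample(20:120, 30L, replace = TRUE)
  rnd$mapping_quality <- 60L
  cov <- depth_from_reads(rnd, model)
  probe <- seq(e5$start, e5$end, by = 7L)
  brute <- vapply(probe, function(p)
    sum(rnd$start <= p & rnd$end >= p), integer(1))
  expect_equal(vapply(probe, d, integer(1)), brute)
})

test_that("normalization is an identity on the control and scale-invariant", {
  ctrl <- simulate_control_coverage(model, base_depth = 600)
  np <- normalize_to_control(ctrl, ctrl, model)
  expect_true(all(abs(np$segment_ratios - 1) < 1e-12))

  doubled <- ctrl
  doubled$depth <- ctrl$depth * 3L
  attr(doubled, "sample") <- "scaled"
  class(doubled) <- class(ctrl)
  np2 <- normalize_to_control(doubled, ctrl, model)
  expect_true(all(abs(np2$segment_ratios - 1) < 1e-12))
})

test_that("halving exon depth halves exon ratios but not the upstream block", {
  ctrl <- simulate_control_coverage(model, base_depth = 600)
  halved <- ctrl
  exon_pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i)
    seq.int(model$exons$start[i], model$exons$end[i])))
  sel <- halved$chrom == "chr22" & halved$pos %in% exon_pos
  halved$depth[sel] <- as.integer(halved$depth[sel] / 2L)
  attr(halved, "sample") <- "halved"
  class(halved) <- class(ctrl)
  np <- normalize_to_control(halved, ctrl, model)
  expect_true(all(abs(np$segment_ratios[paste0("exon", 1:9)] - 0.5) <
                    1e-6))
  expect_lt(abs(np$segment_ratios[["upstream_homolog"]] - 1), 1e-6)
})

test_that("the five structural archetypes classify to their labels", {
  ctrl <- simulate_control_coverage(model)
  expected <- list(diploid = list("none", 2L),
                   deletion_het = list("deletion_het", 1L),
                   duplication = list("duplication", 3L),
                   hybrid_68 = list("hybrid_68_tandem", 2L),
                   deletion_plus_hybrid = list("deletion_plus_hybrid", 1L))
  for (arch in names(expected)) {
    spec <- sim_spec(seed = 1, cnv_archetype = arch, noise_cv = 0)
    cov <- pgxpanel:::simulate_cnv_coverage(spec, model, "s")
    sc <- classify_structure(normalize_to_control(cov, ctrl, model))
    expect_equal(sc$events, expected[[arch]][[1]], info = arch)
    expect_equal(sc$copy_number, expected[[arch]][[2]], info = arch)
  }
})

test_that("constant-ratio profiles obey copy_number = round(2r)", {
  ctrl <- simulate_control_coverage(model)
  for (r in c(0.5, 1.0, 1.5)) {
    cov <- ctrl
    model_pos <- pgxpanel:::model_positions(model)
    sel <- paste(cov$chrom, cov$pos) %in%
      paste(model_pos$chrom, model_pos$pos)
    cov$depth[sel] <- as.integer(round(ctrl$depth[sel] * r))
    attr(cov, "sample") <- "const"
    class(cov) <- class(ctrl)
    sc <- classify_structure(normalize_to_control(cov, ctrl, model))
    expect_equal(sc$copy_number, as.integer(round(2 * r)))
  }
})

test_that("out-of-band ratios yield unclassified with per-segment states", {
  ctrl <- simulate_control_coverage(model)
  cov <- ctrl
  cov$depth <- as.integer(cov$depth * 3L)  # ratio 3 after control division
  # keep ballast diploid so the panel-wide median stays at base depth
  model_pos <- pgxpanel:::model_positions(model)
  sel <- !(paste(cov$chrom, cov$pos) %in%
             paste(model_pos$chrom, model_pos$pos))
  cov$depth[sel] <- ctrl$depth[sel]
  attr(cov, "sample") <- "amp"
  class(cov) <- class(ctrl)
  sc <- classify_structure(normalize_to_control(cov, ctrl, model))
  expect_false(sc$classified)
  expect_equal(sc$events, "unclassified")
  expect_true(all(is.na(sc$per_segment_state)))
})

test_that("classification is robust to 10% multiplicative depth noise", {
  ctrl <- simulate_control_coverage(model)
  archetype_events <- c(diploid = "none", deletion_het = "deletion_het",
                        duplication = "duplication",
                        hybrid_68 = "hybrid_68_tandem",
                        deletion_plus_hybrid = "deletion_plus_hybrid")
  for (arch in names(archetype_events)) {
    for (seed in 1:20) {
      spec <- sim_spec(seed = seed, cnv_archetype = arch, noise_cv = 0.1)
      cov <- pgxpanel:::simulate_cnv_coverage(spec, model, "s")
      sc <- classify_structure(normalize_to_control(cov, ctrl, model))
      expect_equal(sc$events, unname(archetype_events[arch]),
                   info = paste(arch, seed))
    }
  }
})

test_that("plot-data export is consistent with normalization output", {
  ctrl <- simulate_control_coverage(model)
  spec <- sim_spec(seed = 3, cnv_archetype = "duplication")
  cov <- pgxpanel:::simulate_cnv_coverage(spec, model, "s")
  np <- normalize_to_control(cov, ctrl, model)
  pool_np <- normalize_to_control(ctrl, ctrl, model)

  solo <- export_plot_data(np, list(), ctrl, model)
  expect_setequal(unique(solo$series), c("sample", "control"))

  tab <- export_plot_data(np, list(pool_np, pool_np, pool_np), ctrl,
                          model)
  expect_length(unique(tab$series), 5L)
  s <- tab[tab$series == "sample", ]
  ord_np <- order(np$raw$pos)
  expect_equal(s$ratio[order(s$pos)], np$raw$ratio[ord_np])
  expect_equal(s$depth[order(s$pos)], np$raw$sample_depth[ord_np])
  # positions ascend within each series
  for (id in unique(tab$series)) {
    pos <- tab$pos[tab$series == id]
    expect_true(all(diff(pos) > 0))
  }
})

test_that("paralog filtering never increases depth anywhere", {
  set.seed(13)
  reads <- data.frame(chrom = "chr22",
                      start = sample(seq(42520000L, 42552000L), 60L),
                      mapping_quality = sample(0:60, 60L, replace = TRUE))
  reads$end <- reads$start + 150L
  before <- depth_from_reads(reads, model)
  after <- depth_from_reads(filter_paralog_alignments(reads, model),
                            model)
  expect_true(all(after$depth <= before$depth))
})
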