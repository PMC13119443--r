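# ---------------------------------------------------------------------------
# CYP2D6 structural-variant detection from read depth.
#
# CYP2D6 sits in a cluster with the highly homologous CYP2D7 and CYP2D8P
# paralogs; mis-mapped paralog reads distort coverage, so alignments are
# filtered by region and mapping quality before depth is computed. Depth
# is then library-size scaled and divided by a fixed internal control
# profile; segment-mean ratios drive a +/-50% step copy-number logic.
# ---------------------------------------------------------------------------

#' Load the CYP2D6 gene model
#'
#' Reads the segment table (TSV, header `segment  chrom  start  end`)
#' describing CYP2D6 exons 1..9 (gene on the minus strand: exon 1 has
#' the highest genomic coordinate), the adjacent CYP2D7-derived
#' high-homology block upstream of the gene's 5' end, and the CYP2D7 /
#' CYP2D8P paralog regions to be masked. Coordinates are configuration
#' (GRCh37 in the packaged model), not code.
#'
#' @param path Path to the model TSV; defaults to the packaged GRCh37
#'   model.
#' @return An object of class `gene_model_2d6`: list with `exons`
#'   (data.frame, rows exon1..exon9), `upstream` (one-row data.frame)
#'   and `paralogs` (data.frame).
#' @export
load_gene_model_2d6 <- function(path = cyp2d6_model_path()) {
  rows <- read_tsv_strict(path, c("segment", "chrom", "start", "end"))
  rows$start <- parse_int_col(rows$start, path, rows$.line, "start")
  rows$end <- parse_int_col(rows$end, path, rows$.line, "end")
  rows$.line <- NULL
  exons <- rows[grepl("^exon[1-9]$", rows$segment), , drop = FALSE]
  exons <- exons[order(as.integer(sub("exon", "", exons$segment))), ]
  if (nrow(exons) != 9L) {
    stop("gene model must define segments exon1..exon9", call. = FALSE)
  }
  upstream <- rows[rows$segment == "upstream_homolog", , drop = FALSE]
  if (nrow(upstream) != 1L) {
    stop("gene model must define one upstream_homolog segment",
         call. = FALSE)
  }
  paralogs <- rows[grepl("^paralog_", rows$segment), , drop = FALSE]
  # exons must not overlap; check in genomic order
  ord <- exons[order(exons$start), ]
  if (any(ord$start[-1L] <= ord$end[-nrow(ord)])) {
    stop("gene model exons overlap", call. = FALSE)
  }
  rownames(exons) <- NULL
  rownames(upstream) <- NULL
  rownames(paralogs) <- NULL
  structure(list(exons = exons, upstream = upstream, paralogs = paralogs),
            class = "gene_model_2d6")
}

#' Path to the packaged GRCh37 CYP2D6 gene model
#' @return File path inside the installed package.
#' @export
cyp2d6_model_path <- function() {
  system.file("extdata", "cyp2d6_model_grch37.tsv", package = "pgxpanel",
              mustWork = TRUE)
}

model_segments <- function(model) {
  seg <- rbind(model$exons, model$upstream)
  rownames(seg) <- NULL
  seg
}

# all (chrom, pos) covered by the model's analysis segments, in order
model_positions <- function(model) {
  seg <- model_segments(model)
  do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    data.frame(segment = seg$segment[i], chrom = seg$chrom[i],
               pos = seq.int(seg$start[i], seg$end[i]),
               stringsAsFactors = FALSE)
  }))
}

#' Copy-number classification bands
#'
#' Normalized-ratio intervals (left-closed, right-open) mapped to
#' per-segment copy counts, centered on the half-steps the depth signal
#' takes when one copy of a diploid locus is lost or gained: ~0.5 for a
#' heterozygous loss, ~1.0 for two copies, ~1.5 for a single extra copy.
#'
#' @param loss_band,diploid_band,gain_band Numeric length-2 intervals.
#' @return An object of class `cnv_thresholds`.
#' @export
cnv_thresholds <- function(loss_band = c(0.25, 0.75),
                           diploid_band = c(0.75, 1.25),
                           gain_band = c(1.25, 1.75)) {
  stopifnot(loss_band[2] == diploid_band[1], diploid_band[2] == gain_band[1])
  structure(list(loss_band = loss_band, diploid_band = diploid_band,
                 gain_band = gain_band), class = "cnv_thresholds")
}

# ---------------------------------------------------------------------------
# Alignment filtering and depth
# ---------------------------------------------------------------------------

#' Filter out paralog-derived alignments
#'
#' Removes reads whose alignment midpoint falls in a CYP2D7/CYP2D8P
#' paralog region, and reads below the mapping-quality floor; surviving
#' records are returned unchanged. This keeps mis-mapped homolog reads
#' out of the coverage profile.
#'
#' @param reads Data.frame with columns `chrom`, `start`, `end`,
#'   `mapping_quality` (half-open intervals not required; `start < end`).
#' @param model A `gene_model_2d6`.
#' @param min_mapq Minimum mapping quality kept (default 20).
#' @return The filtered data.frame.
#' @export
filter_paralog_alignments <- function(reads, model, min_mapq = 20L) {
  stopifnot(inherits(model, "gene_model_2d6"),
            all(c("chrom", "start", "end", "mapping_quality") %in%
                  names(reads)))
  if (nrow(reads) == 0L) return(reads)
  if (any(reads$start >= reads$end)) {
    stop("alignment records must satisfy start < end", call. = FALSE)
  }
  mid <- floor((reads$start + reads$end) / 2)
  in_paralog <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(model$paralogs))) {
    p <- model$paralogs[i, ]
    in_paralog <- in_paralog |
      (reads$chrom == p$chrom & mid >= p$start & mid <= p$end)
  }
  keep <- !in_paralog & reads$mapping_quality >= min_mapq
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pileup depth over the gene-model segments
#'
#' @param reads Filtered alignment records (`chrom`, `start`, `end`
#'   inclusive coordinates).
#' @param model A `gene_model_2d6`.
#' @param sample Sample identifier for the resulting profile.
#' @return A `coverage_profile` over all model segment positions
#'   (positions not touched by any read have depth 0).
#' @export
depth_from_reads <- function(reads, model, sample = "sample") {
  pos_tab <- model_positions(model)
  depth <- integer(nrow(pos_tab))
  if (nrow(reads)) {
    for (i in seq_len(nrow(reads))) {
      hit <- pos_tab$chrom == reads$chrom[i] &
        pos_tab$pos >= reads$start[i] & pos_tab$pos <= reads$end[i]
      depth[hit] <- depth[hit] + 1L
    }
  }
  coverage_profile(data.frame(chrom = pos_tab$chrom, pos = pos_tab$pos,
                              depth = depth, stringsAsFactors = FALSE),
                   sample)
}

# ---------------------------------------------------------------------------
# Normalization and classification
# ---------------------------------------------------------------------------

depth_lookup <- function(cov, chrom, pos) {
  idx <- match(paste(chrom, pos), paste(cov$chrom, cov$pos))
  d <- cov$depth[idx]
  d[is.na(d)] <- 0
  d
}

#' Normalize a sample depth profile against the internal control
#'
#' Each profile is first scaled by its own median depth over **all**
#' positions it covers (panel-wide library-size correction; because the
#' CYP2D6 footprint is a tiny fraction of the panel, the median is
#' robust to the very CNV events being detected), then the per-position
#' ratio sample/control is averaged within each model segment. Pass
#' full-panel coverage profiles, not profiles clipped to the gene
#' model, or the scaling step loses its anchor.
#'
#' @param sample_cov,control_cov `coverage_profile`s covering the model
#'   segments (the control plays the role of a fixed diploid reference
#'   sample sequenced in every run).
#' @param model A `gene_model_2d6`.
#' @return An object of class `normalized_profile_2d6`: list with
#'   `sample`, `segment_ratios` (named numeric over exon1..exon9 and
#'   `upstream_homolog`) and `raw` (per-position table of sample depth,
#'   control depth and normalized ratio).
#' @export
normalize_to_control <- function(sample_cov, control_cov, model) {
  stopifnot(inherits(sample_cov, "coverage_profile"),
            inherits(control_cov, "coverage_profile"),
            inherits(model, "gene_model_2d6"))
  pos_tab <- model_positions(model)
  s_depth <- depth_lookup(sample_cov, pos_tab$chrom, pos_tab$pos)
  c_depth <- depth_lookup(control_cov, pos_tab$chrom, pos_tab$pos)
  s_med <- stats::median(sample_cov$depth)
  c_med <- stats::median(control_cov$depth)
  if (s_med <= 0) stop("sample median depth is zero over the gene model",
                       call. = FALSE)
  if (c_med <= 0) stop("control median depth is zero over the gene model",
                       call. = FALSE)
  zero_ctrl <- tapply(c_depth, pos_tab$segment, function(d) all(d == 0))
  if (any(zero_ctrl)) {
    stop("control has zero depth across segment: ",
         names(zero_ctrl)[zero_ctrl][1L], call. = FALSE)
  }
  s_scaled <- s_depth / s_med
  c_scaled <- c_depth / c_med
  ratio <- ifelse(c_scaled > 0, s_scaled / c_scaled, NA_real_)
  seg_levels <- model_segments(model)$segment
  seg_ratios <- vapply(seg_levels, function(sg) {
    mean(ratio[pos_tab$segment == sg], na.rm = TRUE)
  }, numeric(1))
  raw <- data.frame(segment = pos_tab$segment, chrom = pos_tab$chrom,
                    pos = pos_tab$pos, sample_depth = s_depth,
                    control_depth = c_depth, ratio = ratio,
                    stringsAsFactors = FALSE)
  structure(list(sample = attr(sample_cov, "sample"),
                 segment_ratios = seg_ratios, raw = raw),
            class = "normalized_profile_2d6")
}

band_copies <- function(r, t) {
  if (is.na(r)) return(NA_integer_)
  if (r >= t$loss_band[1] && r < t$loss_band[2]) return(1L)
  if (r >= t$diploid_band[1] && r < t$diploid_band[2]) return(2L)
  if (r >= t$gain_band[1] && r < t$gain_band[2]) return(3L)
  NA_integer_
}

#' Classify CYP2D6 structure from a normalized profile
#'
#' Per-segment copies come from band lookup (loss -> 1, diploid -> 2,
#' gain -> 3). Pattern rules, in priority order: all exons diploid ->
#' no event (2 copies); all exons in the loss band -> heterozygous
#' whole-gene deletion (1 copy); all exons in the gain band -> gene
#' duplication (3 copies); exon 1 plus the upstream homolog block gained
#' with exons 2-9 diploid -> CYP2D6*68-style hybrid tandem (2 intact
#' copies plus the hybrid segment); exons 2-9 lost with the upstream
#' block gained -> heterozygous deletion co-occurring with a hybrid
#' tandem (1 intact copy). Anything else, including ratios outside all
#' bands, is reported `unclassified` with per-segment states intact.
#'
#' @param np A `normalized_profile_2d6`.
#' @param thresholds A [cnv_thresholds()].
#' @return An object of class `cyp2d6_structure_call`: list with
#'   `copy_number`, `events` (character vector), `per_segment_state`
#'   (named integer, NA where out of band) and `classified` (logical).
#' @export
classify_structure <- function(np, thresholds = cnv_thresholds()) {
  stopifnot(inherits(np, "normalized_profile_2d6"))
  r <- np$segment_ratios
  state <- vapply(r, band_copies, integer(1), t = thresholds)
  exon_names <- paste0("exon", 1:9)
  ex <- state[exon_names]
  up <- state[["upstream_homolog"]]
  call <- NULL
  if (!anyNA(ex) && !is.na(up)) {
    if (all(ex == 2L) && up == 2L) {
      call <- list(copy_number = 2L, events = "none")
    } else if (all(ex == 1L)) {
      call <- list(copy_number = 1L, events = "deletion_het")
    } else if (all(ex == 3L)) {
      call <- list(copy_number = 3L, events = "duplication")
    } else if (ex[["exon1"]] == 3L && up == 3L &&
               all(ex[paste0("exon", 2:9)] == 2L)) {
      call <- list(copy_number = 2L, events = "hybrid_68_tandem")
    } else if (all(ex[paste0("exon", 2:9)] == 1L) && up == 3L) {
      call <- list(copy_number = 1L, events = "deletion_plus_hybrid")
    }
  }
  if (is.null(call)) {
    call <- list(copy_number = NA_integer_, events = "unclassified")
  }
  structure(list(copy_number = call$copy_number, events = call$events,
                 per_segment_state = state,
                 classified = !identical(call$events, "unclassified")),
            class = "cyp2d6_structure_call")
}

#' @export
print.cyp2d6_structure_call <- function(x, ...) {
  cat(sprintf("<cyp2d6_structure_call> copies=%s events=%s\n",
              ifelse(is.na(x$copy_number), "NA", x$copy_number),
              paste(x$events, collapse = "+")))
  invisible(x)
}

#' Export long-format plot data for the CYP2D6 coverage view
#'
#' One row per (position, series): the sample under analysis, each pool
#' sample, and the internal control, carrying raw depth and normalized
#' ratio (the control's ratio is 1 by construction). Positions are
#' ordered by genomic coordinate so any plotting front end can draw the
#' standard depth/ratio panels directly.
#'
#' @param np A `normalized_profile_2d6` for the sample under analysis.
#' @param pool List of `normalized_profile_2d6` for the other samples in
#'   the sequencing pool (may be empty).
#' @param control_cov The control `coverage_profile`.
#' @param model A `gene_model_2d6`.
#' @return Data.frame with columns `series`, `segment`, `chrom`, `pos`,
#'   `depth`, `ratio`.
#' @export
export_plot_data <- function(np, pool = list(), control_cov, model) {
  stopifnot(inherits(np, "normalized_profile_2d6"))
  pos_tab <- model_positions(model)
  one_series <- function(id, depth, ratio) {
    data.frame(series = id, segment = pos_tab$segment,
               chrom = pos_tab$chrom, pos = pos_tab$pos, depth = depth,
               ratio = ratio, stringsAsFactors = FALSE)
  }
  out <- list(one_series("sample", np$raw$sample_depth, np$raw$ratio))
  for (i in seq_along(pool)) {
    out[[length(out) + 1L]] <- one_series(paste0("pool_", i),
                                          pool[[i]]$raw$sample_depth,
                                          pool[[i]]$raw$ratio)
  }
  c_depth <- depth_lookup(control_cov, pos_tab$chrom, pos_tab$pos)
  out[[length(out) + 1L]] <- one_series("control", c_depth,
                                        rep(1, nrow(pos_tab)))
  res <- do.call(rbind, out)
  res <- res[order(res$series != "sample", res$series, res$chrom, res$pos), ]
  rownames(res) <- NULL
  res
}
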