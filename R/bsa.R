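# Bulked segregant analysis (QTL-seq) scan: informative-SNP prioritization,
# per-pool SNP index, sliding-window delta(SNP index), SNP-density
# transformed delta, candidate regions, marker overlap and candidate genes.

#' Prioritize informative SNPs for a BSA cross
#'
#' Keeps sites that are homozygous (for either allele) in exactly one parent
#' and heterozygous in the other, with both pool depths at or above
#' `min_pool_depth` and neither parent genotype missing; computes the
#' per-pool SNP index at each kept site. Counts of each rejection reason are
#' stored in the `rejections` attribute.
#'
#' @param sites Site table from [read_vcf_biallelic()] (or
#'   [simulate_bsa_cross()]`$sites`).
#' @param parent1,parent2 Parent sample names in `sites`.
#' @param pool_early,pool_late Pool sample names in `sites`.
#' @param min_pool_depth Minimum allele-depth sum per pool (default 6, the
#'   population SNP-filter depth cutoff).
#' @return `data.frame` of informative sites with columns `chrom`, `pos`,
#'   `ref`, `alt`, `parent1_gt`, `parent2_gt`, `hom_parent_gt`, per-pool
#'   depths (`early_ref`, `early_alt`, `late_ref`, `late_alt`) and
#'   `index_early`, `index_late` (`NA` when the pool depth is zero).
#' @export
prioritize_informative_snps <- function(sites, parent1, parent2,
                                        pool_early, pool_late,
                                        min_pool_depth = 6L) {
  g1 <- sites[[paste0("gt.", parent1)]]
  g2 <- sites[[paste0("gt.", parent2)]]
  if (is.null(g1) || is.null(g2)) stop("parent sample(s) not present in site table")
  er <- sites[[paste0("ad_ref.", pool_early)]]
  ea <- sites[[paste0("ad_alt.", pool_early)]]
  lr <- sites[[paste0("ad_ref.", pool_late)]]
  la <- sites[[paste0("ad_alt.", pool_late)]]
  if (is.null(er) || is.null(lr)) stop("pool sample(s) not present in site table")

  hom <- c("hom_ref", "hom_alt")
  missing_parent <- g1 == "missing" | g2 == "missing"
  informative <- (g1 %in% hom & g2 == "het") | (g2 %in% hom & g1 == "het")
  ed <- er + ea; ld <- lr + la
  depth_ok <- !is.na(ed) & !is.na(ld) & ed >= min_pool_depth & ld >= min_pool_depth
  keep <- informative & !missing_parent & depth_ok
  rej <- c(missing_parent = sum(missing_parent),
           not_informative = sum(!informative & !missing_parent),
           low_pool_depth = sum(informative & !missing_parent & !depth_ok))

  hom_gt <- ifelse(g1 %in% hom, g1, g2)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    ref = sites$ref, alt = sites$alt,
                    parent1_gt = g1, parent2_gt = g2, hom_parent_gt = hom_gt,
                    early_ref = er, early_alt = ea,
                    late_ref = lr, late_alt = la,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$index_early <- snp_index(out$early_ref, out$early_alt, out$hom_parent_gt)
  out$index_late <- snp_index(out$late_ref, out$late_alt, out$hom_parent_gt)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rej
  out
}

#' Pool SNP index at an informative site
#'
#' The SNP index is the fraction of pool reads carrying the allele *not*
#' carried by the homozygous parent (the homozygous parent's genotype is the
#' reference for polarity): with a hom-ref parent it is
#' `alt / (ref + alt)`, with a hom-alt parent `ref / (ref + alt)`.
#'
#' @param ref_depth,alt_depth Pool allele depths (vectors).
#' @param hom_parent_gt `"hom_ref"` or `"hom_alt"` per site.
#' @return SNP index in `[0, 1]`; `NA` at zero total depth.
#' @export
snp_index <- function(ref_depth, alt_depth, hom_parent_gt) {
  tot <- ref_depth + alt_depth
  idx <- ifelse(hom_parent_gt == "hom_ref", alt_depth, ref_depth) / tot
  idx[!is.na(tot) & tot == 0L] <- NA_real_
  idx
}

#' Sliding windows over a chromosome
#'
#' Windows start at `1 + k * step_size` for `k = 0, 1, ...` while the start
#' lies within the chromosome; windows overhanging the end are truncated.
#' A window larger than the chromosome yields a single chromosome-spanning
#' window.
#'
#' @param chrom_length Chromosome length, bp.
#' @param window_size Window size, bp (default 1 Mb).
#' @param step_size Step, bp (default 10 kb); must not exceed `window_size`.
#' @return `data.frame` with 1-based inclusive `start`, `end`.
#' @export
sliding_windows <- function(chrom_length, window_size = 1e6, step_size = 1e4) {
  stopifnot(chrom_length >= 1, window_size >= 1, step_size >= 1)
  if (step_size > window_size) stop("step_size exceeds window_size")
  if (window_size > chrom_length)
    return(data.frame(start = 1, end = chrom_length))
  starts <- seq(1, chrom_length, by = step_size)
  data.frame(start = starts, end = pmin(starts + window_size - 1, chrom_length))
}

#' Per-window SNP-index statistics for one chromosome
#'
#' For each window: the arithmetic mean of defined SNP indices per pool,
#' `delta = mean_index_late - mean_index_early`, the SNP density normalized
#' by the chromosome-wise maximum window count, and
#' `transformed_delta = delta * norm_density`. Empty windows report zero
#' delta and transformed delta with `empty = TRUE`, preserving genome-wide
#' window coordinates.
#'
#' @param pool_sites Informative-site table from
#'   [prioritize_informative_snps()], one chromosome, sorted by position.
#' @param windows Window table from [sliding_windows()].
#' @param chrom Chromosome name stamped on the output (default from sites).
#' @return `data.frame` with `chrom`, `start`, `end`, `n_snps`,
#'   `mean_index_early`, `mean_index_late`, `delta`, `norm_density`,
#'   `transformed_delta`, `empty`.
#' @export
window_statistics <- function(pool_sites, windows, chrom = NULL) {
  if (is.null(chrom))
    chrom <- if (nrow(pool_sites)) pool_sites$chrom[1L] else NA_character_
  if (nrow(pool_sites) && length(unique(pool_sites$chrom)) > 1L)
    stop("window_statistics expects sites from a single chromosome")
  pos <- pool_sites$pos
  if (is.unsorted(pos)) {
    o <- order(pos)
    pool_sites <- pool_sites[o, , drop = FALSE]
    pos <- pool_sites$pos
  }
  ie <- pool_sites$index_early; il <- pool_sites$index_late
  # prefix sums for O(log n) per-window means
  cs_e <- cumsum(ifelse(is.na(ie), 0, ie)); cn_e <- cumsum(!is.na(ie))
  cs_l <- cumsum(ifelse(is.na(il), 0, il)); cn_l <- cumsum(!is.na(il))
  i0 <- findInterval(windows$start - 1, pos)  # last site before window
  i1 <- findInterval(windows$end, pos)        # last site inside window
  rng <- function(cs, a, b) ifelse(b > a, cs[pmax(b, 1L)] - ifelse(a > 0, cs[pmax(a, 1L)], 0), 0)
  n_e <- rng(cn_e, i0, i1); s_e <- rng(cs_e, i0, i1)
  n_l <- rng(cn_l, i0, i1); s_l <- rng(cs_l, i0, i1)
  n_snps <- i1 - i0
  me <- ifelse(n_e > 0, s_e / n_e, NA_real_)
  ml <- ifelse(n_l > 0, s_l / n_l, NA_real_)
  delta <- ifelse(n_snps > 0 & !is.na(me) & !is.na(ml), ml - me, 0)
  max_n <- max(n_snps, 1L)
  norm_density <- n_snps / max_n
  data.frame(chrom = chrom, start = windows$start, end = windows$end,
             n_snps = n_snps, mean_index_early = me, mean_index_late = ml,
             delta = delta, norm_density = norm_density,
             transformed_delta = delta * norm_density,
             empty = n_snps == 0L, stringsAsFactors = FALSE)
}

#' Call candidate regions from a transformed-delta scan
#'
#' Thresholds `|transformed_delta|` at the given quantile over non-empty
#' windows (or at a fixed absolute value) and merges selected windows that
#' overlap or are adjacent into regions.
#'
#' @param window_stats Output of [window_statistics()] (one or more
#'   chromosomes row-bound).
#' @param quantile_threshold Quantile of `|transformed_delta|` defining the
#'   calling threshold (default 0.995).
#' @param abs_threshold Optional fixed absolute threshold overriding the
#'   quantile rule.
#' @return `data.frame` of class `"candidate_regions"` with `chrom`,
#'   `start`, `end`, `peak_abs_transformed_delta`, `n_windows_merged`;
#'   attribute `threshold`.
#' @export
call_candidate_regions <- function(window_stats, quantile_threshold = 0.995,
                                   abs_threshold = NULL) {
  ws <- window_stats[!window_stats$empty, , drop = FALSE]
  if (nrow(ws) == 0L) stop("all windows are empty; nothing to call")
  td <- abs(ws$transformed_delta)
  thr <- if (is.null(abs_threshold)) unname(quantile(td, quantile_threshold))
         else abs_threshold
  sel <- ws[td >= thr, , drop = FALSE]
  regions <- list()
  for (ch in unique(sel$chrom)) {
    w <- sel[sel$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    i <- 1L
    while (i <= nrow(w)) {
      s <- w$start[i]; e <- w$end[i]; pk <- abs(w$transformed_delta[i]); nm <- 1L
      j <- i + 1L
      while (j <= nrow(w) && w$start[j] <= e + 1) {
        e <- max(e, w$end[j])
        pk <- max(pk, abs(w$transformed_delta[j]))
        nm <- nm + 1L
        j <- j + 1L
      }
      regions[[length(regions) + 1L]] <-
        data.frame(chrom = ch, start = s, end = e,
                   peak_abs_transformed_delta = pk, n_windows_merged = nm,
                   stringsAsFactors = FALSE)
      i <- j
    }
  }
  out <- if (length(regions)) do.call(rbind, regions)
         else data.frame(chrom = character(), start = numeric(), end = numeric(),
                         peak_abs_transformed_delta = numeric(),
                         n_windows_merged = integer())
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' Test candidate regions for overlap with a QTL marker
#'
#' A region overlaps the marker iff it is on the same chromosome and
#' `start <= marker_pos <= end` (closed interval).
#'
#' @param regions Region table (`chrom`, `start`, `end`).
#' @param marker_chrom,marker_pos Marker coordinates (1-based).
#' @return `data.frame` report: the regions plus `length_mb` (interval
#'   length in Mb, 2 decimals) and `overlaps_marker`.
#' @export
overlap_marker <- function(regions, marker_chrom, marker_pos) {
  hit <- regions$chrom == marker_chrom &
    regions$start <= marker_pos & marker_pos <= regions$end
  out <- as.data.frame(regions)
  out$length_mb <- round((regions$end - regions$start + 1) / 1e6, 2)
  out$overlaps_marker <- hit
  out
}

#' Expression-filtered candidate genes in a region
#'
#' Keeps gene models whose interval intersects the region and whose
#' expression exceeds `min_expression` in at least one of the five
#' flowering stages. Genes in the region but absent from the expression
#' matrix are excluded and counted in the `n_missing_expression` attribute.
#'
#' @param region Single region (list/row with `chrom`, `start`, `end`).
#' @param gene_models Gene table from [read_gff3_genes()].
#' @param expression Expression table from [read_expression_tsv()].
#' @param min_expression Expression threshold (default 0: "expressed at
#'   all").
#' @return Gene table (sorted by start) joined with stage expression.
#' @export
candidate_genes <- function(region, gene_models, expression,
                            min_expression = 0) {
  inreg <- gene_models$chrom == region$chrom &
    gene_models$start <= region$end & gene_models$end >= region$start
  g <- gene_models[inreg, , drop = FALSE]
  known <- g$gene_id %in% expression$gene_id
  n_missing <- sum(!known)
  g <- g[known, , drop = FALSE]
  e <- expression[match(g$gene_id, expression$gene_id), .EXPR_STAGES, drop = FALSE]
  expressed <- rowSums(as.matrix(e) > min_expression) > 0L
  out <- cbind(g[expressed, , drop = FALSE], e[expressed, , drop = FALSE])
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_expression") <- n_missing
  out
}

#' Full BSA scan over a simulated or real cross
#'
#' Orchestrates [prioritize_informative_snps()], [sliding_windows()],
#' [window_statistics()] per chromosome and [call_candidate_regions()].
#'
#' @param sites Site table from [read_vcf_biallelic()].
#' @param parent1,parent2,pool_early,pool_late Sample names.
#' @param chrom_lengths Named numeric vector of chromosome lengths; defaults
#'   to the maximum SNP position per chromosome.
#' @param window_size,step_size Window parameters (default 1 Mb / 10 kb).
#' @param quantile_threshold,abs_threshold Region-calling threshold, see
#'   [call_candidate_regions()].
#' @param min_pool_depth Pool depth cutoff for informative sites.
#' @return Object of class `"bsa_scan"`: list with `windows`, `regions`,
#'   `sites` (informative sites), `params`.
#' @export
bsa_scan <- function(sites, parent1 = "P1", parent2 = "P2",
                     pool_early = "pool_early", pool_late = "pool_late",
                     chrom_lengths = NULL, window_size = 1e6, step_size = 1e4,
                     quantile_threshold = 0.995, abs_threshold = NULL,
                     min_pool_depth = 6L) {
  inf <- prioritize_informative_snps(sites, parent1, parent2,
                                     pool_early, pool_late, min_pool_depth)
  if (nrow(inf) == 0L) stop("no informative SNPs after filtering")
  chroms <- unique(inf$chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(ch) max(inf$pos[inf$chrom == ch]), 0)
  ws <- do.call(rbind, lapply(chroms, function(ch) {
    win <- sliding_windows(chrom_lengths[[ch]], window_size, step_size)
    window_statistics(inf[inf$chrom == ch, , drop = FALSE], win, chrom = ch)
  }))
  regions <- call_candidate_regions(ws, quantile_threshold, abs_threshold)
  out <- list(windows = ws, regions = regions, sites = inf,
              params = list(window_size = window_size, step_size = step_size,
                            quantile_threshold = quantile_threshold,
                            abs_threshold = abs_threshold,
                            min_pool_depth = min_pool_depth,
                            rejections = attr(inf, "rejections")))
  class(out) <- "bsa_scan"
  out
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("BSA scan:", nrow(x$sites), "informative SNPs,",
      nrow(x$windows), "windows,", nrow(x$regions), "candidate region(s)\n")
  cat(sprintf("threshold |transformed delta| >= %.4g\n",
              attr(x$regions, "threshold")))
  if (nrow(x$regions)) print.data.frame(as.data.frame(x$regions), digits = 4)
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  rej <- object$params$rejections
  cat("Informative-site rejections:",
      paste(names(rej), rej, sep = "=", collapse = ", "), "\n")
  print(object)
  invisible(object)
}

#' @export
plot.bsa_scan <- function(x, chrom = NULL, ...) {
  ws <- x$windows
  if (!is.null(chrom)) ws <- ws[ws$chrom == chrom, , drop = FALSE]
  mid <- (ws$start + ws$end) / 2e6
  plot(mid, ws$transformed_delta, type = "l",
       xlab = "Position (Mb)", ylab = "transformed delta(SNP index)", ...)
  abline(h = c(-1, 1) * attr(x$regions, "threshold"), lty = 2)
  invisible(x)
}
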