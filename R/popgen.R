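# Population-scale SNP filters and windowed nucleotide diversity (pi),
# Hudson FST and linkage-disequilibrium r^2 scans.

.FILTER_PRESETS <- list(
  "diploid-mixed" = list(min_depth = 6, min_rms_mq = 20, min_maf = 0.01,
                         max_missing = 0.2),
  "autotetraploid" = list(min_depth = 15, min_rms_mq = 20, min_maf = 0.05,
                          max_missing = 0.0)
)

#' Dosage matrix from a site table
#'
#' @param sites Site table from [read_vcf_biallelic()].
#' @param samples Sample names (default: the `samples` attribute).
#' @return Integer matrix samples x sites of alternate-allele dosages
#'   (`0, 1, 2`, `NA` for missing); column names `chrom_pos`, attribute
#'   `positions` (`data.frame` of `chrom`, `pos`).
#' @export
genotype_matrix <- function(sites, samples = attr(sites, "samples")) {
  stopifnot(!is.null(samples))
  code <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  m <- vapply(samples, function(s) {
    g <- sites[[paste0("gt.", s)]]
    unname(code[g])
  }, integer(nrow(sites)))
  m <- matrix(t(m), nrow = length(samples),
              dimnames = list(samples,
                              if (nrow(sites)) paste0(sites$chrom, "_", sites$pos)))
  attr(m, "positions") <- data.frame(chrom = sites$chrom, pos = sites$pos,
                                     stringsAsFactors = FALSE)
  m
}

#' Population-scale SNP quality filters
#'
#' Applies the resequencing-panel site filters: minimum coverage depth,
#' minimum RMS mapping quality, minimum minor-allele frequency and maximum
#' missing-genotype fraction. Presets: `"diploid-mixed"` (depth >= 6,
#' MQ >= 20, maf >= 0.01, missing <= 0.2) and `"autotetraploid"`
#' (depth >= 15, MQ >= 20, maf >= 0.05, no missing).
#'
#' @param sites Site table from [read_vcf_biallelic()].
#' @param preset `"diploid-mixed"` (default) or `"autotetraploid"`; any
#'   explicitly supplied cutoff overrides the preset.
#' @param min_depth,min_rms_mq,min_maf,max_missing Explicit cutoffs.
#' @param depth_source `"ad"` (default: per-site mean over samples of the
#'   allele-depth sum) or `"dp"` (INFO `DP`).
#' @return Filtered site table; attribute `rejections` counts sites failing
#'   each criterion (a site may fail several).
#' @export
apply_population_filters <- function(sites, preset = "diploid-mixed",
                                     min_depth = NULL, min_rms_mq = NULL,
                                     min_maf = NULL, max_missing = NULL,
                                     depth_source = c("ad", "dp")) {
  depth_source <- match.arg(depth_source)
  if (!preset %in% names(.FILTER_PRESETS))
    stop("unknown preset '", preset, "'")
  p <- .FILTER_PRESETS[[preset]]
  if (is.null(min_depth)) min_depth <- p$min_depth
  if (is.null(min_rms_mq)) min_rms_mq <- p$min_rms_mq
  if (is.null(min_maf)) min_maf <- p$min_maf
  if (is.null(max_missing)) max_missing <- p$max_missing

  samples <- attr(sites, "samples")
  geno <- genotype_matrix(sites, samples)
  n_missing <- colSums(is.na(geno))
  miss_frac <- n_missing / length(samples)
  n_called <- 2 * (length(samples) - n_missing)
  alt_count <- colSums(geno, na.rm = TRUE)
  af <- ifelse(n_called > 0, alt_count / n_called, NA)
  maf <- pmin(af, 1 - af)

  depth <- if (depth_source == "dp") {
    sites$info_dp
  } else {
    ad <- vapply(samples, function(s)
      sites[[paste0("ad_ref.", s)]] + sites[[paste0("ad_alt.", s)]],
      numeric(nrow(sites)))
    if (nrow(sites) == 1L) ad <- matrix(ad, nrow = 1L)
    rowMeans(ad, na.rm = TRUE)
  }

  fail_depth <- is.na(depth) | depth < min_depth
  fail_mq <- is.na(sites$rms_mq) | sites$rms_mq < min_rms_mq
  fail_maf <- is.na(maf) | maf < min_maf
  fail_miss <- miss_frac > max_missing
  keep <- !(fail_depth | fail_mq | fail_maf | fail_miss)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  attr(out, "rejections") <- c(depth = sum(fail_depth), rms_mq = sum(fail_mq),
                               maf = sum(fail_maf), missing = sum(fail_miss))
  out
}

# per-site pi: average pairwise difference = 2 * n_alt * n_ref / (n (n-1))
# over n sampled alleles (from dosages, missing excluded)
.pi_per_site <- function(geno) {
  n_missing <- colSums(is.na(geno))
  n <- 2 * (nrow(geno) - n_missing)
  n_alt <- colSums(geno, na.rm = TRUE)
  n_ref <- n - n_alt
  ifelse(n >= 2, 2 * n_alt * n_ref / (n * (n - 1)), NA_real_)
}

#' Windowed nucleotide diversity
#'
#' Per-site pi is the average pairwise difference among sampled alleles,
#' `2 n_alt n_ref / (n (n - 1))`; the window value is the sum over SNP sites
#' divided by the window length in bp (invariant sites assumed
#' monomorphic).
#'
#' @param geno Dosage matrix from [genotype_matrix()] (one chromosome).
#' @param windows Window table from [sliding_windows()].
#' @param positions Site positions (default from the matrix attribute).
#' @return `data.frame` with `start`, `end`, `n_snps`, `pi_per_site`
#'   (`NA`-flagged for windows with no sites the value is still computed as
#'   0 contribution; `empty` marks them).
#' @export
nucleotide_diversity <- function(geno, windows,
                                 positions = attr(geno, "positions")$pos) {
  ps <- .pi_per_site(geno)
  o <- order(positions)
  positions <- positions[o]; ps <- ps[o]
  cs <- cumsum(ifelse(is.na(ps), 0, ps))
  i0 <- findInterval(windows$start - 1, positions)
  i1 <- findInterval(windows$end, positions)
  tot <- ifelse(i1 > i0, cs[pmax(i1, 1L)] - ifelse(i0 > 0, cs[pmax(i0, 1L)], 0), 0)
  n_snps <- i1 - i0
  data.frame(start = windows$start, end = windows$end, n_snps = n_snps,
             pi_per_site = tot / (windows$end - windows$start + 1),
             empty = n_snps == 0L)
}

#' Windowed Hudson FST
#'
#' Per site, the Hudson estimator (Bhatia et al. form): numerator
#' `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)`,
#' denominator `p1 (1 - p2) + p2 (1 - p1)`, with `p` the alternate-allele
#' frequency and `n` the sampled-allele count. The window value is the
#' ratio of sums (ratio of averages). Sites with fewer than 2 sampled
#' alleles in either population are excluded.
#'
#' @param geno Dosage matrix (one chromosome).
#' @param pops Named character vector (sample -> population); exactly two
#'   populations.
#' @param windows Window table; if `NULL`, a single genome-wide value is
#'   returned.
#' @param positions Site positions.
#' @return With windows: `data.frame` of `start`, `end`, `n_snps`, `fst`
#'   (`NA` where the denominator sum is zero). Without: a single numeric.
#' @export
hudson_fst <- function(geno, pops, windows = NULL,
                       positions = attr(geno, "positions")$pos) {
  pops <- pops[rownames(geno)]
  pn <- unique(pops)
  if (length(pn) != 2L) stop("exactly two populations required")
  g1 <- geno[pops == pn[1L], , drop = FALSE]
  g2 <- geno[pops == pn[2L], , drop = FALSE]
  comp <- function(g) {
    n <- 2 * colSums(!is.na(g))
    p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / n, NA)
    list(n = n, p = p)
  }
  a <- comp(g1); b <- comp(g2)
  ok <- a$n >= 2 & b$n >= 2
  num <- (a$p - b$p)^2 - a$p * (1 - a$p) / (a$n - 1) - b$p * (1 - b$p) / (b$n - 1)
  den <- a$p * (1 - b$p) + b$p * (1 - a$p)
  num[!ok] <- NA; den[!ok] <- NA
  if (is.null(windows)) {
    s_den <- sum(den, na.rm = TRUE)
    if (s_den == 0) return(NA_real_)
    return(sum(num, na.rm = TRUE) / s_den)
  }
  o <- order(positions)
  positions <- positions[o]; num <- num[o]; den <- den[o]; ok <- ok[o]
  cnum <- cumsum(ifelse(is.na(num), 0, num))
  cden <- cumsum(ifelse(is.na(den), 0, den))
  cok <- cumsum(ok)
  i0 <- findInterval(windows$start - 1, positions)
  i1 <- findInterval(windows$end, positions)
  rng <- function(cs, a, b) ifelse(b > a, cs[pmax(b, 1L)] - ifelse(a > 0, cs[pmax(a, 1L)], 0), 0)
  s_num <- rng(cnum, i0, i1); s_den <- rng(cden, i0, i1)
  data.frame(start = windows$start, end = windows$end,
             n_snps = rng(cok, i0, i1),
             fst = ifelse(s_den > 0, s_num / s_den, NA_real_))
}

#' Pairwise LD r-squared by distance bin
#'
#' Composite LD on genotype dosages: for each SNP pair within
#' `max_pair_distance`, `r^2` is the squared Pearson correlation of dosage
#' vectors over samples non-missing at both sites. Pairs involving a
#' monomorphic site are skipped. Pairs are binned by bp distance.
#'
#' @param geno Dosage matrix (one chromosome).
#' @param max_pair_distance Maximum pair separation, bp.
#' @param distance_bins Number of equal-width distance bins (default 10) or
#'   an explicit vector of bin breaks starting at 0.
#' @param positions Site positions.
#' @return `data.frame` with `bin_start`, `bin_end`, `n_pairs`, `mean_r2`.
#' @export
ld_r2 <- function(geno, max_pair_distance, distance_bins = 10L,
                  positions = attr(geno, "positions")$pos) {
  o <- order(positions)
  positions <- positions[o]
  geno <- geno[, o, drop = FALSE]
  breaks <- if (length(distance_bins) > 1L) distance_bins
            else seq(0, max_pair_distance, length.out = distance_bins + 1L)
  nb <- length(breaks) - 1L
  sum_r2 <- numeric(nb); n_pairs <- integer(nb)
  v <- apply(geno, 2L, var, na.rm = TRUE)
  m <- ncol(geno)
  for (i in seq_len(max(m - 1L, 0L))) {
    if (is.na(v[i]) || v[i] == 0) next
    j <- i + 1L
    while (j <= m && positions[j] - positions[i] <= max_pair_distance) {
      if (!is.na(v[j]) && v[j] > 0) {
        r <- suppressWarnings(cor(geno[, i], geno[, j],
                                  use = "pairwise.complete.obs"))
        if (!is.na(r)) {
          d <- positions[j] - positions[i]
          bin <- min(max(findInterval(d, breaks, left.open = TRUE), 1L), nb)
          sum_r2[bin] <- sum_r2[bin] + r^2
          n_pairs[bin] <- n_pairs[bin] + 1L
        }
      }
      j <- j + 1L
    }
  }
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1L],
             n_pairs = n_pairs,
             mean_r2 = ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_))
}

#' Windowed pi / FST scan over a two-population panel
#'
#' Convenience wrapper combining per-population [nucleotide_diversity()]
#' and [hudson_fst()] on shared windows.
#'
#' @param geno Dosage matrix (one chromosome).
#' @param pops Named character vector (sample -> population).
#' @param chrom_length Chromosome length (default max position).
#' @param window_size,step_size Window parameters (default 100 kb,
#'   non-overlapping).
#' @return Object of class `"popgen_scan"`: `data.frame` with `start`,
#'   `end`, `n_snps`, per-population `pi`, and `fst`.
#' @export
popgen_scan <- function(geno, pops, chrom_length = NULL,
                        window_size = 1e5, step_size = window_size) {
  positions <- attr(geno, "positions")$pos
  if (is.null(chrom_length)) chrom_length <- max(positions)
  win <- sliding_windows(chrom_length, window_size, step_size)
  pn <- unique(pops[rownames(geno)])
  out <- data.frame(start = win$start, end = win$end)
  fst <- hudson_fst(geno, pops, win, positions)
  out$n_snps <- fst$n_snps
  for (p in pn) {
    sub <- geno[names(pops)[pops == p], , drop = FALSE]
    attr(sub, "positions") <- attr(geno, "positions")
    out[[paste0("pi_", p)]] <- nucleotide_diversity(sub, win, positions)$pi_per_site
  }
  out$fst <- fst$fst
  class(out) <- c("popgen_scan", "data.frame")
  out
}

#' @export
print.popgen_scan <- function(x, ...) {
  cat("Windowed popgen scan:", nrow(x), "windows\n")
  print.data.frame(head(as.data.frame(x), 10L), digits = 4, ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' @export
plot.popgen_scan <- function(x, ...) {
  mid <- (x$start + x$end) / 2e6
  plot(mid, x$fst, type = "l", xlab = "Position (Mb)", ylab = "Hudson FST", ...)
  invisible(x)
}
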