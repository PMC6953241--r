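# Population SNP filters and the windowed pi / FST / LD statistics.

panel_geno <- function(n_per_pop, n_snps, fst, seed) {
  p <- simulate_two_pop_panel(n_per_pop, n_snps, fst, seed = seed)
  g <- p$genotypes
  attr(g, "positions") <- p$positions
  list(g = g, pops = p$pops, truth = p$truth)
}

test_that("population filters apply the preset cutoffs site by site", {
  p <- withr::local_tempfile(fileext = ".vcf")
  # hand-built sites: (1) passes, (2) depth 5 < 6, (3) MQ 15 < 20,
  # (4) monomorphic -> maf 0, (5) all genotypes missing
  write_mini_vcf(p, c("a", "b", "c", "d"), c(
    "chr6\t10\t.\tA\tT\t50\t.\tMQ=40\tGT:AD\t0/0:6,0\t0/1:3,3\t0/1:4,4\t1/1:0,8",
    "chr6\t20\t.\tA\tT\t50\t.\tMQ=40\tGT:AD\t0/0:5,0\t0/1:3,2\t0/1:2,3\t1/1:0,5",
    "chr6\t30\t.\tA\tT\t50\t.\tMQ=15\tGT:AD\t0/0:6,0\t0/1:3,3\t0/1:4,4\t1/1:0,8",
    "chr6\t40\t.\tA\tT\t50\t.\tMQ=40\tGT:AD\t0/0:8,0\t0/0:8,0\t0/0:8,0\t0/0:8,0",
    "chr6\t50\t.\tA\tT\t50\t.\tMQ=40\tGT:AD\t./.:8,0\t./.:8,0\t./.:8,0\t./.:8,0"
  ))
  sites <- read_vcf_biallelic(p, c("a", "b", "c", "d"))
  kept <- apply_population_filters(sites, preset = "diploid-mixed")
  expect_equal(kept$pos, 10L)
  rej <- attr(kept, "rejections")
  expect_equal(unname(rej["depth"]), 1L)
  expect_equal(unname(rej["rms_mq"]), 1L)
  expect_true(rej["maf"] >= 2L)       # monomorphic and all-missing sites
  expect_equal(unname(rej["missing"]), 1L)
})

test_that("autotetraploid preset is stricter on depth, maf and missingness", {
  p <- withr::local_tempfile(fileext = ".vcf")
  # maf = 1/8 = 0.125 passes diploid (>=0.01) and tetraploid (>=0.05);
  # depth 10 passes diploid (>=6) but fails tetraploid (>=15)
  write_mini_vcf(p, c("a", "b", "c", "d"), c(
    "chr6\t10\t.\tA\tT\t50\t.\tMQ=40\tGT:AD\t0/0:10,0\t0/0:10,0\t0/0:10,0\t0/1:5,5",
    "chr6\t20\t.\tA\tT\t50\t.\tMQ=40\tGT:AD\t0/0:20,0\t0/0:20,0\t0/0:20,0\t0/1:10,10"
  ))
  sites <- read_vcf_biallelic(p, c("a", "b", "c", "d"))
  expect_equal(apply_population_filters(sites, "diploid-mixed")$pos, c(10L, 20L))
  expect_equal(apply_population_filters(sites, "autotetraploid")$pos, 20L)
  # explicit override beats the preset
  expect_equal(nrow(apply_population_filters(sites, "autotetraploid",
                                             min_depth = 5)), 2L)
})

test_that("per-site pi equals the average pairwise difference", {
  # alleles {A,A,T,T}: 2*2*2/(4*3) = 2/3, equal to brute-force enumeration
  geno <- matrix(c(0L, 2L), nrow = 2,
                 dimnames = list(c("s1", "s2"), "chr1_100"))
  attr(geno, "positions") <- data.frame(chrom = "chr1", pos = 100L)
  win <- data.frame(start = 100, end = 100)
  pis <- nucleotide_diversity(geno, win)
  expect_equal(pis$pi_per_site, 2 / 3)
  expect_equal(pis$pi_per_site, brute_force_pi(c(0, 0, 1, 1)))

  # monomorphic window
  geno2 <- matrix(c(0L, 0L), nrow = 2,
                  dimnames = list(c("s1", "s2"), "chr1_100"))
  attr(geno2, "positions") <- data.frame(chrom = "chr1", pos = 100L)
  expect_equal(nucleotide_diversity(geno2, win)$pi_per_site, 0)

  # doubling the window length halves pi per site
  w1 <- nucleotide_diversity(geno, data.frame(start = 1, end = 1000))
  w2 <- nucleotide_diversity(geno, data.frame(start = 1, end = 2000))
  expect_equal(w2$pi_per_site, w1$pi_per_site / 2)
})

test_that("pi matches brute-force pairwise enumeration on random sites", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(3:5, 1)   # <= 10 haplotypes
    g <- matrix(sample(0:2, n, TRUE), ncol = 1,
                dimnames = list(paste0("s", 1:n), "chr1_50"))
    attr(g, "positions") <- data.frame(chrom = "chr1", pos = 50L)
    alleles <- unlist(lapply(g[, 1], function(d) c(rep(1, d), rep(0, 2 - d))))
    got <- nucleotide_diversity(g, data.frame(start = 50, end = 50))$pi_per_site
    expect_equal(got, brute_force_pi(alleles))
  }
})

test_that("Hudson FST is 0 for identical populations and 1 at fixation", {
  pn <- panel_geno(40, 1000, 0, seed = 51)
  expect_lt(abs(hudson_fst(pn$g, pn$pops)), 0.02)

  # fixed difference
  g <- matrix(c(rep(2L, 4), rep(0L, 4)), ncol = 1,
              dimnames = list(paste0("s", 1:8), "chr1_10"))
  attr(g, "positions") <- data.frame(chrom = "chr1", pos = 10L)
  pops <- setNames(rep(c("p1", "p2"), each = 4), paste0("s", 1:8))
  expect_equal(hudson_fst(g, pops), 1)
})

test_that("windowed FST recovers the Balding-Nichols target and is monotone in F", {
  fhat <- vapply(c(0, 0.05, 0.1, 0.2), function(f) {
    pn <- panel_geno(50, 2000, f, seed = 60 + round(100 * f))
    hudson_fst(pn$g, pn$pops)
  }, 0)
  expect_true(all(diff(fhat) > 0))
  expect_lt(abs(fhat[4] - 0.2), 0.03)
})

test_that("LD r2 is 1 for duplicated sites and small for independent ones", {
  set.seed(33)
  n <- 100
  d1 <- sample(0:2, n, TRUE)
  g <- cbind(d1, d1, sample(0:2, n, TRUE, prob = c(.25, .5, .25)))
  dimnames(g) <- list(paste0("s", 1:n), c("chr1_100", "chr1_200", "chr1_5000"))
  attr(g, "positions") <- data.frame(chrom = "chr1", pos = c(100L, 200L, 5000L))
  ld <- ld_r2(g, max_pair_distance = 200, distance_bins = 1)
  expect_equal(ld$n_pairs, 1L)         # the 4900-bp pair is beyond range
  expect_equal(ld$mean_r2, 1)

  # independent sites: mean r2 near the 1/(n-1) sampling bias
  m <- 40
  gi <- matrix(sample(0:2, n * m, TRUE, prob = c(.25, .5, .25)), nrow = n,
               dimnames = list(paste0("s", 1:n), paste0("chr1_", 1:m * 10)))
  attr(gi, "positions") <- data.frame(chrom = "chr1", pos = 1:m * 10L)
  ldi <- ld_r2(gi, max_pair_distance = 1000, distance_bins = 1)
  expect_lt(ldi$mean_r2, 3 / n)
})

test_that("LD r2 is symmetric in site order and allele labels", {
  set.seed(12)
  n <- 60
  g <- matrix(sample(0:2, n * 4, TRUE), nrow = n,
              dimnames = list(paste0("s", 1:n), paste0("chr1_", c(10, 20, 30, 40))))
  attr(g, "positions") <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L))
  ld <- ld_r2(g, 100, 1)
  g_rev <- g[, 4:1]
  attr(g_rev, "positions") <- data.frame(chrom = "chr1", pos = c(40L, 30L, 20L, 10L))
  expect_equal(ld_r2(g_rev, 100, 1)$mean_r2, ld$mean_r2)
  g_fl <- 2L - g
  attr(g_fl, "positions") <- attr(g, "positions")
  expect_equal(ld_r2(g_fl, 100, 1)$mean_r2, ld$mean_r2)
})

test_that("popgen_scan stitches pi and FST over shared windows", {
  pn <- panel_geno(30, 1500, 0.1, seed = 71)
  sc <- popgen_scan(pn$g, pn$pops, window_size = 2e5)
  expect_true(all(c("pi_pop1", "pi_pop2", "fst", "n_snps") %in% names(sc)))
  expect_true(all(sc$pi_pop1 >= 0, na.rm = TRUE))
  expect_true(all(sc$fst[sc$n_snps > 50] > -0.05, na.rm = TRUE))
  # windowed values agree with direct per-window recomputation
  w3 <- sliding_windows(max(attr(pn$g, "positions")$pos), 2e5, 2e5)[3, ]
  in_w <- attr(pn$g, "positions")$pos >= w3$start &
    attr(pn$g, "positions")$pos <= w3$end
  sub <- pn$g[, in_w, drop = FALSE]
  attr(sub, "positions") <- attr(pn$g, "positions")[in_w, ]
  expect_equal(sc$fst[3], hudson_fst(sub, pn$pops))
})
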