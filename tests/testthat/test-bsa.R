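# Informative-SNP rules, SNP-index polarity, window statistics and
# candidate-region/gene calling.

make_pool_sites <- function(pos, ie, il, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
             parent1_gt = "hom_ref", parent2_gt = "het",
             hom_parent_gt = "hom_ref",
             early_ref = 10L, early_alt = 10L, late_ref = 10L, late_alt = 10L,
             index_early = ie, index_late = il, stringsAsFactors = FALSE)
}

test_that("informative-SNP prioritization follows the hom x het rule", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(p, c("P1", "P2", "E", "L"), c(
    "chr6\t100\t.\tA\tT\t50\t.\t.\tGT:AD\t0/0:20,0\t0/1:10,10\t0/1:12,8\t0/1:9,11",
    "chr6\t200\t.\tA\tT\t50\t.\t.\tGT:AD\t0/1:10,10\t0/1:10,10\t0/1:12,8\t0/1:9,11",
    "chr6\t300\t.\tA\tT\t50\t.\t.\tGT:AD\t0/0:20,0\t0/1:10,10\t0/1:2,1\t0/1:9,11",
    "chr6\t400\t.\tA\tT\t50\t.\t.\tGT:AD\t1/1:0,20\t0/1:10,10\t0/1:12,8\t0/1:9,11",
    "chr6\t500\t.\tA\tT\t50\t.\t.\tGT:AD\t./.\t0/1:10,10\t0/1:12,8\t0/1:9,11"
  ))
  sites <- read_vcf_biallelic(p, c("P1", "P2", "E", "L"))
  inf <- prioritize_informative_snps(sites, "P1", "P2", "E", "L",
                                     min_pool_depth = 6)
  expect_equal(inf$pos, c(100L, 400L))      # het x het, low depth, missing out
  rej <- attr(inf, "rejections")
  expect_equal(unname(rej["not_informative"]), 1L)
  expect_equal(unname(rej["low_pool_depth"]), 1L)
  expect_equal(unname(rej["missing_parent"]), 1L)
  # hom-alt parent flips the index polarity
  expect_equal(inf$hom_parent_gt, c("hom_ref", "hom_alt"))
  expect_equal(inf$index_early, c(8 / 20, 12 / 20))
})

test_that("snp_index is polarized by the homozygous parent's allele", {
  expect_equal(snp_index(15L, 15L, "hom_ref"), 0.5)
  expect_equal(snp_index(30L, 0L, "hom_ref"), 0)
  expect_equal(snp_index(12L, 28L, "hom_alt"), 0.3)
  expect_true(is.na(snp_index(0L, 0L, "hom_ref")))
})

test_that("sliding_windows enumerates, truncates and validates", {
  w <- sliding_windows(3000, 1000, 500)
  expect_equal(w$start, c(1, 501, 1001, 1501, 2001, 2501))
  expect_equal(w$end, c(1000, 1500, 2000, 2500, 3000, 3000))

  w1 <- sliding_windows(1000, 1000, 1000)
  expect_equal(nrow(w1), 1L)
  expect_equal(unlist(w1), c(start = 1, end = 1000))

  expect_error(sliding_windows(3000, 100, 500), "step")
  wbig <- sliding_windows(500, 1000, 10)
  expect_equal(nrow(wbig), 1L)
  expect_equal(wbig$end, 500)
})

test_that("window statistics compute means, delta and transformed delta", {
  ps <- make_pool_sites(c(100, 200), ie = c(0.2, 0.4), il = c(0.5, 0.7))
  ws <- window_statistics(ps, data.frame(start = 1, end = 1000))
  expect_equal(ws$mean_index_early, 0.3)
  expect_equal(ws$mean_index_late, 0.6)
  expect_equal(ws$delta, 0.3)
  expect_equal(ws$norm_density, 1)

  # transformed = delta * normalized density
  ps2 <- make_pool_sites(c(100, 200, 1100), ie = c(0, 0, 0.1),
                         il = c(0.4, 0.4, 0.1))
  ws2 <- window_statistics(ps2, data.frame(start = c(1, 1001),
                                           end = c(1000, 2000)))
  expect_equal(ws2$norm_density, c(1, 0.5))
  expect_equal(ws2$transformed_delta, ws2$delta * ws2$norm_density)

  # empty window reports zero with a flag
  ws3 <- window_statistics(ps, data.frame(start = c(1, 5001),
                                          end = c(1000, 6000)))
  expect_true(ws3$empty[2])
  expect_equal(ws3$delta[2], 0)
  expect_equal(ws3$transformed_delta[2], 0)
})

test_that("window means and deltas equal a naive recomputation", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    len <- sample(5000:50000, 1)
    ps <- make_pool_sites(sort(sample.int(len, n)),
                          ie = runif(n), il = runif(n))
    win <- sliding_windows(len, sample(1000:5000, 1), sample(200:1000, 1))
    got <- window_statistics(ps, win)
    want <- naive_window_stats(ps, win)
    expect_equal(got$n_snps, want$n_snps)
    expect_equal(got$mean_index_early, want$mean_index_early)
    expect_equal(got$delta, want$delta)
    expect_equal(got$transformed_delta, want$transformed_delta)
  }
})

test_that("swapping pool labels negates delta and transformed delta", {
  set.seed(7)
  n <- 100
  ps <- make_pool_sites(sort(sample.int(20000, n)), ie = runif(n), il = runif(n))
  win <- sliding_windows(20000, 2000, 500)
  ws <- window_statistics(ps, win)
  ps_sw <- ps
  ps_sw$index_early <- ps$index_late
  ps_sw$index_late <- ps$index_early
  ws_sw <- window_statistics(ps_sw, win)
  expect_equal(ws_sw$delta, -ws$delta)
  expect_equal(ws_sw$transformed_delta, -ws$transformed_delta)
})

test_that("transformed delta is invariant to uniform SNP-count scaling", {
  ps <- make_pool_sites(c(100, 200, 1100, 1200), ie = c(0, 0, 0.1, 0.3),
                        il = c(0.4, 0.4, 0.2, 0.4))
  win <- data.frame(start = c(1, 1001), end = c(1000, 2000))
  base <- window_statistics(ps, win)
  # triple every site (same indices): densities and deltas unchanged
  ps3 <- ps[rep(seq_len(nrow(ps)), each = 3), ]
  ps3$pos <- ps3$pos + rep(0:2, times = nrow(ps))
  tripled <- window_statistics(ps3, win)
  expect_equal(tripled$norm_density, base$norm_density)
  expect_equal(tripled$transformed_delta, base$transformed_delta)
})

test_that("candidate regions merge overlapping windows above threshold", {
  ws <- data.frame(chrom = "chr1",
                   start = c(1, 501, 1001, 5001),
                   end = c(1000, 1500, 2000, 6000),
                   n_snps = c(5, 5, 5, 5),
                   mean_index_early = 0.1, mean_index_late = 0.2,
                   delta = c(0.9, 0.85, 0.1, -0.95),
                   norm_density = 1,
                   transformed_delta = c(0.9, 0.85, 0.1, -0.95),
                   empty = FALSE)
  reg <- call_candidate_regions(ws, abs_threshold = 0.5)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start, c(1, 5001))
  expect_equal(reg$end, c(1500, 6000))
  expect_equal(reg$n_windows_merged, c(2L, 1L))
  expect_equal(reg$peak_abs_transformed_delta, c(0.9, 0.95))

  expect_error(call_candidate_regions(ws[ws$empty, , drop = FALSE]), "empty")
})

test_that("synthetic cross scan localizes the causal locus (seed 1)", {
  sim <- simulate_bsa_cross(1e7, 2000, 5e6, 30, 50, seed = 1)
  scan <- bsa_scan(sim$sites, chrom_lengths = c(chr1 = 1e7))
  top <- scan$regions[which.max(scan$regions$peak_abs_transformed_delta), ]
  expect_true(top$start <= 5e6 && 5e6 <= top$end)
  # late-minus-early delta is positive at the causal locus (alt -> late)
  ci <- which.min(abs((scan$windows$start + scan$windows$end) / 2 - 5e6))
  expect_gt(scan$windows$delta[ci], 0.3)
})

test_that("marker overlap uses closed intervals and reports Mb lengths", {
  regions <- data.frame(chrom = "chr6",
                        start = c(154344001, 157050001),
                        end = c(156231000, 159599000))
  rep1 <- overlap_marker(regions, "chr6", 157639000)
  expect_equal(rep1$length_mb, c(1.89, 2.55))
  expect_equal(rep1$overlaps_marker, c(FALSE, TRUE))

  expect_true(overlap_marker(data.frame(chrom = "c", start = 1, end = 100),
                             "c", 100)$overlaps_marker)
  expect_false(overlap_marker(data.frame(chrom = "c", start = 1, end = 100),
                              "d", 50)$overlaps_marker)
})

test_that("candidate genes are region-intersected and expression-filtered", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      chrom = "chr6",
                      start = c(150, 250, 380, 900),
                      end = c(220, 300, 420, 950),
                      strand = "+", stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = c("g1", "g2", "g4"),
                     prevernalization = c(0, 0, 1),
                     vernalization = c(0, 0, 0),
                     postvernalization = c(1.5, 0, 0),
                     preheading = c(2, 0, 0),
                     heading = c(0, 0, 0), stringsAsFactors = FALSE)
  region <- list(chrom = "chr6", start = 200, end = 400)
  got <- candidate_genes(region, genes, expr)
  # g1 straddles the boundary and is expressed -> kept; g2 inside but
  # never expressed -> removed; g3 lacks expression data -> excluded+logged;
  # g4 outside the region
  expect_equal(got$gene_id, "g1")
  expect_equal(attr(got, "n_missing_expression"), 1L)
})
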