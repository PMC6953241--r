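# Simulators that carry ground truth, so each analysis stage can be tested
# against the process it inverts. All are pure functions of (params, seed).

.BASES <- c("A", "C", "G", "T")

# Exact per-site Jukes-Cantor endpoint sampling: after time t at clock rate
# r (substitutions/site/year) a site equals its ancestor with probability
# 1/4 + 3/4 exp(-4 r t / 3), otherwise it is uniform over the other three
# bases. Operates on a character matrix of bases.
.jc_evolve <- function(mat, rate, time) {
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * rate * time / 3)
  change <- runif(length(mat)) > p_same
  n_ch <- sum(change)
  if (n_ch) {
    cur <- mat[change]
    # uniform over the three non-current bases
    shift <- sample.int(3L, n_ch, replace = TRUE)
    idx <- (match(cur, .BASES) - 1L + shift) %% 4L + 1L
    mat[change] <- .BASES[idx]
  }
  mat
}

#' Simulate diverged 5'/3' LTR pairs under a Jukes-Cantor clock
#'
#' At insertion the two long terminal repeats of a retrotransposon are
#' identical; afterwards each accumulates substitutions independently. This
#' simulator draws a random ancestral LTR per element and evolves it down
#' two branches of `true_age_years` under the Jukes-Cantor model at
#' `clock_rate` substitutions/site/year (exact per-site endpoint sampling
#' from the JC transition matrix).
#'
#' @param n_pairs Number of elements (pairs) to simulate.
#' @param seq_length LTR length in bp.
#' @param true_age_years True insertion age (branch duration), years.
#' @param clock_rate Substitutions per site per year.
#' @param seed Integer seed; same seed and parameters give identical output.
#' @param fasta,truth Optional output paths; when given, the paired FASTA
#'   and a truth TSV are written.
#' @return List with `sequences` (named character vector; ids
#'   `elementK_5p` / `elementK_3p`, interleaved) and `truth` (`data.frame`
#'   with `element_id`, `true_age_years`, `clock_rate`).
#' @export
simulate_ltr_pairs <- function(n_pairs, seq_length, true_age_years, clock_rate,
                               seed, fasta = NULL, truth = NULL) {
  stopifnot(n_pairs >= 1, seq_length >= 1, true_age_years >= 0, clock_rate > 0)
  set.seed(seed)
  anc <- matrix(sample(.BASES, n_pairs * seq_length, replace = TRUE),
                nrow = n_pairs)
  ltr5 <- .jc_evolve(anc, clock_rate, true_age_years)
  ltr3 <- .jc_evolve(anc, clock_rate, true_age_years)
  ids <- paste0("element", seq_len(n_pairs))
  seqs <- character(2L * n_pairs)
  seqs[seq(1L, by = 2L, length.out = n_pairs)] <- apply(ltr5, 1L, paste, collapse = "")
  seqs[seq(2L, by = 2L, length.out = n_pairs)] <- apply(ltr3, 1L, paste, collapse = "")
  names(seqs) <- as.vector(rbind(paste0(ids, "_5p"), paste0(ids, "_3p")))
  tr <- data.frame(element_id = ids, true_age_years = true_age_years,
                   clock_rate = clock_rate, stringsAsFactors = FALSE)
  if (!is.null(fasta)) write_fasta(seqs, fasta)
  if (!is.null(truth)) write.table(tr, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(sequences = seqs, truth = tr)
}

# --- codon machinery shared with the Ks module -------------------------------

.codon_tables <- function() {
  if (!is.null(.grasskit_env$codons)) return(invisible(NULL))
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  sense <- codons[aa != "*"]
  # per codon x position: which alternative bases are synonymous single steps
  syn_alt <- vector("list", length = 64L)
  names(syn_alt) <- codons
  for (cod in codons) {
    b <- strsplit(cod, "")[[1L]]
    per_pos <- vector("list", 3L)
    for (p in 1:3) {
      alts <- setdiff(.BASES, b[p])
      mut <- vapply(alts, function(x) {
        bb <- b; bb[p] <- x; paste(bb, collapse = "")
      }, "")
      per_pos[[p]] <- alts[gc[mut] == gc[cod] & gc[mut] != "*"]
    }
    syn_alt[[cod]] <- per_pos
  }
  # fractional synonymous sites per codon (changes to stops are
  # nonsynonymous; denominator of 3 changes per position kept)
  syn_sites <- vapply(codons, function(cod)
    sum(vapply(syn_alt[[cod]], length, 0L)) / 3, 0)
  .grasskit_env$codons <- codons
  .grasskit_env$aa <- setNames(aa, codons)
  .grasskit_env$sense_codons <- sense
  .grasskit_env$syn_alt <- syn_alt
  .grasskit_env$syn_sites <- syn_sites
  invisible(NULL)
}

#' Simulate duplicate CDS pairs with a known synonymous distance
#'
#' Generates stop-free coding sequences and produces a diverged copy in
#' which substitutions are placed only at synonymous positions
#' (codon-table-checked single-step synonymous changes). The per-position
#' substitution probability is scaled so that the expected Nei-Gojobori
#' synonymous difference proportion equals the Jukes-Cantor mismatch
#' probability at divergence `true_ks`, hence the expected JC-corrected ks
#' equals `true_ks`.
#'
#' @param n_pairs Number of CDS pairs.
#' @param n_codons Codons per CDS (>= 10).
#' @param true_ks True synonymous distance (substitutions per synonymous
#'   site); must be < 2 (saturation guard).
#' @param seed Integer seed.
#' @param fasta,truth Optional output paths.
#' @return List with `sequences` (ids `pairK_a` / `pairK_b`) and `truth`
#'   (`data.frame` with `pair_id`, `true_ks`).
#' @export
simulate_wgd_pairs <- function(n_pairs, n_codons, true_ks, seed,
                               fasta = NULL, truth = NULL) {
  stopifnot(n_pairs >= 1, n_codons >= 10, true_ks >= 0)
  if (true_ks >= 2) stop("true_ks >= 2: synonymous distance would be saturated")
  .codon_tables()
  set.seed(seed)
  sense <- .grasskit_env$sense_codons
  syn_alt <- .grasskit_env$syn_alt
  p_mm <- 0.75 * (1 - exp(-4 * true_ks / 3))
  ids <- paste0("pair", seq_len(n_pairs))
  seqs <- character(2L * n_pairs)
  for (k in seq_len(n_pairs)) {
    a_cod <- sample(sense, n_codons, replace = TRUE)
    b_cod <- a_cod
    for (i in seq_len(n_codons)) {
      alts <- syn_alt[[a_cod[i]]]
      bb <- strsplit(a_cod[i], "")[[1L]]
      hit <- FALSE
      for (p in 1:3) {
        n_syn <- length(alts[[p]])
        if (n_syn == 0L) next
        if (runif(1) < (n_syn / 3) * p_mm) {
          bb[p] <- if (n_syn == 1L) alts[[p]] else sample(alts[[p]], 1L)
          hit <- TRUE
        }
      }
      if (hit) b_cod[i] <- paste(bb, collapse = "")
    }
    seqs[2L * k - 1L] <- paste(a_cod, collapse = "")
    seqs[2L * k] <- paste(b_cod, collapse = "")
  }
  names(seqs) <- as.vector(rbind(paste0(ids, "_a"), paste0(ids, "_b")))
  tr <- data.frame(pair_id = ids, true_ks = true_ks, stringsAsFactors = FALSE)
  if (!is.null(fasta)) write_fasta(seqs, fasta)
  if (!is.null(truth)) write.table(tr, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(sequences = seqs, truth = tr)
}

# --- BSA cross ---------------------------------------------------------------

#' Simulate an F1 biparental pool-seq cross with one causal flowering locus
#'
#' Emulates the QTL-seq design: parent P1 homozygous reference everywhere,
#' parent P2 heterozygous at every SNP (alternate allele on one haplotype),
#' F1 individuals formed from a non-recombinant P1 gamete and a P2 gamete
#' with Haldane (Poisson, no-interference) crossovers. The phenotype is an
#' indicator of carrying the alternate allele at the causal locus (dominant
#' model; `additive` scores half the dosage) plus Gaussian noise; the pools
#' are the `pool_size` earliest- and latest-phenotype individuals, and pool
#' reads are binomial draws at the pool allele frequency.
#'
#' @param chrom_length Chromosome length, bp.
#' @param n_snps Number of informative SNPs (a SNP is forced at
#'   `causal_pos`, replacing the nearest sampled position).
#' @param causal_pos 1-based position of the causal locus.
#' @param pool_size Individuals per pool (>= 2).
#' @param read_depth Pooled read depth per site (>= 1).
#' @param recomb_rate_per_mb Expected crossovers per Mb per meiosis
#'   (default 0.1, i.e. 10 cM/Mb: about one obligate crossover per meiosis
#'   on a 10-Mb linkage group).
#' @param phenotype_noise_sd SD of Gaussian phenotype noise.
#' @param seed Integer seed.
#' @param n_individuals Size of the F1 population from which the extreme
#'   pools are drawn.
#' @param effect_model `"dominant"` (default) or `"additive"`.
#' @param vcf,truth Optional output paths (VCF with samples
#'   `P1, P2, pool_early, pool_late`; truth TSV of per-site pool allele
#'   frequencies).
#' @return List with `sites` (the parsed site table, as from
#'   [read_vcf_biallelic()]), `truth` (list: `causal_chrom`, `causal_pos`,
#'   `effect_model`, `individuals` data.frame, `site_freqs` data.frame) and
#'   `vcf_lines` (character vector of the VCF text).
#' @export
simulate_bsa_cross <- function(chrom_length, n_snps, causal_pos, pool_size,
                               read_depth, recomb_rate_per_mb = 0.1,
                               phenotype_noise_sd = 0, seed = 1,
                               n_individuals = 200L,
                               effect_model = c("dominant", "additive"),
                               vcf = NULL, truth = NULL) {
  effect_model <- match.arg(effect_model)
  stopifnot(causal_pos >= 1, causal_pos <= chrom_length,
            pool_size >= 2, read_depth >= 1, phenotype_noise_sd >= 0)
  if (n_snps > chrom_length) stop("n_snps exceeds chrom_length")
  if (2L * pool_size > n_individuals)
    stop("pools larger than half the population")
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_snps))
  if (!causal_pos %in% pos) pos[which.min(abs(pos - causal_pos))] <- causal_pos
  pos <- sort(pos)
  causal_idx <- match(causal_pos, pos)

  # P2 gametes: haplotype 1 carries alt at every SNP, haplotype 0 is ref.
  # Haldane model: Poisson crossover count, uniform positions, random start.
  lambda <- recomb_rate_per_mb * chrom_length / 1e6
  gam <- matrix(0L, nrow = n_individuals, ncol = n_snps)
  for (i in seq_len(n_individuals)) {
    nx <- rpois(1L, lambda)
    bk <- if (nx) sort(runif(nx, 0, chrom_length)) else numeric()
    phase0 <- sample(0:1, 1L)
    # haplotype at each SNP: parity of crossovers to the left
    gam[i, ] <- (phase0 + findInterval(pos, bk)) %% 2L
  }
  carrier <- gam[, causal_idx] == 1L
  pheno <- switch(effect_model, dominant = as.numeric(carrier),
                  additive = 0.5 * as.numeric(carrier)) +
    rnorm(n_individuals, 0, phenotype_noise_sd)
  ord <- order(pheno)
  early <- ord[seq_len(pool_size)]
  late <- ord[seq(n_individuals - pool_size + 1L, n_individuals)]

  # pool alt-allele frequency: each F1 = ref chromosome (P1) + P2 gamete
  freq_early <- colSums(gam[early, , drop = FALSE]) / (2 * pool_size)
  freq_late <- colSums(gam[late, , drop = FALSE]) / (2 * pool_size)
  alt_e <- rbinom(n_snps, read_depth, freq_early)
  alt_l <- rbinom(n_snps, read_depth, freq_late)
  p2_ref <- rbinom(n_snps, read_depth, 0.5)

  ref_b <- sample(.BASES, n_snps, replace = TRUE)
  alt_b <- vapply(ref_b, function(b) sample(setdiff(.BASES, b), 1L), "")

  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=chr1,length=", format(chrom_length, scientific = FALSE), ">"),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "P1", "P2", "pool_early", "pool_late"), collapse = "\t"),
    paste(
      "chr1", format(pos, scientific = FALSE, trim = TRUE), ".", ref_b, alt_b,
      "60", ".", "MQ=60", "GT:AD",
      paste0("0/0:", read_depth, ",0"),
      paste0("0/1:", p2_ref, ",", read_depth - p2_ref),
      paste0("0/1:", read_depth - alt_e, ",", alt_e),
      paste0("0/1:", read_depth - alt_l, ",", alt_l),
      sep = "\t")
  )
  path <- if (is.null(vcf)) tempfile(fileext = ".vcf") else vcf
  writeLines(lines, path)
  sites <- read_vcf_biallelic(path, c("P1", "P2", "pool_early", "pool_late"))
  if (is.null(vcf)) unlink(path)

  individuals <- data.frame(individual = seq_len(n_individuals),
                            carrier = carrier, phenotype = pheno,
                            pool = ifelse(seq_len(n_individuals) %in% early, "early",
                                          ifelse(seq_len(n_individuals) %in% late,
                                                 "late", "none")),
                            stringsAsFactors = FALSE)
  site_freqs <- data.frame(chrom = "chr1", pos = pos,
                           freq_early = freq_early, freq_late = freq_late)
  tr <- list(causal_chrom = "chr1", causal_pos = causal_pos,
             effect_model = effect_model, individuals = individuals,
             site_freqs = site_freqs)
  if (!is.null(truth))
    write.table(site_freqs, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(sites = sites, truth = tr, vcf_lines = lines)
}

#' Simulate a two-population diploid panel with a known FST
#'
#' Balding-Nichols model: each SNP has an ancestral frequency
#' `p ~ Uniform(0.05, 0.95)`; each population's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst_target`; diploid genotypes
#' are binomial in the population frequency.
#'
#' @param n_samples_per_pop Diploid samples per population.
#' @param n_snps Number of SNPs.
#' @param fst_target Target differentiation `F` in `[0, 1)`.
#' @param seed Integer seed.
#' @param chrom_length Chromosome length for SNP placement (default
#'   `1000 * n_snps`).
#' @param vcf,truth Optional output paths.
#' @return List with `genotypes` (samples x sites dosage matrix),
#'   `positions` (`data.frame` of `chrom`, `pos`), `pops` (named character
#'   vector, sample -> population), `truth` (`data.frame` of per-site
#'   population frequencies) and `vcf_lines`.
#' @export
simulate_two_pop_panel <- function(n_samples_per_pop, n_snps, fst_target, seed,
                                   chrom_length = NULL, vcf = NULL, truth = NULL) {
  stopifnot(n_samples_per_pop >= 1, n_snps >= 0,
            fst_target >= 0, fst_target < 1)
  set.seed(seed)
  if (is.null(chrom_length)) chrom_length <- max(1000L * max(n_snps, 1L), 1000L)
  pos <- if (n_snps) sort(sample.int(chrom_length, n_snps)) else integer()
  p <- runif(n_snps, 0.05, 0.95)
  if (fst_target == 0) {
    p1 <- p; p2 <- p
  } else {
    Fv <- fst_target
    p1 <- rbeta(n_snps, p * (1 - Fv) / Fv, (1 - p) * (1 - Fv) / Fv)
    p2 <- rbeta(n_snps, p * (1 - Fv) / Fv, (1 - p) * (1 - Fv) / Fv)
  }
  n <- n_samples_per_pop
  samples <- c(paste0("w", seq_len(n)), paste0("c", seq_len(n)))
  pops <- setNames(rep(c("pop1", "pop2"), each = n), samples)
  g1 <- matrix(rbinom(n * n_snps, 2L, rep(p1, each = n)), nrow = n)
  g2 <- matrix(rbinom(n * n_snps, 2L, rep(p2, each = n)), nrow = n)
  geno <- rbind(g1, g2)
  rownames(geno) <- samples
  if (n_snps) colnames(geno) <- paste0("chr1_", pos)

  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno))
  ad_str <- matrix(c("20,0", "10,10", "0,20")[geno + 1L], nrow = nrow(geno))
  ref_b <- sample(.BASES, n_snps, replace = TRUE)
  alt_b <- vapply(ref_b, function(b) sample(setdiff(.BASES, b), 1L), "",
                  USE.NAMES = FALSE)
  body <- if (n_snps) {
    per_site <- vapply(seq_len(n_snps), function(j)
      paste(paste0(gt_str[, j], ":", ad_str[, j]), collapse = "\t"), "")
    paste("chr1", format(pos, scientific = FALSE, trim = TRUE), ".", ref_b,
          alt_b, "60", ".", "MQ=60;DP=20", "GT:AD", per_site, sep = "\t")
  } else character()
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=chr1,length=", format(chrom_length, scientific = FALSE), ">"),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  )
  if (!is.null(vcf)) writeLines(lines, vcf)
  tr <- data.frame(chrom = rep("chr1", n_snps), pos = pos,
                   p_ancestral = p, p_pop1 = p1, p_pop2 = p2,
                   fst_target = rep(fst_target, n_snps))
  if (!is.null(truth))
    write.table(tr, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(genotypes = geno,
       positions = data.frame(chrom = rep("chr1", n_snps), pos = pos),
       pops = pops, truth = tr, vcf_lines = lines)
}
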