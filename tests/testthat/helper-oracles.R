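# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with the package.

# exhaustive global-alignment score by recursion over all alignments
brute_force_nw_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0L)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    if (ca[i] == cb[j]) match else mismatch)
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(ca), length(cb))
}

# all permutations of 1..n (n <= 3 needed here)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# independent NG86 pathway oracle built on seqinr's codon translation
ng86_oracle_codon_pair <- function(c1, c2) {
  tr <- function(cod) seqinr::translate(strsplit(cod, "")[[1L]])
  b1 <- strsplit(c1, "")[[1L]]; b2 <- strsplit(c2, "")[[1L]]
  dpos <- which(b1 != b2)
  if (length(dpos) == 0L) return(c(Sd = 0, Nd = 0))
  collect <- function(exclude_stops) {
    res <- list()
    for (ord in all_perms(length(dpos))) {
      cur <- b1; s <- 0; n <- 0; valid <- TRUE
      for (p in dpos[ord]) {
        nxt <- cur; nxt[p] <- b2[p]
        if (exclude_stops && tr(paste(nxt, collapse = "")) == "*" &&
            !identical(nxt, b2)) { valid <- FALSE; break }
        if (tr(paste(cur, collapse = "")) == tr(paste(nxt, collapse = "")))
          s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (valid) res[[length(res) + 1L]] <- c(s, n)
    }
    res
  }
  paths <- collect(TRUE)
  if (length(paths) == 0L) paths <- collect(FALSE)
  m <- do.call(rbind, paths)
  c(Sd = mean(m[, 1L]), Nd = mean(m[, 2L]))
}

# fractional synonymous sites of one codon (stops nonsynonymous), via seqinr
ng86_oracle_syn_sites <- function(cod) {
  tr <- function(x) seqinr::translate(strsplit(x, "")[[1L]])
  b <- strsplit(cod, "")[[1L]]
  s <- 0
  for (p in 1:3) {
    for (x in setdiff(c("A", "C", "G", "T"), b[p])) {
      bb <- b; bb[p] <- x
      mut <- paste(bb, collapse = "")
      if (tr(mut) == tr(cod) && tr(mut) != "*") s <- s + 1 / 3
    }
  }
  s
}

sense_codons <- function() {
  cods <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1L, paste, collapse = "")
  cods[vapply(cods, function(x)
    seqinr::translate(strsplit(x, "")[[1L]]) != "*", TRUE)]
}

# naive per-window recomputation of BSA window statistics from raw sites
naive_window_stats <- function(pool_sites, windows) {
  n <- nrow(windows)
  me <- ml <- delta <- numeric(n)
  ns <- integer(n)
  for (i in seq_len(n)) {
    in_w <- pool_sites$pos >= windows$start[i] & pool_sites$pos <= windows$end[i]
    ns[i] <- sum(in_w)
    ie <- pool_sites$index_early[in_w]; il <- pool_sites$index_late[in_w]
    me[i] <- if (any(!is.na(ie))) mean(ie, na.rm = TRUE) else NA_real_
    ml[i] <- if (any(!is.na(il))) mean(il, na.rm = TRUE) else NA_real_
    delta[i] <- if (ns[i] > 0 && !is.na(me[i]) && !is.na(ml[i])) ml[i] - me[i] else 0
  }
  nd <- ns / max(ns, 1L)
  data.frame(n_snps = ns, mean_index_early = me, mean_index_late = ml,
             delta = delta, norm_density = nd, transformed_delta = delta * nd)
}

# pi as the literal average pairwise difference over all haplotype pairs
brute_force_pi <- function(alleles) {
  n <- length(alleles)
  diffs <- 0; pairs <- 0
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    diffs <- diffs + (alleles[i] != alleles[j])
    pairs <- pairs + 1L
  }
  unname(diffs / pairs)
}

# minimal VCF writer for hand-built fixtures
write_mini_vcf <- function(path, samples, rows,
                           format = "GT:AD", extra_header = character()) {
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr6>",
             extra_header,
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             rows)
  writeLines(lines, path)
  path
}
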