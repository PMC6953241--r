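# Readers/writers for the plain-text formats every stage touches.
# Internal coordinates are 1-based inclusive (VCF/GFF3 convention); the BED
# writer/reader is the only place the 0-based half-open conversion happens.

.DNA_OK <- c("A", "C", "G", "T", "N")

#' Read a DNA FASTA file
#'
#' Reads a FASTA file into a named character vector of upper-case DNA
#' sequences. Multi-line records are concatenated and lower-case letters are
#' folded to upper case. Only the alphabet `A, C, G, T, N` is accepted.
#'
#' @param path Path to a FASTA text file.
#' @return Named character vector, one element per record, in file order.
#'   Names are the FASTA ids (first whitespace-delimited token).
#' @details Errors on an empty file, on duplicate record ids (the offending
#'   id is named) and on any symbol outside `A,C,G,T,N`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  seqs <- toupper(as.character(ss))
  bad <- grepl(paste0("[^", paste(.DNA_OK, collapse = ""), "]"), seqs)
  if (any(bad)) {
    sym <- regmatches(seqs[bad][1L],
                      regexpr(paste0("[^", paste(.DNA_OK, collapse = ""), "]"),
                              seqs[bad][1L]))
    stop("illegal symbol '", sym, "' in FASTA record '", ids[bad][1L], "'")
  }
  if (any(!nzchar(seqs))) stop("empty sequence in record '", ids[!nzchar(seqs)][1L], "'")
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read biallelic SNPs from a VCF file
#'
#' Parses a VCF (v4.x) file, keeping only biallelic single-nucleotide
#' records, and extracts per-sample genotype calls and allele depths for the
#' requested samples. Multi-allelic records, indels/MNVs and records with a
#' malformed GT or AD field are skipped, and the number skipped per reason is
#' recorded in the `skipped` attribute.
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @param sample_names Character vector of sample names to extract; all must
#'   be present in the VCF header.
#' @return A `data.frame` with one row per retained SNP and columns `chrom`,
#'   `pos`, `ref`, `alt`, `qual`, `rms_mq` (INFO `MQ`, `NA` when absent),
#'   `info_dp` (INFO `DP`, `NA` when absent) and, per sample `s`, `gt.s` (one
#'   of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`), `ad_ref.s` and
#'   `ad_alt.s` (integer allele depths, `NA` when AD absent). Attributes:
#'   `samples`, `skipped` (named integer vector of skip counts).
#' @export
read_vcf_biallelic <- function(path, sample_names) {
  stopifnot(file.exists(path), is.character(sample_names), length(sample_names) >= 1L)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(v@gt)[-1L]
  miss <- setdiff(sample_names, have)
  if (length(miss))
    stop("sample(s) not in VCF header: ", paste(miss, collapse = ", "))

  fix <- v@fix
  n0 <- nrow(fix)
  skipped <- c(multiallelic = 0L, not_snp = 0L, malformed = 0L)
  if (n0 == 0L) {
    out <- .empty_sites(sample_names)
    attr(out, "skipped") <- skipped
    return(out)
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & !is.na(alt)
  skipped["multiallelic"] <- sum(multi)
  skipped["not_snp"] <- sum(!snp & !multi)

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  info <- fix[, "INFO"]
  info_field <- function(info, key) {
    pat <- paste0("(^|;)", key, "=([0-9eE.+-]+)")
    m <- regexpr(pat, ifelse(is.na(info), "", info))
    val <- rep(NA_character_, length(info))
    hit <- m > 0L
    val[hit] <- sub(pat, "\\2", regmatches(info, m))
    suppressWarnings(as.numeric(val))
  }
  mq <- info_field(info, "MQ")
  dp <- info_field(info, "DP")

  keep <- which(snp)
  parse_gt <- function(g) {
    g <- sub("|", "/", g, fixed = TRUE)
    out <- rep("missing", length(g))
    out[g %in% "0/0"] <- "hom_ref"
    out[g %in% c("0/1", "1/0")] <- "het"
    out[g %in% "1/1"] <- "hom_alt"
    bad <- !is.na(g) & !(g %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
    list(gt = out, bad = bad)
  }
  cols <- list(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    qual = suppressWarnings(as.numeric(fix[keep, "QUAL"])),
    rms_mq = mq[keep], info_dp = dp[keep]
  )
  bad_any <- rep(FALSE, length(keep))
  for (s in sample_names) {
    g <- parse_gt(gt_raw[keep, s])
    a <- ad_raw[keep, s]
    ok_ad <- is.na(a) | grepl("^[0-9]+(,[0-9]+)*$", a)
    adr <- rep(NA_integer_, length(a)); ada <- rep(NA_integer_, length(a))
    two <- !is.na(a) & ok_ad
    if (any(two)) {
      sp <- strsplit(a[two], ",", fixed = TRUE)
      adr[two] <- as.integer(vapply(sp, `[`, "", 1L))
      ada[two] <- as.integer(vapply(sp, function(x) if (length(x) >= 2L) x[2L] else "0", ""))
    }
    bad_any <- bad_any | g$bad | !ok_ad
    cols[[paste0("gt.", s)]] <- g$gt
    cols[[paste0("ad_ref.", s)]] <- adr
    cols[[paste0("ad_alt.", s)]] <- ada
  }
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  skipped["malformed"] <- sum(bad_any)
  out <- out[!bad_any, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- sample_names
  attr(out, "skipped") <- skipped
  out
}

.empty_sites <- function(sample_names) {
  cols <- list(chrom = character(), pos = integer(), ref = character(),
               alt = character(), qual = numeric(), rms_mq = numeric(),
               info_dp = numeric())
  for (s in sample_names) {
    cols[[paste0("gt.", s)]] <- character()
    cols[[paste0("ad_ref.", s)]] <- integer()
    cols[[paste0("ad_alt.", s)]] <- integer()
  }
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  attr(out, "samples") <- sample_names
  out
}

#' Write genomic regions to a BED file
#'
#' Converts internal 1-based inclusive intervals to BED's 0-based half-open
#' convention (`start - 1`, `end`) and writes one line per region.
#'
#' @param regions `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) && any(regions$end < regions$start))
    stop("region with end < start")
  df <- data.frame(chrom = regions$chrom,
                   start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
                   end = format(regions$end, scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive regions
#'
#' @param path Path to a BED file (first three columns used).
#' @return `data.frame` with `chrom`, `start`, `end`, 1-based inclusive.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df[[1L]], start = as.integer(df[[2L]]) + 1L,
             end = as.integer(df[[3L]]), stringsAsFactors = FALSE)
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` features and their `ID` attribute, returning models
#' sorted by chromosome and start.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, sorted by `(chrom, start)`.
#' @export
read_gff3_genes <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character()))
  ids <- vapply(strsplit(as.character(g$attributes), ";", fixed = TRUE),
                function(parts) {
                  parts <- trimws(parts)
                  hit <- parts[startsWith(parts, "ID=")]
                  if (length(hit)) sub("^ID=", "", hit[1L]) else NA_character_
                }, "")
  if (anyNA(ids)) stop("gene feature without ID attribute at ",
                       g$seqid[is.na(ids)][1L], ":", g$start[is.na(ids)][1L])
  out <- data.frame(gene_id = ids, chrom = as.character(g$seqid),
                    start = g$start, end = g$end,
                    strand = as.character(g$strand), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# the five developmental stages of the flowering-time expression design
.EXPR_STAGES <- c("prevernalization", "vernalization", "postvernalization",
                  "preheading", "heading")

#' Read a gene-by-stage expression matrix
#'
#' Reads a TSV with a `gene_id` column and the five flowering-stage columns
#' `prevernalization`, `vernalization`, `postvernalization`, `preheading`,
#' `heading` (RPKM-like, non-negative).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with `gene_id` plus the five stage columns, in the
#'   fixed stage order.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("gene_id", .EXPR_STAGES), names(df))
  if (length(miss)) stop("expression TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, c("gene_id", .EXPR_STAGES)]
  vals <- as.matrix(df[, .EXPR_STAGES])
  if (any(is.na(vals))) stop("missing expression values")
  if (any(vals < 0)) stop("negative expression value for gene '",
                          df$gene_id[which(rowSums(vals < 0) > 0)[1L]], "'")
  df
}
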