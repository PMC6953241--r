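# Synonymous-distance (ks) estimation for duplicate CDS pairs by
# Nei-Gojobori (1986) counting with the Jukes-Cantor multiple-hit
# correction, and conversion of the ks distribution peak to a duplication
# time via ks / (2 r).

# all orderings in which the differing codon positions can be visited
.perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# average (syn, nonsyn) differences between two codons over all minimal
# mutational pathways; pathways through stop codons are excluded (if every
# pathway is blocked, all are used with stop steps counted nonsynonymous)
.codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  aa <- .grasskit_env$aa
  b1 <- strsplit(c1, "")[[1L]]
  b2 <- strsplit(c2, "")[[1L]]
  diffpos <- which(b1 != b2)
  d <- length(diffpos)
  paths <- .perms[[d]]
  tally <- function(skip_stops) {
    sd <- 0; nd <- 0; used <- 0L
    for (ord in paths) {
      cur <- b1
      s <- 0; n <- 0; ok <- TRUE
      for (p in diffpos[ord]) {
        nxt <- cur; nxt[p] <- b2[p]
        a1 <- aa[[paste(cur, collapse = "")]]
        a2 <- aa[[paste(nxt, collapse = "")]]
        if (a2 == "*" && skip_stops && paste(nxt, collapse = "") != c2) {
          ok <- FALSE; break
        }
        if (a1 == a2) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) { sd <- sd + s; nd <- nd + n; used <- used + 1L }
    }
    if (used) c(sd / used, nd / used) else NULL
  }
  res <- tally(skip_stops = TRUE)
  if (is.null(res)) res <- tally(skip_stops = FALSE)
  res
}

.split_codons <- function(x) {
  substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
}

#' Nei-Gojobori site and difference counts for a CDS pair
#'
#' Counts fractional synonymous (`S`) and nonsynonymous (`N`) sites from the
#' standard codon table, averaged across the two sequences, and synonymous
#' (`Sd`) and nonsynonymous (`Nd`) differences, averaging multi-difference
#' codons over all minimal mutational pathways (pathways through stop codons
#' excluded). Changes to stop codons count as nonsynonymous in site
#' fractions. Codons containing `N` (in either sequence) are skipped.
#'
#' @param cds_a,cds_b Equal-length coding sequences, length divisible by 3,
#'   without stop codons.
#' @return List with `S`, `N`, `Sd`, `Nd` and `n_codons_compared`.
#' @export
ng86_counts <- function(cds_a, cds_b) {
  .codon_tables()
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("CDS lengths differ (", nchar(cds_a), " vs ", nchar(cds_b), ")")
  if (nchar(cds_a) %% 3L != 0L) stop("CDS length not divisible by 3")
  ca <- .split_codons(cds_a); cb <- .split_codons(cds_b)
  aa <- .grasskit_env$aa
  for (i in seq_along(ca)) {
    for (cod in c(ca[i], cb[i])) {
      if (!grepl("N", cod, fixed = TRUE) && !is.na(aa[cod]) && aa[[cod]] == "*")
        stop("stop codon at codon index ", i)
    }
  }
  skip <- grepl("N", ca, fixed = TRUE) | grepl("N", cb, fixed = TRUE)
  ca <- ca[!skip]; cb <- cb[!skip]
  if (any(is.na(aa[ca])) || any(is.na(aa[cb])))
    stop("illegal codon symbol (only A,C,G,T,N allowed)")
  syn_sites <- .grasskit_env$syn_sites
  S <- sum((syn_sites[ca] + syn_sites[cb]) / 2)
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] != cb[i]) {
      dd <- .codon_pair_diffs(ca[i], cb[i])
      Sd <- Sd + dd[1L]; Nd <- Nd + dd[2L]
    }
  }
  list(S = unname(S), N = unname(N), Sd = Sd, Nd = Nd,
       n_codons_compared = length(ca))
}

#' Jukes-Cantor-corrected synonymous distance from NG86 counts
#'
#' @param S Synonymous sites (`> 0`).
#' @param Sd Synonymous differences.
#' @return List with `ps = Sd/S`, `ks = -0.75 ln(1 - 4 ps / 3)` (or `NA`)
#'   and `saturated` (`TRUE` when `ps >= 0.75`).
#' @export
ks_from_counts <- function(S, Sd) {
  if (S <= 0) stop("S must be positive")
  ps <- Sd / S
  saturated <- ps >= 0.75
  list(ps = ps,
       ks = if (saturated) NA_real_ else -0.75 * log(1 - 4 * ps / 3),
       saturated = saturated)
}

#' Estimate ks for a set of paired CDS records
#'
#' Pairs are matched by the id suffixes `_a` / `_b` (as produced by
#' [simulate_wgd_pairs()] or a paired FASTA).
#'
#' @param sequences Named character vector of CDS.
#' @return Object of class `"ks_estimates"` (a `data.frame`) with columns
#'   `pair_id`, `S`, `N`, `Sd`, `Nd`, `ps`, `ks`, `saturated`.
#' @export
ks_estimates <- function(sequences) {
  ids_a <- grep("_a$", names(sequences), value = TRUE)
  pid <- sub("_a$", "", ids_a)
  ids_b <- paste0(pid, "_b")
  if (!all(ids_b %in% names(sequences)))
    stop("unpaired CDS record(s): ",
         paste(head(pid[!ids_b %in% names(sequences)], 3L), collapse = ", "))
  if (length(pid) == 0L) stop("no *_a/*_b pairs found")
  rows <- lapply(seq_along(pid), function(i) {
    cnt <- ng86_counts(sequences[[ids_a[i]]], sequences[[ids_b[i]]])
    kk <- ks_from_counts(cnt$S, cnt$Sd)
    data.frame(pair_id = pid[i], S = cnt$S, N = cnt$N, Sd = cnt$Sd,
               Nd = cnt$Nd, ps = kk$ps, ks = kk$ks,
               saturated = kk$saturated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ks_estimates", "data.frame")
  out
}

#' @export
print.ks_estimates <- function(x, ...) {
  cat("ks estimates for", nrow(x), "CDS pairs;",
      sum(x$saturated), "saturated\n")
  print.data.frame(head(as.data.frame(x), 10L), digits = 4, ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' @export
summary.ks_estimates <- function(object, ...) {
  ok <- object$ks[!object$saturated]
  cat(sprintf("%d pairs (%d saturated); mean ks %.4f, median %.4f\n",
              nrow(object), sum(object$saturated), mean(ok), stats::median(ok)))
  invisible(object)
}

#' @export
plot.ks_estimates <- function(x, bin_width = 0.05, xlab = "ks",
                              ylab = "gene pairs", ...) {
  ks <- x$ks[!x$saturated]
  hist(ks, breaks = seq(0, max(ks) + bin_width, by = bin_width),
       xlab = xlab, ylab = ylab, main = "ks distribution", ...)
  invisible(x)
}

#' Peak of a ks distribution
#'
#' Histogram mode over left-closed right-open bins *centred* on multiples of
#' `bin_width` (so a bin width of 0.1 puts 0.48, 0.50 and 0.52 in the bin
#' `[0.45, 0.55)` whose midpoint is 0.5); ties broken toward the smaller ks.
#' Saturated estimates are excluded.
#'
#' @param estimates A `"ks_estimates"` object or numeric ks vector (`NA` =
#'   saturated).
#' @param bin_width Histogram bin width (default 0.05).
#' @return Object of class `"ks_peak"`: list with `peak_ks` (midpoint of the
#'   maximal bin), `bin_width`, `breaks`, `counts`, `n`, `n_saturated`.
#' @export
ks_distribution_peak <- function(estimates, bin_width = 0.05) {
  stopifnot(bin_width > 0)
  ks <- if (inherits(estimates, "ks_estimates")) estimates$ks else estimates
  if (length(ks) == 0L) stop("no ks estimates supplied")
  n_sat <- sum(is.na(ks))
  ks <- ks[!is.na(ks)]
  if (length(ks) == 0L) stop("all ", n_sat, " ks estimates are saturated")
  idx <- floor(ks / bin_width + 0.5) + 1L  # bin k holds [(k-1.5)w, (k-0.5)w)
  counts <- tabulate(idx)
  peak_bin <- which.max(counts)            # first maximum = smaller ks on ties
  out <- list(peak_ks = (peak_bin - 1L) * bin_width, bin_width = bin_width,
              breaks = seq(-bin_width / 2, by = bin_width,
                           length.out = length(counts) + 1L),
              counts = counts, n = length(ks), n_saturated = n_sat)
  class(out) <- "ks_peak"
  out
}

#' @export
print.ks_peak <- function(x, ...) {
  cat(sprintf("ks distribution peak: %.4g (bin width %.3g, %d pairs, %d saturated)\n",
              x$peak_ks, x$bin_width, x$n, x$n_saturated))
  invisible(x)
}

#' Duplication/divergence time from a ks peak
#'
#' `time = ks / (2 r)` with `r` in substitutions per synonymous site per
#' year (default `6.96e-9`).
#'
#' @param peak_ks ks value(s) (`>= 0`).
#' @param clock_rate Synonymous clock rate (`> 0`).
#' @return Time(s) in years.
#' @export
wgd_time <- function(peak_ks, clock_rate = 6.96e-9) {
  if (clock_rate <= 0) stop("clock_rate must be positive")
  if (any(peak_ks < 0, na.rm = TRUE)) stop("peak_ks must be non-negative")
  peak_ks / (2 * clock_rate)
}
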