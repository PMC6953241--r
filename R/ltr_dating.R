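# LTR insertion-age dating: lambda (5'/3' mismatch proportion) -> K
# (Jukes-Cantor distance) -> T = K / (2 r) under a molecular clock.

#' Globally align a 5'/3' LTR pair
#'
#' Needleman-Wunsch global alignment with linear gap penalty and a fixed
#' deterministic tie-break (diagonal, then gap in the second sequence, then
#' gap in the first). Columns containing a gap or an `N` are excluded from
#' both the mismatch count and the ungapped-column count, so that
#' `lambda = n_mismatches / n_ungapped_columns` is a proportion over
#' confidently aligned sites.
#'
#' @param a,b DNA sequences (character scalars over `A,C,G,T,N`).
#' @param match,mismatch,gap Integer alignment scores (defaults +1/-1/-2).
#' @return Object of class `"ltr_alignment"`: list with `aligned_a`,
#'   `aligned_b`, `n_columns`, `n_ungapped_columns`, `n_mismatches`, `score`.
#' @export
align_ltr_pair <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  aln <- .nw_align_cpp(toupper(a), toupper(b),
                       as.integer(match), as.integer(mismatch), as.integer(gap))
  ca <- strsplit(aln$aligned_a, "")[[1L]]
  cb <- strsplit(aln$aligned_b, "")[[1L]]
  usable <- ca != "-" & cb != "-" & ca != "N" & cb != "N"
  out <- list(aligned_a = aln$aligned_a, aligned_b = aln$aligned_b,
              n_columns = length(ca),
              n_ungapped_columns = sum(usable),
              n_mismatches = sum(ca[usable] != cb[usable]),
              score = aln$score)
  class(out) <- "ltr_alignment"
  out
}

#' @export
print.ltr_alignment <- function(x, ...) {
  cat("Global LTR alignment:", x$n_columns, "columns,",
      x$n_ungapped_columns, "ungapped,", x$n_mismatches, "mismatches",
      sprintf("(score %d)\n", x$score))
  invisible(x)
}

#' Mismatch proportion of an aligned LTR pair
#'
#' @param alignment An `"ltr_alignment"` object.
#' @return `lambda`, the mismatch proportion over ungapped non-`N` columns.
#' @export
lambda_hat <- function(alignment) {
  if (alignment$n_ungapped_columns < 1L)
    stop("alignment has no ungapped columns; lambda undefined")
  alignment$n_mismatches / alignment$n_ungapped_columns
}

#' Jukes-Cantor distance from a mismatch proportion
#'
#' `K = -0.75 ln(1 - 4 lambda / 3)`, the multiple-hit-corrected number of
#' substitutions per site. Saturated inputs (`lambda >= 0.75`) yield `NA`.
#'
#' @param lambda Mismatch proportion(s), `>= 0`.
#' @return Numeric vector of distances; `NA` where saturated.
#' @export
jc_distance <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  ifelse(lambda < 0.75, -0.75 * log(1 - 4 * lambda / 3), NA_real_)
}

#' Insertion age from a Jukes-Cantor distance
#'
#' `T = K / (2 r)`: the two LTRs diverge along two branches, so the per-pair
#' distance accrues at twice the clock rate.
#'
#' @param K Jukes-Cantor distance(s), substitutions/site.
#' @param clock_rate Substitutions per site per year (`> 0`).
#' @return Age(s) in years.
#' @export
insertion_age <- function(K, clock_rate) {
  if (clock_rate <= 0) stop("clock_rate must be positive")
  if (any(K < 0, na.rm = TRUE)) stop("K must be non-negative")
  K / (2 * clock_rate)
}

#' Date LTR insertions for a set of 5'/3' pairs
#'
#' Runs the full chain alignment -> lambda -> K -> T for every element in a
#' paired sequence set. Pairs are matched by the id suffixes `_5p` / `_3p`.
#'
#' @param sequences Named character vector as returned by [read_fasta()] or
#'   [simulate_ltr_pairs()]; ids `<element>_5p` and `<element>_3p`.
#' @param clock_rate Substitutions/site/year (default `1.3e-8`).
#' @param pre_aligned If `TRUE`, sequences of each pair are assumed already
#'   aligned (equal length, gaps as `-`) and alignment is skipped.
#' @param match,mismatch,gap Alignment scores, see [align_ltr_pair()].
#' @return Object of class `"ltr_ages"` (a `data.frame`) with columns
#'   `element_id`, `lambda`, `K`, `age_years`, `saturated`; attribute
#'   `clock_rate`.
#' @export
ltr_age <- function(sequences, clock_rate = 1.3e-8, pre_aligned = FALSE,
                    match = 1L, mismatch = -1L, gap = -2L) {
  ids5 <- grep("_5p$", names(sequences), value = TRUE)
  el <- sub("_5p$", "", ids5)
  ids3 <- paste0(el, "_3p")
  if (!all(ids3 %in% names(sequences)))
    stop("unpaired LTR record(s): ", paste(head(el[!ids3 %in% names(sequences)], 3L),
                                           collapse = ", "))
  if (length(el) == 0L) stop("no *_5p/*_3p pairs found")
  lam <- vapply(seq_along(el), function(i) {
    if (pre_aligned) {
      ca <- strsplit(toupper(sequences[[ids5[i]]]), "")[[1L]]
      cb <- strsplit(toupper(sequences[[ids3[i]]]), "")[[1L]]
      if (length(ca) != length(cb)) stop("pre-aligned pair '", el[i],
                                         "' has unequal lengths")
      usable <- ca != "-" & cb != "-" & ca != "N" & cb != "N"
      if (!any(usable)) stop("pair '", el[i], "' has no usable columns")
      sum(ca[usable] != cb[usable]) / sum(usable)
    } else {
      lambda_hat(align_ltr_pair(sequences[[ids5[i]]], sequences[[ids3[i]]],
                                match, mismatch, gap))
    }
  }, 0)
  K <- jc_distance(lam)
  out <- data.frame(element_id = el, lambda = lam, K = K,
                    age_years = insertion_age(K, clock_rate),
                    saturated = is.na(K), stringsAsFactors = FALSE)
  attr(out, "clock_rate") <- clock_rate
  class(out) <- c("ltr_ages", "data.frame")
  out
}

#' @export
print.ltr_ages <- function(x, ...) {
  cat("LTR insertion-age estimates:", nrow(x), "elements",
      sprintf("(clock rate %.3g subs/site/year), %d saturated\n",
              attr(x, "clock_rate"), sum(x$saturated)))
  print.data.frame(head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' @export
summary.ltr_ages <- function(object, ...) {
  ok <- object$age_years[!object$saturated]
  res <- list(n = nrow(object), n_saturated = sum(object$saturated),
              mean_age = mean(ok), median_age = stats::median(ok),
              clock_rate = attr(object, "clock_rate"))
  class(res) <- "summary.ltr_ages"
  res
}

#' @export
print.summary.ltr_ages <- function(x, ...) {
  cat(sprintf("%d LTR elements (%d saturated); mean age %.4g yr, median %.4g yr\n",
              x$n, x$n_saturated, x$mean_age, x$median_age))
  invisible(x)
}

#' @export
plot.ltr_ages <- function(x, bin_width_years = 2.5e5, ...) {
  h <- age_distribution(x, bin_width_years)
  plot(h, ...)
  invisible(x)
}

#' Histogram of LTR insertion ages
#'
#' Bins ages into left-closed right-open intervals of `bin_width_years`
#' starting at zero. Saturated estimates are excluded but counted. The mode
#' is the midpoint of the maximal bin, ties broken toward the younger bin.
#'
#' @param estimates An `"ltr_ages"` object or a numeric vector of ages in
#'   years (`NA` = saturated).
#' @param bin_width_years Bin width, years (default 0.25 Myr).
#' @return Object of class `"age_histogram"`: list with `bin_width_years`,
#'   `breaks`, `counts`, `mode_age_years`, `n`, `n_saturated`.
#' @export
age_distribution <- function(estimates, bin_width_years = 2.5e5) {
  stopifnot(bin_width_years > 0)
  ages <- if (inherits(estimates, "ltr_ages")) estimates$age_years else estimates
  if (length(ages) == 0L) stop("no age estimates supplied")
  n_sat <- sum(is.na(ages))
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0L)
    stop("all ", n_sat, " estimates are saturated; no datable ages")
  idx <- floor(ages / bin_width_years) + 1L
  counts <- tabulate(idx)
  breaks <- seq(0, by = bin_width_years, length.out = length(counts) + 1L)
  mode_bin <- which.max(counts)  # first maximum = youngest on ties
  out <- list(bin_width_years = bin_width_years, breaks = breaks,
              counts = counts,
              mode_age_years = (mode_bin - 0.5) * bin_width_years,
              n = length(ages), n_saturated = n_sat)
  class(out) <- "age_histogram"
  out
}

#' @export
print.age_histogram <- function(x, ...) {
  cat(sprintf("Age histogram: %d estimates in %d bins of %.3g yr; mode %.4g yr (%d saturated excluded)\n",
              x$n, length(x$counts), x$bin_width_years, x$mode_age_years,
              x$n_saturated))
  invisible(x)
}

#' @export
plot.age_histogram <- function(x, xlab = "Insertion age (Myr)",
                               ylab = "LTR elements", ...) {
  mids <- (x$breaks[-1L] + x$breaks[-length(x$breaks)]) / 2e6
  barplot(x$counts, names.arg = sprintf("%.2f", mids), xlab = xlab,
          ylab = ylab, space = 0, ...)
  invisible(x)
}
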