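# Allele-specific ChIP-seq peak classification: exact one-sided binomial
# tests of each diploid peak's BL6-SNP read count against a chromosome-level
# allelic background. Peaks on the X are tested against pX, the pooled BL6
# proportion over all X peaks (the X background differs from autosomes under
# skewed XCI); autosomal peaks against a pooled autosomal background or a
# fixed 0.5.

#' Construct a peak-region table
#'
#' @param peak_id Peak identifiers.
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open peak intervals (BED convention).
#' @param n_bl,n_sp BL6-SNP and spretus-SNP read counts inside the peak.
#' @return A data.frame of class `peak_regions`.
#' @export
peak_regions <- function(peak_id, chrom, start, end, n_bl, n_sp) {
  n <- length(peak_id)
  chrom <- rep_len(chrom, n)
  stopifnot(length(start) == n, length(end) == n,
            length(n_bl) == n, length(n_sp) == n)
  if (any(end <= start)) stop("peak intervals must satisfy end > start",
                              call. = FALSE)
  if (any(n_bl < 0) || any(n_sp < 0)) stop("counts must be non-negative",
                                           call. = FALSE)
  out <- data.frame(peak_id = as.character(peak_id),
                    chrom = normalize_chrom(chrom),
                    start = as.integer(start), end = as.integer(end),
                    n_bl = as.numeric(n_bl), n_sp = as.numeric(n_sp),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_regions", "data.frame")
  out
}

#' Estimate the X-chromosome allelic background
#'
#' Pools all SNP reads over the diploid peak regions on the X and returns
#' `pX = sum(n_bl) / (sum(n_bl) + sum(n_sp))`, the null BL6 proportion used
#' for X-linked peak tests.
#'
#' @param x_peaks A [peak_regions()] table of X-linked peaks.
#' @return A list of class `allelic_background`: `chrom_class` ("chrX"),
#'   `p0`, and the pooled totals `n_bl`, `n_sp`.
#' @export
estimate_x_background <- function(x_peaks) {
  stopifnot(inherits(x_peaks, "peak_regions"))
  if (any(!is_x_chrom(x_peaks$chrom))) {
    stop("estimate_x_background expects X-linked peaks only", call. = FALSE)
  }
  pooled_background(x_peaks, "chrX")
}

#' @rdname estimate_x_background
#' @param peaks A [peak_regions()] table (autosomal for `chrom_class`
#'   "autosomal").
#' @param chrom_class `"chrX"` or `"autosomal"`.
#' @export
pooled_background <- function(peaks, chrom_class = c("chrX", "autosomal")) {
  chrom_class <- match.arg(chrom_class)
  nb <- sum(peaks$n_bl); ns <- sum(peaks$n_sp)
  if (nb + ns <= 0) stop("zero pooled SNP reads: background undefined",
                         call. = FALSE)
  p0 <- nb / (nb + ns)
  if (p0 <= 0 || p0 >= 1) {
    stop("degenerate background (all reads on one haplotype)", call. = FALSE)
  }
  structure(list(chrom_class = chrom_class, p0 = p0, n_bl = nb, n_sp = ns),
            class = "allelic_background")
}

#' Fixed allelic background
#'
#' The balanced-null alternative for autosomal peaks (`p0 = 0.5` by default).
#'
#' @param p0 Null proportion in (0,1).
#' @param chrom_class Label for the background.
#' @export
fixed_background <- function(p0 = 0.5, chrom_class = "autosomal") {
  stopifnot(p0 > 0, p0 < 1)
  structure(list(chrom_class = chrom_class, p0 = p0,
                 n_bl = NA_real_, n_sp = NA_real_),
            class = "allelic_background")
}

#' @export
print.allelic_background <- function(x, ...) {
  cat("allelic_background (", x$chrom_class, "): p0 =", signif(x$p0, 4))
  if (!is.na(x$n_bl)) cat("  [pooled", x$n_bl, "BL6 /", x$n_sp, "spretus reads]")
  cat("\n")
  invisible(x)
}

#' Exact binomial tail probabilities
#'
#' Inclusive one-sided tails of the exact binomial distribution:
#' `p_upper = P(K >= k)` and `p_lower = P(K <= k)` for
#' `K ~ Binomial(n, p0)`. They satisfy `p_upper + p_lower = 1 + P(K = k)`.
#'
#' @param k Observed success count(s), `0 <= k <= n`.
#' @param n Trial count(s).
#' @param p0 Null proportion in (0,1).
#' @return A list with numeric vectors `p_upper` and `p_lower`; both `NA`
#'   where `n = 0` (no information).
#' @examples
#' exact_binomial_tails(10, 10, 0.5)  # p_upper = 2^-10
#' @export
exact_binomial_tails <- function(k, n, p0) {
  stopifnot(all(p0 > 0 & p0 < 1))
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  p_upper <- ifelse(n > 0, pbinom(k - 1, n, p0, lower.tail = FALSE), NA_real_)
  p_lower <- ifelse(n > 0, pbinom(k, n, p0), NA_real_)
  # n = 0 carries no allelic information; k = 0, n > 0 is a valid boundary
  p_upper[n == 0] <- NA_real_
  p_lower[n == 0] <- NA_real_
  list(p_upper = p_upper, p_lower = p_lower)
}

#' Classify allele-specific ChIP-seq peaks
#'
#' Tests each peak's BL6-SNP read count against the background proportion
#' with inclusive one-sided exact binomial tests. A peak is assessable when
#' its allele-specific reads reach one per 10 million mapped reads of the
#' library (`ceiling(lib_total_mapped / 1e7)` reads). Assessable peaks are
#' `bl6_preferred` when the upper-tail p-value < `alpha_pref`,
#' `spretus_preferred` when the lower-tail p-value < `alpha_pref`,
#' `both_preferred` when both tails are >= `alpha_both`, and `ambiguous`
#' when the smaller tail lies in `[alpha_pref, alpha_both)` — a band the
#' three preferred labels do not cover.
#'
#' @param peaks A [peak_regions()] table.
#' @param bg An `allelic_background` (from [estimate_x_background()],
#'   [pooled_background()] or [fixed_background()]).
#' @param lib_total_mapped Total mapped reads of the library (sets the
#'   coverage filter).
#' @param alpha_pref One-sided significance level for allelic preference
#'   (default 0.05).
#' @param alpha_both Lower bound on both tails for a both-preferred call
#'   (default 0.25).
#' @return An object of class `peak_allele_calls`: a list with the per-peak
#'   data.frame `calls` (`peak_id`, `chrom`, `n_bl`, `n_sp`, `p_upper`,
#'   `p_lower`, `category`), the background, and the thresholds.
#' @export
classify_peaks <- function(peaks, bg, lib_total_mapped,
                           alpha_pref = 0.05, alpha_both = 0.25) {
  stopifnot(inherits(peaks, "peak_regions"), inherits(bg, "allelic_background"),
            lib_total_mapped > 0, alpha_pref <= 0.5, alpha_pref <= alpha_both)
  n <- peaks$n_bl + peaks$n_sp
  min_reads <- ceiling(lib_total_mapped / 1e7)
  assessable <- n >= min_reads & n >= 1
  tails <- exact_binomial_tails(peaks$n_bl, n, bg$p0)
  up <- !is.na(tails$p_upper) & tails$p_upper < alpha_pref
  lo <- !is.na(tails$p_lower) & tails$p_lower < alpha_pref
  both <- !is.na(tails$p_upper) &
    tails$p_upper >= alpha_both & tails$p_lower >= alpha_both
  category <- rep("ambiguous", nrow(peaks))
  category[up] <- "bl6_preferred"
  category[lo] <- "spretus_preferred"
  category[both] <- "both_preferred"
  category[!assessable] <- "not_assessable"
  stopifnot(!any(up & lo))  # impossible for alpha_pref <= 0.5 with inclusive tails
  calls <- data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom,
                      n_bl = peaks$n_bl, n_sp = peaks$n_sp,
                      p_upper = tails$p_upper, p_lower = tails$p_lower,
                      category = category, stringsAsFactors = FALSE)
  structure(list(calls = calls, background = bg,
                 alpha_pref = alpha_pref, alpha_both = alpha_both,
                 min_reads = min_reads, lib_total_mapped = lib_total_mapped),
            class = "peak_allele_calls")
}

#' @export
print.peak_allele_calls <- function(x, ...) {
  cat("Allele-specific peak calls:", nrow(x$calls), "peaks",
      "(p0 =", signif(x$background$p0, 4),
      ", min", x$min_reads, "allele-specific reads)\n")
  print(table(factor(x$calls$category,
                     levels = c("bl6_preferred", "spretus_preferred",
                                "both_preferred", "ambiguous",
                                "not_assessable"))))
  invisible(x)
}

#' @export
as.data.frame.peak_allele_calls <- function(x, ...) x$calls

#' Summarize peak calls with Xa/Xi labels
#'
#' Maps the haplotype-labelled categories onto active/inactive-X labels
#' given the experiment's Xi orientation, in the shape of a peak-number
#' summary row: total peaks, X-linked peaks, Xa-preferred, Xi-preferred,
#' both-preferred.
#'
#' @param x A `peak_allele_calls` object (X-linked peaks).
#' @param xi_haplotype `"spretus"` (F1 tissues) or `"bl6"` (Patski cells).
#' @param n_total_peaks Optional genome-wide diploid peak count for the
#'   first column (defaults to the number of classified peaks).
#' @param sample_id Optional row label.
#' @return A one-row data.frame with columns `sample_id`, `n_total_peaks`,
#'   `n_x_peaks`, `n_xa_preferred`, `n_xi_preferred`, `n_both_preferred`,
#'   `n_ambiguous`, `n_not_assessable`.
#' @export
summarize_peak_calls <- function(x, xi_haplotype = c("spretus", "bl6"),
                                 n_total_peaks = NULL, sample_id = "sample") {
  stopifnot(inherits(x, "peak_allele_calls"))
  xi_haplotype <- match.arg(xi_haplotype)
  cat_tab <- table(factor(x$calls$category,
                          levels = c("bl6_preferred", "spretus_preferred",
                                     "both_preferred", "ambiguous",
                                     "not_assessable")))
  if (xi_haplotype == "spretus") {
    n_xa <- cat_tab[["bl6_preferred"]]; n_xi <- cat_tab[["spretus_preferred"]]
  } else {
    n_xa <- cat_tab[["spretus_preferred"]]; n_xi <- cat_tab[["bl6_preferred"]]
  }
  data.frame(sample_id = sample_id,
             n_total_peaks = as.integer(n_total_peaks %||% nrow(x$calls)),
             n_x_peaks = nrow(x$calls),
             n_xa_preferred = as.integer(n_xa),
             n_xi_preferred = as.integer(n_xi),
             n_both_preferred = as.integer(cat_tab[["both_preferred"]]),
             n_ambiguous = as.integer(cat_tab[["ambiguous"]]),
             n_not_assessable = as.integer(cat_tab[["not_assessable"]]),
             stringsAsFactors = FALSE)
}

#' Intersect two peak sets
#'
#' Plumbing for consensus diploid peaks from two peak callers: keeps the
#' intervals of `a` that overlap an interval of `b` by at least one base.
#'
#' @param a,b Data.frames with `chrom`, `start`, `end` (0-based half-open;
#'   e.g. from [read_bed()]).
#' @return The overlapping subset of `a`.
#' @export
intersect_peaks <- function(a, b) {
  gr <- function(d) GenomicRanges::GRanges(normalize_chrom(d$chrom),
                                           IRanges::IRanges(d$start + 1L, d$end))
  a[IRanges::overlapsAny(gr(a), gr(b)), , drop = FALSE]
}
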