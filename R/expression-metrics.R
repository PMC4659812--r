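# Expression metrics: diploid RPKM, haploid Xi-/Xa-SRPM, and the
# experiment-level mapping-bias ratio rm.

#' Construct per-gene allelic counts
#'
#' Per gene: allele-specific exonic reads assigned to the inactive-X
#' haplotype (`n_xi`), to the active-X haplotype (`n_xa`), and all
#' high-MAPQ unique exonic reads (`n_diploid`, allelic plus uncertain).
#'
#' @param gene_id Gene identifiers.
#' @param n_xi,n_xa,n_diploid Non-negative read counts with
#'   `n_diploid >= n_xi + n_xa`.
#' @return A data.frame of class `allelic_counts`.
#' @export
allelic_counts <- function(gene_id, n_xi, n_xa, n_diploid) {
  n <- length(gene_id)
  stopifnot(length(n_xi) == n, length(n_xa) == n, length(n_diploid) == n)
  if (any(n_xi < 0) || any(n_xa < 0) || any(n_diploid < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(n_diploid < n_xi + n_xa)) {
    stop("n_diploid must be >= n_xi + n_xa for every gene", call. = FALSE)
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    n_xi = as.numeric(n_xi), n_xa = as.numeric(n_xa),
                    n_diploid = as.numeric(n_diploid),
                    stringsAsFactors = FALSE)
  class(out) <- c("allelic_counts", "data.frame")
  out
}

#' Construct per-experiment library statistics
#'
#' @param experiment_id Experiment label.
#' @param total_raw Raw read count.
#' @param total_unique_hq High-MAPQ uniquely mapped reads; the denominator
#'   of RPKM and SRPM.
#' @param na0,na1 Allele-specific autosomal read totals for the Xi-carrying
#'   and Xa-carrying haplotypes; their ratio is the mapping-bias ratio
#'   `rm = na0 / na1`.
#' @param xi_haplotype Which parental haplotype is inactivated (`"spretus"`
#'   in the F1 tissues, `"bl6"` in Patski cells).
#' @return A list of class `library_stats` with the fields above plus `rm`
#'   (NA when `na0`/`na1` are unavailable).
#' @export
library_stats <- function(experiment_id, total_raw, total_unique_hq,
                          na0 = NA_real_, na1 = NA_real_,
                          xi_haplotype = c("spretus", "bl6")) {
  xi_haplotype <- match.arg(xi_haplotype)
  stopifnot(total_unique_hq > 0, total_unique_hq <= total_raw)
  rm_ratio <- NA_real_
  if (!is.na(na0) && !is.na(na1)) {
    if (na1 <= 0) stop("na1 must be > 0 to define rm", call. = FALSE)
    if (na0 <= 0) stop("na0 must be > 0 to define rm", call. = FALSE)
    rm_ratio <- na0 / na1
  }
  out <- list(experiment_id = experiment_id,
              total_raw = as.numeric(total_raw),
              total_unique_hq = as.numeric(total_unique_hq),
              na0 = as.numeric(na0), na1 = as.numeric(na1),
              rm = rm_ratio, xi_haplotype = xi_haplotype)
  class(out) <- "library_stats"
  out
}

#' @export
print.library_stats <- function(x, ...) {
  cat("library_stats:", x$experiment_id, "\n",
      " total_raw:", format(x$total_raw, big.mark = ","), "\n",
      " total_unique_hq:", format(x$total_unique_hq, big.mark = ","), "\n",
      " Xi haplotype:", x$xi_haplotype, "\n",
      " NA0/NA1:", x$na0, "/", x$na1, " rm:", signif(x$rm, 4), "\n")
  invisible(x)
}

#' Diploid RPKM
#'
#' Reads per kilobase of exon length per million mapped reads:
#' `n_diploid / (exonic_length_bp/1000) / (total_unique_hq/1e6)`. The
#' denominator is the experiment's total high-MAPQ uniquely mapped reads.
#'
#' @param n_diploid Diploid exonic read count(s).
#' @param exonic_length_bp Union exon length(s) in bp, > 0.
#' @param total_unique_hq Library size (high-MAPQ unique reads), > 0.
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(1000, 2000, 1e7)  # 50
#' @export
rpkm <- function(n_diploid, exonic_length_bp, total_unique_hq) {
  if (any(exonic_length_bp <= 0)) stop("exonic length must be > 0", call. = FALSE)
  if (any(total_unique_hq <= 0)) stop("library size must be > 0", call. = FALSE)
  n_diploid / (exonic_length_bp / 1000) / (total_unique_hq / 1e6)
}

#' Haploid SRPM
#'
#' Allele-specific SNP-containing exonic reads per 10 million high-MAPQ
#' uniquely mapped reads: `allelic_reads * 1e7 / total_unique_hq`. Applied
#' to `n_xi` this is the Xi-SRPM, to `n_xa` the Xa-SRPM.
#'
#' @param allelic_reads Allele-specific read count(s), >= 0.
#' @param total_unique_hq Library size, > 0.
#' @return Numeric SRPM value(s).
#' @examples
#' srpm(40, 2e7)  # 20
#' @export
srpm <- function(allelic_reads, total_unique_hq) {
  if (any(allelic_reads < 0)) stop("allelic read count must be >= 0", call. = FALSE)
  if (any(total_unique_hq <= 0)) stop("library size must be > 0", call. = FALSE)
  allelic_reads * 1e7 / total_unique_hq
}

#' Mapping-bias ratio from autosomal allelic counts
#'
#' Pools allele-specific autosomal reads across genes and returns
#' `rm = NA0 / NA1`, where NA0 sums the reads of the haplotype that carries
#' the inactive X (per the experiment's orientation) and NA1 the other.
#' With skewed XCI both autosomal haplotypes are expressed equally, so rm
#' measures the residual mapping bias between the two haplotype genomes; it
#' is used to correct the binomial escape-probability estimate.
#'
#' @param autosomal_counts An [allelic_counts()] table for autosomal genes,
#'   with `n_xi`/`n_xa` meaning counts on the Xi-carrying/Xa-carrying
#'   haplotype respectively.
#' @return The scalar ratio `rm > 0`.
#' @export
mapping_bias_ratio <- function(autosomal_counts) {
  stopifnot(inherits(autosomal_counts, "allelic_counts"))
  na0 <- sum(autosomal_counts$n_xi)
  na1 <- sum(autosomal_counts$n_xa)
  if (na1 <= 0) stop("rm undefined: zero reads on the Xa-carrying haplotype",
                     call. = FALSE)
  if (na0 <= 0) stop("rm undefined: zero reads on the Xi-carrying haplotype",
                     call. = FALSE)
  na0 / na1
}
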