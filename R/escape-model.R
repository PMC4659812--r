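# The escape model: per-gene binomial model of the Xi-expression proportion
# with experiment-level mapping-bias correction, Wald confidence limits and
# the three-criterion escape-gene classification.
#
# For gene i on the X, n_xi ~ Binomial(n, p) with n = n_xi + n_xa. The raw
# estimate p_hat = n_xi/n is corrected for mapping bias toward the reference
# haplotype by p_bar = n_xi/(n_xi + rm*n_xa) = f(p_hat) with
# f(p) = p/(p + rm*(1-p)); the Wald limits of p_hat are mapped through the
# same monotone transform f.

#' Escape-model parameters
#'
#' Bundles the tunable thresholds of the escape classification.
#'
#' @param alpha Significance level of the per-gene confidence interval; the
#'   escape criterion uses the `100*(1-alpha)`\% lower limit (default 0.01,
#'   i.e. a 99\% lower confidence limit).
#' @param rpkm_min Diploid expression floor: the gene must have RPKM >= this
#'   to count as expressed (default 1).
#' @param srpm_low,srpm_high Xi-SRPM thresholds: `[srpm_low, srpm_high)` is
#'   low-level escape, `>= srpm_high` high-level escape (defaults 2 and 5).
#' @return A list of class `escape_params`.
#' @export
escape_params <- function(alpha = 0.01, rpkm_min = 1, srpm_low = 2, srpm_high = 5) {
  stopifnot(alpha > 0, alpha < 1, srpm_low > 0, srpm_low <= srpm_high)
  structure(list(alpha = alpha, rpkm_min = rpkm_min,
                 srpm_low = srpm_low, srpm_high = srpm_high),
            class = "escape_params")
}

#' Binomial proportion estimate of Xi expression
#'
#' `p_hat = n_xi / (n_xi + n_xa)`.
#'
#' @param n_xi,n_xa Allele-specific read counts on the inactive and active X.
#' @return Numeric estimate(s); `NA` where `n_xi + n_xa = 0` (not assessable).
#' @export
estimate_proportion <- function(n_xi, n_xa) {
  n <- n_xi + n_xa
  ifelse(n > 0, n_xi / n, NA_real_)
}

#' Wald confidence interval for a binomial proportion
#'
#' `p_hat +/- z_{alpha/2} * sqrt(p_hat*(1-p_hat)/n)`, with `z_{alpha/2}` the
#' `100*(1-alpha/2)`th percentile of N(0,1) (2.575829... at alpha = 0.01).
#' Limits are returned unclamped: the escape criterion tests the raw lower
#' limit, and clamping to [0,1] happens only before transformation and
#' reporting.
#'
#' @param p_hat Proportion estimate(s) in [0,1].
#' @param n Number(s) of trials, >= 1.
#' @param alpha Significance level in (0,1).
#' @return A list with numeric vectors `lower` and `upper`.
#' @examples
#' wald_ci(0.5, 100, 0.01)
#' @export
wald_ci <- function(p_hat, n, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  stopifnot(all(n >= 1), all(p_hat >= 0 & p_hat <= 1))
  z <- qnorm(1 - alpha / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  list(lower = p_hat - half, upper = p_hat + half)
}

#' Mapping-bias-corrected proportion estimate
#'
#' `p_bar = n_xi / (n_xi + rm * n_xa)`, algebraically equal to
#' `p_hat / (p_hat + rm * (1 - p_hat))`. With rm = 1 (no bias) this is
#' `p_hat`; rm > 1 (bias favouring the Xi-carrying haplotype genome on
#' autosomes) shrinks the estimate.
#'
#' @param n_xi,n_xa Allele-specific read counts.
#' @param rm Mapping-bias ratio, > 0.
#' @return Corrected estimate(s) in [0,1]; `NA` where `n_xi + n_xa = 0`.
#' @export
bias_correct <- function(n_xi, n_xa, rm) {
  if (any(rm <= 0)) stop("rm must be > 0", call. = FALSE)
  ifelse(n_xi + n_xa > 0, n_xi / (n_xi + rm * n_xa), NA_real_)
}

# The bias-correction transform f(p) = p/(p + rm*(1-p)); monotone increasing
# on [0,1] for rm > 0, with f(0)=0 and f(1)=1.
bias_transform <- function(p, rm) p / (p + rm * (1 - p))

#' Bias-corrected confidence limits
#'
#' Computes the Wald limits of the raw proportion, clamps them to [0,1],
#' and maps them through the bias-correction transform
#' `f(p) = p/(p + rm*(1-p))`. Because f is monotone increasing, the order of
#' the limits is preserved and `lower <= p_bar <= upper` always holds.
#'
#' @inheritParams bias_correct
#' @param alpha Significance level (see [wald_ci()]).
#' @return A list with `lower`, `upper` (corrected, in [0,1]),
#'   `raw_lower`, `raw_upper` (unclamped Wald limits of `p_hat`).
#' @export
corrected_ci <- function(n_xi, n_xa, rm, alpha = 0.01) {
  n <- n_xi + n_xa
  stopifnot(all(n >= 1))
  p_hat <- estimate_proportion(n_xi, n_xa)
  ci <- wald_ci(p_hat, n, alpha)
  list(lower = bias_transform(pmin(pmax(ci$lower, 0), 1), rm),
       upper = bias_transform(pmin(pmax(ci$upper, 0), 1), rm),
       raw_lower = ci$lower, raw_upper = ci$upper)
}

#' Fit the escape model to X-linked allelic counts
#'
#' For every X-linked gene, estimates the Xi-expression proportion under the
#' binomial model, corrects it for the experiment's mapping bias, forms
#' bias-corrected Wald confidence limits, and classifies escape status by
#' three criteria: (1) the lower confidence limit of the corrected escape
#' probability exceeds zero, (2) diploid RPKM >= `rpkm_min`, and (3) Xi-SRPM
#' >= `srpm_low` (low-level escape if below `srpm_high`, high-level escape
#' otherwise). Genes with zero allele-specific reads are `not_assessable`;
#' genes failing any criterion are `not_escape`.
#'
#' @param counts An [allelic_counts()] table of X-linked genes.
#' @param genes A [gene_models()] object covering the genes in `counts`;
#'   all must lie on chrX (autosomal genes are never classified).
#' @param lib A [library_stats()] with a defined mapping-bias ratio `rm`.
#' @param params An [escape_params()] bundle.
#' @param rm Optional override of `lib$rm`.
#' @return An object of class `xci_escape`: a fit whose per-gene table
#'   (see [as.data.frame.xci_escape()]) carries `gene_id`, `n_xi`, `n_xa`,
#'   `n`, `p_hat`, `p_bar`, `ci_lower`, `ci_upper`, `rpkm`, `xi_srpm`,
#'   `xa_srpm`, the criterion flags `ci_positive`, `expressed`,
#'   `srpm_low_met`, `srpm_high_met`, and `category` (one of
#'   `not_assessable`, `not_escape`, `low_escape`, `high_escape`).
#' @seealso [classify_escape()] for the scalar interface,
#'   [replicate_concordance()] for comparing replicate fits.
#' @export
xci_escape <- function(counts, genes, lib, params = escape_params(), rm = NULL) {
  stopifnot(inherits(counts, "allelic_counts"), inherits(genes, "gene_models"),
            inherits(lib, "library_stats"), inherits(params, "escape_params"))
  rm <- rm %||% lib$rm
  if (is.null(rm) || is.na(rm) || rm <= 0) {
    stop("a positive mapping-bias ratio rm is required (from lib or the rm argument)",
         call. = FALSE)
  }
  idx <- match(counts$gene_id, genes$genes$gene_id)
  if (anyNA(idx)) {
    stop("gene model(s) missing for: ",
         paste(counts$gene_id[is.na(idx)][1:min(5, sum(is.na(idx)))],
               collapse = ", "), call. = FALSE)
  }
  gchrom <- genes$genes$chrom[idx]
  if (any(!is_x_chrom(gchrom))) {
    stop("non-X gene(s) passed to the escape model: ",
         paste(counts$gene_id[!is_x_chrom(gchrom)][1:min(5, sum(!is_x_chrom(gchrom)))],
               collapse = ", "), call. = FALSE)
  }
  n_xi <- counts$n_xi; n_xa <- counts$n_xa
  n <- n_xi + n_xa
  assessable <- n > 0
  p_hat <- estimate_proportion(n_xi, n_xa)
  p_bar <- bias_correct(n_xi, n_xa, rm)
  lower <- upper <- raw_lower <- rep(NA_real_, length(n))
  if (any(assessable)) {
    ci <- corrected_ci(n_xi[assessable], n_xa[assessable], rm, params$alpha)
    lower[assessable] <- ci$lower
    upper[assessable] <- ci$upper
    raw_lower[assessable] <- ci$raw_lower
  }
  gene_rpkm <- rpkm(counts$n_diploid, genes$genes$exonic_length_bp[idx],
                    lib$total_unique_hq)
  xi_srpm <- srpm(n_xi, lib$total_unique_hq)
  xa_srpm <- srpm(n_xa, lib$total_unique_hq)
  ci_positive <- !is.na(raw_lower) & raw_lower > 0
  expressed <- gene_rpkm >= params$rpkm_min
  srpm_low_met <- xi_srpm >= params$srpm_low
  srpm_high_met <- xi_srpm >= params$srpm_high
  category <- rep("not_escape", length(n))
  escape <- ci_positive & expressed & srpm_low_met
  category[escape & !srpm_high_met] <- "low_escape"
  category[escape & srpm_high_met] <- "high_escape"
  category[!assessable] <- "not_assessable"
  calls <- data.frame(
    gene_id = counts$gene_id, n_xi = n_xi, n_xa = n_xa, n = n,
    p_hat = p_hat, p_bar = p_bar, ci_lower = lower, ci_upper = upper,
    rpkm = gene_rpkm, xi_srpm = xi_srpm, xa_srpm = xa_srpm,
    ci_positive = ci_positive, expressed = expressed,
    srpm_low_met = srpm_low_met, srpm_high_met = srpm_high_met,
    category = category, stringsAsFactors = FALSE
  )
  structure(list(calls = calls, params = params, rm = rm,
                 experiment_id = lib$experiment_id,
                 xi_haplotype = lib$xi_haplotype,
                 total_unique_hq = lib$total_unique_hq),
            class = "xci_escape")
}

#' Classify a single gene's escape status
#'
#' Scalar convenience wrapper around [xci_escape()] for one gene.
#'
#' @inheritParams xci_escape
#' @param gene_id The gene to classify (must be X-linked in `genes`).
#' @param n_xi,n_xa,n_diploid Its allelic counts.
#' @return A one-row data.frame of the per-gene call fields.
#' @export
classify_escape <- function(gene_id, n_xi, n_xa, n_diploid, genes, lib,
                            params = escape_params(), rm = NULL) {
  fit <- xci_escape(allelic_counts(gene_id, n_xi, n_xa, n_diploid),
                    genes, lib, params, rm)
  fit$calls
}

#' Squared Pearson correlation of Xi-SRPM between replicate fits
#'
#' Biological replicates are analyzed separately; their Xi-SRPM values
#' should be highly correlated (R^2 > 0.9 in well-behaved experiments).
#' Computes R^2 across genes shared between the two fits, restricted to
#' genes with nonzero Xi-SRPM in at least one replicate (silenced genes,
#' identically zero in both, carry no information about concordance).
#'
#' @param fit1,fit2 Two [xci_escape()] fits (or their call data.frames).
#' @param nonzero_only Keep only genes with Xi-SRPM > 0 in at least one
#'   replicate (default TRUE).
#' @return The squared Pearson correlation, in [0,1].
#' @export
replicate_concordance <- function(fit1, fit2, nonzero_only = TRUE) {
  c1 <- if (inherits(fit1, "xci_escape")) fit1$calls else fit1
  c2 <- if (inherits(fit2, "xci_escape")) fit2$calls else fit2
  shared <- intersect(c1$gene_id, c2$gene_id)
  x <- c1$xi_srpm[match(shared, c1$gene_id)]
  y <- c2$xi_srpm[match(shared, c2$gene_id)]
  if (nonzero_only) {
    keep <- x > 0 | y > 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3L) stop("fewer than 3 shared genes with defined Xi-SRPM",
                           call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Xi-SRPM constant in a replicate: R^2 undefined", call. = FALSE)
  }
  cor(x, y)^2
}
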