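# S3 methods for the xci_escape fit.

#' @export
print.xci_escape <- function(x, ...) {
  cat("X-inactivation escape model fit\n")
  cat("  experiment:", x$experiment_id,
      " (Xi =", paste0(x$xi_haplotype, ")"), "\n")
  cat("  genes:", nrow(x$calls),
      " rm:", signif(x$rm, 4),
      " alpha:", x$params$alpha, "\n")
  tab <- table(factor(x$calls$category,
                      levels = c("not_assessable", "not_escape",
                                 "low_escape", "high_escape")))
  cat("  categories:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Summarize an escape-model fit
#'
#' @param object An [xci_escape()] fit.
#' @param ... Unused.
#' @return A list of class `summary.xci_escape` with category counts, the
#'   escape-gene table (low + high escape), and the fit's parameters.
#' @export
summary.xci_escape <- function(object, ...) {
  calls <- object$calls
  counts <- table(factor(calls$category,
                         levels = c("not_assessable", "not_escape",
                                    "low_escape", "high_escape")))
  esc <- calls[calls$category %in% c("low_escape", "high_escape"), , drop = FALSE]
  esc <- esc[order(-esc$xi_srpm), , drop = FALSE]
  structure(list(experiment_id = object$experiment_id,
                 xi_haplotype = object$xi_haplotype,
                 rm = object$rm, params = object$params,
                 category_counts = counts, escape_genes = esc),
            class = "summary.xci_escape")
}

#' @export
print.summary.xci_escape <- function(x, ...) {
  cat("X-inactivation escape calls:", x$experiment_id, "\n")
  cat("  Xi haplotype:", x$xi_haplotype, "  rm:", signif(x$rm, 4), "\n")
  cat("  thresholds: alpha", x$params$alpha,
      "| RPKM >=", x$params$rpkm_min,
      "| Xi-SRPM low/high", x$params$srpm_low, "/", x$params$srpm_high, "\n\n")
  print(x$category_counts)
  if (nrow(x$escape_genes) > 0L) {
    cat("\nEscape genes (by Xi-SRPM):\n")
    cols <- c("gene_id", "n_xi", "n_xa", "p_bar", "ci_lower", "rpkm",
              "xi_srpm", "category")
    df <- x$escape_genes[, cols]
    df$p_bar <- signif(df$p_bar, 3)
    df$ci_lower <- signif(df$ci_lower, 3)
    df$rpkm <- signif(df$rpkm, 3)
    df$xi_srpm <- signif(df$xi_srpm, 3)
    print(utils::head(df, 20L), row.names = FALSE)
    if (nrow(df) > 20L) cat("  ...", nrow(df) - 20L, "more\n")
  }
  invisible(x)
}

#' @export
as.data.frame.xci_escape <- function(x, ...) x$calls

#' Extract corrected escape-probability estimates
#'
#' @param object An [xci_escape()] fit.
#' @param ... Unused.
#' @return Named vector of per-gene bias-corrected estimates `p_bar`.
#' @export
coef.xci_escape <- function(object, ...) {
  setNames(object$calls$p_bar, object$calls$gene_id)
}

#' Corrected confidence limits of the escape probability
#'
#' @param object An [xci_escape()] fit.
#' @param parm Optional gene ids to subset.
#' @param level Ignored; the fit's own `1 - alpha` level is reported (the
#'   limits are part of the fit, not recomputed).
#' @param ... Unused.
#' @return Two-column matrix of corrected lower and upper limits.
#' @export
confint.xci_escape <- function(object, parm = NULL, level = NULL, ...) {
  calls <- object$calls
  if (!is.null(parm)) calls <- calls[calls$gene_id %in% parm, , drop = FALSE]
  out <- cbind(lower = calls$ci_lower, upper = calls$ci_upper)
  rownames(out) <- calls$gene_id
  out
}

#' @export
fitted.xci_escape <- function(object, ...) {
  setNames(object$calls$p_bar * object$calls$n, object$calls$gene_id)
}

#' Pearson residuals of the binomial escape model
#'
#' `(n_xi - n*p_bar) / sqrt(n*p_bar*(1-p_bar))` per assessable gene; NA for
#' genes with n = 0 or a degenerate fitted proportion.
#'
#' @param object An [xci_escape()] fit.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.xci_escape <- function(object, ...) {
  calls <- object$calls
  mu <- calls$n * calls$p_bar
  v <- calls$n * calls$p_bar * (1 - calls$p_bar)
  r <- ifelse(calls$n > 0 & v > 0, (calls$n_xi - mu) / sqrt(v), NA_real_)
  setNames(r, calls$gene_id)
}

#' Simulate allelic counts from a fitted escape model
#'
#' Draws `n_xi* ~ Binomial(n, p_bar)` per gene, i.e. new Xi read counts at
#' the fitted (bias-corrected) proportions with the observed totals.
#'
#' @param object An [xci_escape()] fit.
#' @param nsim Number of simulated datasets.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data.frame with one column per simulation, rows named by gene.
#' @export
simulate.xci_escape <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  calls <- object$calls
  sims <- replicate(nsim, {
    out <- rep(NA_integer_, nrow(calls))
    ok <- calls$n > 0
    out[ok] <- rbinom(sum(ok), size = calls$n[ok], prob = calls$p_bar[ok])
    out
  })
  sims <- as.data.frame(sims, stringsAsFactors = FALSE)
  names(sims) <- paste0("sim_", seq_len(nsim))
  rownames(sims) <- calls$gene_id
  sims
}

#' Plot an escape-model fit
#'
#' Scatter of the corrected escape probability `p_bar` against Xi-SRPM
#' (log10 axis), coloured by call category, with the Xi-SRPM thresholds
#' marked. Genes with zero Xi reads sit at the axis floor.
#'
#' @param x An [xci_escape()] fit.
#' @param ... Passed to [plot.default()].
#' @export
plot.xci_escape <- function(x, ...) {
  calls <- x$calls[x$calls$n > 0, , drop = FALSE]
  cols <- c(not_escape = "grey60", low_escape = "orange2",
            high_escape = "red3", not_assessable = "grey90")
  floor_srpm <- x$params$srpm_low / 20
  xs <- pmax(calls$xi_srpm, floor_srpm)
  plot.default(xs, calls$p_bar, log = "x",
               col = cols[calls$category], pch = 19, cex = 0.7,
               xlab = "Xi-SRPM (log scale)",
               ylab = expression(bar(p) ~ "(corrected escape probability)"),
               main = paste("Escape calls:", x$experiment_id), ...)
  abline(v = c(x$params$srpm_low, x$params$srpm_high), lty = 2, col = "grey40")
  legend("topleft", legend = names(cols)[1:3], col = cols[1:3], pch = 19,
         bty = "n", cex = 0.8)
  invisible(x)
}
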