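# Small in-code fixtures shared across the suite.

# A 1 kb gene on chrX plus a library sized so that srpm(n) == n and
# rpkm(n_diploid) == n_diploid / 10: convenient round numbers for
# threshold tests.
fix_gene_x <- function(gene_id = "geneX", len = 1000L) {
  gene_models(data.frame(gene_id = gene_id, chrom = "chrX",
                         start = 0L, end = len, strand = "+",
                         stringsAsFactors = FALSE))
}

fix_lib <- function(total = 1e7, rm = 1, xi = "spretus") {
  library_stats("fix", total_raw = total * 2, total_unique_hq = total,
                na0 = rm * 1e5, na1 = 1e5, xi_haplotype = xi)
}

# Write a snp TSV fixture; returns the path.
write_snp_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent brute-force binomial tail oracle: log-factorial pmf summation,
# no calls into pbinom.
brute_tails <- function(k, n, p0) {
  pmf <- function(j) exp(lgamma(n + 1) - lgamma(j + 1) - lgamma(n - j + 1) +
                           j * log(p0) + (n - j) * log1p(-p0))
  list(p_upper = sum(vapply(k:n, pmf, 0)),
       p_lower = sum(vapply(0:k, pmf, 0)))
}

# Subset an allelic_counts table keeping its class.
subset_counts <- function(counts, keep) {
  out <- counts[keep, , drop = FALSE]
  class(out) <- class(counts)
  out
}

# X-linked subset of a sim_experiment's counts.
x_counts <- function(sim) {
  idx <- match(sim$counts$gene_id, sim$truth$gene_id)
  subset_counts(sim$counts, sim$truth$chrom[idx] == "chrX")
}

fit_sim <- function(sim, params = escape_params()) {
  xci_escape(x_counts(sim), sim$genes, sim$lib, params)
}
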