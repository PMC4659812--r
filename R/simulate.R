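# Synthetic hybrid-genome data with known ground truth. The generator
# emulates the skewed-XCI F1 design: X-linked genes are a mixture of
# silenced, low-escape and high-escape states with known Xi-expression
# proportions; autosomal genes are balanced (true proportion 0.5); a
# haplotype-specific read-thinning step injects the mapping-bias ratio
# rm_true; replicates share one ground truth with log-scale depth noise.
# Counts, not reads, are generated (a toy read emitter exercises the
# read-assignment stage separately at small scale).

#' Simulation configuration
#'
#' Defaults define the generator's standard conditions: a 2e7-read library,
#' allele-informative capture probability 0.2, mapping bias 1.1, 300 X-linked
#' and 700 autosomal genes with 10% low-escape and 10% high-escape X genes
#' (the remainder silenced), per-gene expected diploid depth
#' lognormal(log(1000), 0.6) — the assessable gene set being expressed genes
#' carrying exonic SNPs — and replicate depth noise of 0.1 on the log scale.
#'
#' @param seed Integer RNG seed.
#' @param n_genes_x,n_genes_autosomal Gene counts.
#' @param frac_low_escape,frac_high_escape True-state mixture on X; the
#'   remainder is silenced. Must sum to <= 1.
#' @param true_pi_low,true_pi_high Ranges (length-2) of the true Xi
#'   proportion for low- and high-escape genes.
#' @param silenced_leak True Xi proportion of silenced genes (default 0).
#' @param expression_meanlog,expression_sdlog Lognormal parameters of the
#'   per-gene expected diploid exonic read depth.
#' @param snp_capture_prob Probability that a diploid exonic read overlaps a
#'   SNP and is allele-informative.
#' @param rm_true Injected mapping-bias ratio: reads of the Xa-carrying
#'   haplotype are kept with probability `1/rm_true` (or the Xi-carrying
#'   haplotype with probability `rm_true` when `rm_true < 1`).
#' @param replicate_noise_sd Log-scale depth noise between replicates.
#' @param library_size Total high-MAPQ uniquely mapped reads.
#' @param xi_haplotype Which haplotype carries the Xi.
#' @param peak_count,peak_mean_reads,peak_background_p,peak_effect_fraction,
#'   peak_shift_high,peak_shift_low ChIP simulation knobs: number of X
#'   peaks, mean allele-specific reads per peak, background BL6 proportion,
#'   fraction of peaks with a true allelic preference, and the shifted
#'   proportions those draw from (split evenly between high and low).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_x = 300L, n_genes_autosomal = 700L,
                       frac_low_escape = 0.1, frac_high_escape = 0.1,
                       true_pi_low = c(0.05, 0.15),
                       true_pi_high = c(0.20, 0.50),
                       silenced_leak = 0,
                       expression_meanlog = log(1000),
                       expression_sdlog = 0.6,
                       snp_capture_prob = 0.2,
                       rm_true = 1.1,
                       replicate_noise_sd = 0.1,
                       library_size = 2e7,
                       xi_haplotype = c("spretus", "bl6"),
                       peak_count = 200L, peak_mean_reads = 30,
                       peak_background_p = 0.7,
                       peak_effect_fraction = 0.2,
                       peak_shift_high = 0.95, peak_shift_low = 0.2) {
  xi_haplotype <- match.arg(xi_haplotype)
  if (frac_low_escape < 0 || frac_high_escape < 0 ||
      frac_low_escape + frac_high_escape > 1) {
    stop("escape fractions must be >= 0 and sum to <= 1", call. = FALSE)
  }
  stopifnot(rm_true > 0, library_size > 0, snp_capture_prob >= 0,
            snp_capture_prob <= 1, silenced_leak >= 0, silenced_leak <= 1,
            peak_background_p > 0, peak_background_p < 1,
            peak_effect_fraction >= 0, peak_effect_fraction <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_genes_x, "X +",
      x$n_genes_autosomal, "autosomal genes | library",
      format(x$library_size, big.mark = ","), "| rm_true", x$rm_true, "\n")
  invisible(x)
}

# Draw the shared ground truth: gene structure, true states, true Xi
# proportions, expected depths.
draw_ground_truth <- function(config) {
  nx <- config$n_genes_x; na <- config$n_genes_autosomal
  n <- nx + na
  gene_id <- c(sprintf("gx_%04d", seq_len(nx)), sprintf("ga_%04d", seq_len(na)))
  chrom <- c(rep("chrX", nx),
             paste0("chr", rep_len(1:19, na)))
  n_low <- round(config$frac_low_escape * nx)
  n_high <- round(config$frac_high_escape * nx)
  state_x <- sample(c(rep("low_escape", n_low), rep("high_escape", n_high),
                      rep("silenced", nx - n_low - n_high)))
  true_state <- c(state_x, rep("autosomal", na))
  true_pi <- numeric(n)
  true_pi[true_state == "silenced"] <- config$silenced_leak
  true_pi[true_state == "low_escape"] <-
    runif(sum(true_state == "low_escape"),
          config$true_pi_low[1], config$true_pi_low[2])
  true_pi[true_state == "high_escape"] <-
    runif(sum(true_state == "high_escape"),
          config$true_pi_high[1], config$true_pi_high[2])
  true_pi[true_state == "autosomal"] <- 0.5
  depth <- rlnorm(n, config$expression_meanlog, config$expression_sdlog)
  exon_len <- round(runif(n, 500, 5000))
  # lay genes along each chromosome without overlap
  start <- stats::ave(exon_len, chrom, FUN = function(l) {
    cumsum(c(0, utils::head(l, -1) + 10000L))
  })
  truth <- data.frame(gene_id = gene_id, chrom = chrom,
                      true_state = true_state, true_pi = true_pi,
                      expected_depth = depth, exon_start = start,
                      exonic_length_bp = exon_len, stringsAsFactors = FALSE)
  truth
}

truth_gene_models <- function(truth) {
  gene_models(data.frame(gene_id = truth$gene_id, chrom = truth$chrom,
                         start = truth$exon_start,
                         end = truth$exon_start + truth$exonic_length_bp,
                         strand = "+", stringsAsFactors = FALSE))
}

# Sample one experiment's counts from a ground truth.
sample_counts <- function(truth, config, depth_multiplier = 1) {
  n <- nrow(truth)
  n_diploid <- rpois(n, truth$expected_depth * depth_multiplier)
  informative <- rbinom(n, n_diploid, config$snp_capture_prob)
  n_xi_raw <- rbinom(n, informative, truth$true_pi)
  n_xa_raw <- informative - n_xi_raw
  # haplotype-specific thinning implements the mapping bias
  if (config$rm_true >= 1) {
    n_xi <- n_xi_raw
    n_xa <- rbinom(n, n_xa_raw, 1 / config$rm_true)
  } else {
    n_xi <- rbinom(n, n_xi_raw, config$rm_true)
    n_xa <- n_xa_raw
  }
  allelic_counts(truth$gene_id, n_xi, n_xa, n_diploid)
}

#' Simulate one allele-resolved RNA-seq experiment
#'
#' Per gene, a diploid exonic depth is drawn (Poisson around a lognormal
#' expectation), thinned to allele-informative reads by `snp_capture_prob`;
#' Xi-assigned reads are Binomial(informative, true_pi), and haplotype-
#' specific thinning injects the mapping bias `rm_true`. Library statistics
#' (NA0/NA1 and hence rm) are derived from the generated autosomal counts,
#' exactly as the pipeline would compute them on real data.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param experiment_id Label for the library.
#' @return A list of class `sim_experiment`: `counts` ([allelic_counts()]
#'   for all genes), `genes` ([gene_models()]), `lib` ([library_stats()]),
#'   `truth` (per-gene ground-truth data.frame plus attribute `rm_true`),
#'   and `config`.
#' @export
simulate_rnaseq_experiment <- function(config = sim_config(),
                                       seed = config$seed,
                                       experiment_id = "sim_rnaseq") {
  set.seed(seed)
  truth <- draw_ground_truth(config)
  counts <- sample_counts(truth, config)
  build_experiment(counts, truth, config, experiment_id)
}

build_experiment <- function(counts, truth, config, experiment_id) {
  auto <- !is_x_chrom(truth$chrom)
  na0 <- sum(counts$n_xi[auto])
  na1 <- sum(counts$n_xa[auto])
  lib <- library_stats(experiment_id,
                       total_raw = round(config$library_size / 0.75),
                       total_unique_hq = config$library_size,
                       na0 = na0, na1 = na1,
                       xi_haplotype = config$xi_haplotype)
  attr(truth, "rm_true") <- config$rm_true
  structure(list(counts = counts, genes = truth_gene_models(truth),
                 lib = lib, truth = truth, config = config),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment:", x$lib$experiment_id, "-", nrow(x$counts), "genes,",
      "rm =", signif(x$lib$rm, 4),
      "(injected", paste0(attr(x$truth, "rm_true"), ")"), "\n")
  invisible(x)
}

#' Simulate biological replicates sharing one ground truth
#'
#' Replicates share gene structure, true states and true Xi proportions;
#' each replicate's per-gene depth is perturbed by a lognormal factor with
#' log-sd `replicate_noise_sd` before count sampling, emulating biological
#' replicate variability.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates (>= 2).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A list of `sim_experiment` objects sharing one `truth`.
#' @export
simulate_replicates <- function(config = sim_config(), n_reps = 2L,
                                seed = config$seed) {
  stopifnot(n_reps >= 2)
  set.seed(seed)
  truth <- draw_ground_truth(config)
  lapply(seq_len(n_reps), function(r) {
    mult <- exp(stats::rnorm(nrow(truth), 0, config$replicate_noise_sd))
    counts <- sample_counts(truth, config, depth_multiplier = mult)
    build_experiment(counts, truth, config, sprintf("sim_rnaseq_rep%d", r))
  })
}

#' Simulate an allele-resolved ChIP-seq peak set on the X
#'
#' `peak_effect_fraction` of peaks draw their BL6-SNP read counts at a
#' shifted proportion (split evenly between `peak_shift_high` and
#' `peak_shift_low`), the rest at `peak_background_p`; per-peak totals are
#' Poisson around `peak_mean_reads`.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A list of class `sim_chip`: `peaks` ([peak_regions()]),
#'   `truth` (per-peak true proportion and preference label), `config`, and
#'   `lib_total_mapped`.
#' @export
simulate_chip_experiment <- function(config = sim_config(),
                                     seed = config$seed) {
  set.seed(seed)
  k <- config$peak_count
  n_eff <- round(config$peak_effect_fraction * k)
  n_hi <- n_eff %/% 2L
  n_lo <- n_eff - n_hi
  p_true <- sample(c(rep(config$peak_shift_high, n_hi),
                     rep(config$peak_shift_low, n_lo),
                     rep(config$peak_background_p, k - n_eff)))
  preference <- ifelse(p_true > config$peak_background_p, "bl6",
                ifelse(p_true < config$peak_background_p, "spretus", "none"))
  total <- rpois(k, config$peak_mean_reads)
  n_bl <- rbinom(k, total, p_true)
  start <- cumsum(c(0L, rep(2000L, k - 1L)))
  peaks <- peak_regions(sprintf("px_%04d", seq_len(k)), "chrX",
                        start, start + 500L, n_bl, total - n_bl)
  truth <- data.frame(peak_id = peaks$peak_id, true_p = p_true,
                      true_preference = preference, stringsAsFactors = FALSE)
  structure(list(peaks = peaks, truth = truth, config = config,
                 lib_total_mapped = config$library_size),
            class = "sim_chip")
}

#' Simulate toy reads over a synthetic chromosome
#'
#' Small-scale end-to-end exercise of the read-assignment stage: builds a
#' random reference sequence and SNP catalog, substitutes the alternate
#' haplotype, and emits fixed-length ungapped reads drawn from either
#' haplotype at random positions with known origin.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length in bp.
#' @param chrom_len Chromosome length in bp.
#' @param n_snps Number of catalog SNPs.
#' @param chrom Chromosome name.
#' @param frac_low_mapq Fraction of reads given MAPQ below 30.
#' @param seed RNG seed.
#' @return A list: `reference` (character sequence), `snps`
#'   ([snp_catalog()]), `reads` ([aligned_reads()]), and `truth` (per-read
#'   haplotype of origin, `"bl6"` or `"spretus"`).
#' @export
simulate_toy_reads <- function(n_reads = 500L, read_len = 36L,
                               chrom_len = 5000L, n_snps = 50L,
                               chrom = "chrX", frac_low_mapq = 0.1,
                               seed = 1L) {
  set.seed(seed)
  ref <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
               collapse = "")
  pos <- sort(sample(seq_len(chrom_len), n_snps))
  ref_base <- substring(ref, pos, pos)
  alt_base <- vapply(ref_base, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, "")
  snps <- snp_catalog(rep(chrom, n_snps), pos, ref_base, alt_base)
  alt_seq <- substitute_pseudo_genome(ref, snps, chrom)
  origin <- sample(c("bl6", "spretus"), n_reads, replace = TRUE)
  start0 <- sample.int(chrom_len - read_len + 1L, n_reads, replace = TRUE) - 1L
  seqs <- ifelse(origin == "bl6",
                 substring(ref, start0 + 1L, start0 + read_len),
                 substring(alt_seq, start0 + 1L, start0 + read_len))
  mapq <- ifelse(runif(n_reads) < frac_low_mapq,
                 sample(0:29, n_reads, replace = TRUE), 60L)
  reads <- aligned_reads(sprintf("r%05d", seq_len(n_reads)), chrom, start0,
                         seqs, mapq)
  list(reference = ref, snps = snps, reads = reads,
       truth = data.frame(read_id = reads$read_id, origin = origin,
                          stringsAsFactors = FALSE))
}
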