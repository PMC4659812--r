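# Pipeline entry points: each run_* function reads the standard input
# formats, executes one analysis stage, writes its outputs into a directory
# and drops a run manifest (command, parameters, input digests, package
# version, timestamp, seed) so runs are auditable and deterministic runs
# reproducible. A thin Rscript dispatcher over these functions is installed
# at inst/scripts/xci.R.

write_manifest <- function(out_dir, command, params = list(),
                           inputs = character(), seed = NULL) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(normalizePath(inputs)))
  } else list()
  manifest <- list(command = command,
                   package = "xciescape",
                   version = as.character(packageVersion("xciescape")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed, params = params, input_md5 = digests)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

ensure_dir <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  out_dir
}

#' Run the SNP-catalog summary stage
#'
#' Reads a SNP table and gene models, summarizes SNP locations and genes
#' with exonic SNPs, and writes `snp_summary.tsv` (three rows: X,
#' autosomes, both) plus a manifest.
#'
#' @param snp_path SNP table (TSV or VCF-like; see [read_snp_table()]).
#' @param genes_path Gene models (BED12 or exon TSV).
#' @param out_dir Output directory.
#' @return The [snp_location_summary()], invisibly.
#' @export
run_snp_summary <- function(snp_path, genes_path, out_dir) {
  ensure_dir(out_dir)
  snps <- read_snp_table(snp_path)
  genes <- read_gene_models(genes_path)
  summ <- summarize_snp_catalog(snps, genes)
  write_tsv(as.data.frame(summ), file.path(out_dir, "snp_summary.tsv"))
  write_manifest(out_dir, "snp_summary", inputs = c(snp_path, genes_path))
  invisible(summ)
}

#' Run the read-assignment stage
#'
#' Reads aligned-read summaries (SAM or TSV) and a SNP table, segregates
#' retained reads into allelic categories, and writes `assignments.tsv`
#' (read_id, category) and `segregation.tsv` (the per-experiment
#' percentage table) plus a manifest.
#'
#' @param reads_path SAM file or TSV of [aligned_reads()] fields.
#' @param snp_path SNP table.
#' @param out_dir Output directory.
#' @param mapq_min MAPQ retention threshold (default 30).
#' @param experiment_id Label for the segregation row.
#' @return The `allele_assignments` table, invisibly.
#' @export
run_assign <- function(reads_path, snp_path, out_dir, mapq_min = 30L,
                       experiment_id = "experiment") {
  ensure_dir(out_dir)
  reads <- if (grepl("\\.sam$", reads_path)) {
    read_sam_minimal(reads_path)
  } else {
    df <- read_tsv_strict(reads_path,
                          c("read_id", "chrom", "start", "sequence", "mapq"))
    aligned_reads(df$read_id, df$chrom, df$start, df$sequence, df$mapq,
                  if ("unique" %in% names(df)) df$unique else TRUE)
  }
  snps <- read_snp_table(snp_path)
  asg <- assign_reads(reads, snps, mapq_min)
  write_tsv(asg[, c("read_id", "category")],
            file.path(out_dir, "assignments.tsv"))
  write_tsv(tabulate_assignments(asg, experiment_id),
            file.path(out_dir, "segregation.tsv"))
  write_manifest(out_dir, "assign", params = list(mapq_min = mapq_min),
                 inputs = c(reads_path, snp_path))
  invisible(asg)
}

#' Run the escape-calling stage
#'
#' Reads per-gene allelic counts, gene models and library statistics, fits
#' the escape model to the X-linked genes (computing rm from the autosomal
#' counts when the library sidecar does not provide NA0/NA1), and writes
#' `escape_calls.tsv` (one row per X gene with estimates, limits, metrics,
#' criterion flags and category) and `escape_summary.json` (category
#' counts) plus a manifest.
#'
#' @param counts_path Allelic counts TSV (X and autosomal genes).
#' @param genes_path Gene models (BED12 or exon TSV).
#' @param library_path Library-statistics JSON.
#' @param out_dir Output directory.
#' @param alpha,rpkm_min,srpm_low,srpm_high Escape thresholds
#'   (see [escape_params()]).
#' @return The [xci_escape()] fit, invisibly.
#' @export
run_escape <- function(counts_path, genes_path, library_path, out_dir,
                       alpha = 0.01, rpkm_min = 1, srpm_low = 2,
                       srpm_high = 5) {
  ensure_dir(out_dir)
  counts <- read_allelic_counts(counts_path)
  genes <- read_gene_models(genes_path)
  lib <- read_library_stats(library_path)
  chrom <- genes$genes$chrom[match(counts$gene_id, genes$genes$gene_id)]
  if (anyNA(chrom)) stop("gene model(s) missing for counts", call. = FALSE)
  on_x <- is_x_chrom(chrom)
  if (is.na(lib$rm)) {
    auto <- counts[!on_x, , drop = FALSE]
    class(auto) <- class(counts)
    lib$rm <- mapping_bias_ratio(auto)
  }
  x_counts <- counts[on_x, , drop = FALSE]
  class(x_counts) <- class(counts)
  fit <- xci_escape(x_counts, genes, lib,
                    escape_params(alpha, rpkm_min, srpm_low, srpm_high))
  write_tsv(fit$calls, file.path(out_dir, "escape_calls.tsv"))
  counts_tab <- as.list(table(factor(fit$calls$category,
                                     levels = c("not_assessable", "not_escape",
                                                "low_escape", "high_escape"))))
  jsonlite::write_json(
    list(experiment_id = lib$experiment_id, rm = fit$rm,
         xi_haplotype = lib$xi_haplotype, categories = counts_tab),
    file.path(out_dir, "escape_summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "escape",
                 params = list(alpha = alpha, rpkm_min = rpkm_min,
                               srpm_low = srpm_low, srpm_high = srpm_high),
                 inputs = c(counts_path, genes_path, library_path))
  invisible(fit)
}

#' Run the allele-specific peak classification stage
#'
#' Reads a peak table, estimates the X allelic background from the X-linked
#' peaks, classifies every X peak, and writes `peak_calls.tsv` and
#' `peak_summary.tsv` (Xa/Xi-labelled category counts) plus a manifest.
#'
#' @param peaks_path Combined peak TSV, or BED when `counts_path` is given.
#' @param library_path Library-statistics JSON (provides total mapped reads
#'   and the Xi orientation).
#' @param out_dir Output directory.
#' @param counts_path Optional separate per-peak counts TSV.
#' @param alpha_pref,alpha_both Classification thresholds
#'   (see [classify_peaks()]).
#' @return The `peak_allele_calls` object, invisibly.
#' @export
run_chip <- function(peaks_path, library_path, out_dir, counts_path = NULL,
                     alpha_pref = 0.05, alpha_both = 0.25) {
  ensure_dir(out_dir)
  peaks <- read_peak_table(peaks_path, counts_path)
  lib <- read_library_stats(library_path)
  on_x <- is_x_chrom(peaks$chrom)
  if (!any(on_x)) stop("no X-linked peaks in input", call. = FALSE)
  x_peaks <- peaks[on_x, , drop = FALSE]
  class(x_peaks) <- class(peaks)
  bg <- estimate_x_background(x_peaks)
  calls <- classify_peaks(x_peaks, bg, lib$total_unique_hq,
                          alpha_pref, alpha_both)
  write_tsv(calls$calls, file.path(out_dir, "peak_calls.tsv"))
  write_tsv(summarize_peak_calls(calls, lib$xi_haplotype,
                                 n_total_peaks = nrow(peaks),
                                 sample_id = lib$experiment_id),
            file.path(out_dir, "peak_summary.tsv"))
  write_manifest(out_dir, "chip",
                 params = list(alpha_pref = alpha_pref,
                               alpha_both = alpha_both),
                 inputs = c(peaks_path, library_path,
                            if (!is.null(counts_path)) counts_path))
  invisible(calls)
}

#' Run the simulation stage
#'
#' Generates a synthetic RNA-seq experiment and a synthetic ChIP peak set
#' under one configuration and writes their fixture files (the exact
#' formats the other stages read) plus a manifest.
#'
#' @param out_dir Output directory.
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return Invisibly, a list with the two simulation objects.
#' @export
run_simulate <- function(out_dir, config = sim_config(), seed = config$seed) {
  ensure_dir(out_dir)
  rna <- simulate_rnaseq_experiment(config, seed = seed)
  chip <- simulate_chip_experiment(config, seed = seed + 1L)
  write_fixtures(rna, out_dir)
  write_fixtures(chip, out_dir)
  write_manifest(out_dir, "simulate",
                 params = unclass(config)[setdiff(names(config), "seed")],
                 seed = seed)
  invisible(list(rnaseq = rna, chip = chip))
}
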