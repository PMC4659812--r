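# Table readers/writers for the pipeline's exchange formats. All tables are
# header-ful TSVs; BED intervals are 0-based half-open; library statistics
# travel as a JSON sidecar.

#' Read and write per-gene allelic count tables
#'
#' TSV with header columns `gene_id`, `n_xi`, `n_xa`, `n_diploid`.
#'
#' @param path File path.
#' @return [read_allelic_counts()]: an [allelic_counts()] table.
#' @export
read_allelic_counts <- function(path) {
  df <- read_tsv_strict(path, c("gene_id", "n_xi", "n_xa", "n_diploid"))
  allelic_counts(df$gene_id, df$n_xi, df$n_xa, df$n_diploid)
}

#' @rdname read_allelic_counts
#' @param counts An [allelic_counts()] table.
#' @export
write_allelic_counts <- function(counts, path) {
  stopifnot(inherits(counts, "allelic_counts"))
  write_tsv(counts, path)
}

#' Read and write library statistics as JSON
#'
#' @param path File path.
#' @return [read_library_stats()]: a [library_stats()] object.
#' @export
read_library_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  library_stats(x$experiment_id, x$total_raw, x$total_unique_hq,
                na0 = x$na0 %||% NA_real_, na1 = x$na1 %||% NA_real_,
                xi_haplotype = x$xi_haplotype %||% "spretus")
}

#' @rdname read_library_stats
#' @param lib A [library_stats()] object.
#' @export
write_library_stats <- function(lib, path) {
  stopifnot(inherits(lib, "library_stats"))
  jsonlite::write_json(unclass(lib)[c("experiment_id", "total_raw",
                                      "total_unique_hq", "na0", "na1",
                                      "xi_haplotype")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Minimal BED reader: columns chrom, start, end and optional name; track
#' and comment lines are skipped. Coordinates stay 0-based half-open.
#'
#' @param path BED file path.
#' @return A data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("no intervals in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) stop("BED lines need >= 3 fields", call. = FALSE)
  data.frame(
    chrom = normalize_chrom(vapply(fields, `[[`, "", 1L)),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    name = vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

#' Read and write peak tables
#'
#' Either a combined 6-column TSV (`peak_id`, `chrom`, `start`, `end`,
#' `n_bl`, `n_sp`) or a BED of intervals plus a separate counts TSV
#' (`peak_id`, `n_bl`, `n_sp`) joined on peak id.
#'
#' @param path Combined TSV path (or BED path when `counts_path` is given).
#' @param counts_path Optional separate counts TSV.
#' @return A [peak_regions()] table.
#' @export
read_peak_table <- function(path, counts_path = NULL) {
  if (is.null(counts_path)) {
    df <- read_tsv_strict(path, c("peak_id", "chrom", "start", "end",
                                  "n_bl", "n_sp"))
    return(peak_regions(df$peak_id, df$chrom, df$start, df$end,
                        df$n_bl, df$n_sp))
  }
  bed <- read_bed(path)
  if (anyNA(bed$name)) stop("BED peaks need a name column to join counts",
                            call. = FALSE)
  cnt <- read_tsv_strict(counts_path, c("peak_id", "n_bl", "n_sp"))
  idx <- match(bed$name, cnt$peak_id)
  if (anyNA(idx)) stop("counts missing for peak(s): ",
                       paste(utils::head(bed$name[is.na(idx)], 5), collapse = ", "),
                       call. = FALSE)
  peak_regions(bed$name, bed$chrom, bed$start, bed$end,
               cnt$n_bl[idx], cnt$n_sp[idx])
}

#' @rdname read_peak_table
#' @param peaks A [peak_regions()] table.
#' @export
write_peak_table <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_regions"))
  write_tsv(peaks, path)
}

#' Write fixture files for a simulated experiment
#'
#' Serializes a [simulate_rnaseq_experiment()] or
#' [simulate_chip_experiment()] result into the exact formats the pipeline
#' readers consume: `counts.tsv`, `genes.tsv` (exon intervals),
#' `library.json`, `truth.tsv` for RNA-seq; `peaks.tsv` and
#' `peaks_truth.tsv` for ChIP. Writing then reading reproduces the
#' in-memory tables exactly.
#'
#' @param sim A `sim_experiment` or `sim_chip` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  if (inherits(sim, "sim_experiment")) {
    paths <- c(counts = file.path(out_dir, "counts.tsv"),
               genes = file.path(out_dir, "genes.tsv"),
               library = file.path(out_dir, "library.json"),
               truth = file.path(out_dir, "truth.tsv"))
    write_allelic_counts(sim$counts, paths[["counts"]])
    write_gene_models(sim$genes, paths[["genes"]])
    write_library_stats(sim$lib, paths[["library"]])
    write_tsv(sim$truth, paths[["truth"]])
  } else if (inherits(sim, "sim_chip")) {
    paths <- c(peaks = file.path(out_dir, "peaks.tsv"),
               peaks_truth = file.path(out_dir, "peaks_truth.tsv"))
    write_peak_table(sim$peaks, paths[["peaks"]])
    write_tsv(sim$truth, paths[["peaks_truth"]])
  } else {
    stop("unsupported simulation object of class ",
         paste(class(sim), collapse = "/"), call. = FALSE)
  }
  invisible(paths)
}
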