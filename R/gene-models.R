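# Gene models: per-gene exon interval sets. Exon coordinates follow the BED
# convention (0-based half-open) at the file boundary and are stored 1-based
# closed internally as IRanges, the Bioconductor convention. Exonic length is
# the length of the union of a gene's exons.

#' Construct gene models from an exon table
#'
#' @param exons A data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open, BED convention) and optionally `strand` (`+`/`-`).
#' @return An object of class `gene_models`: a list with
#'   `genes` (data.frame: gene_id, chrom, strand, exonic_length_bp, n_exons)
#'   and `exons_gr` (a [GenomicRanges::GRanges] of reduced per-gene exons
#'   with metadata column `gene_id`).
#' @examples
#' gene_models(data.frame(gene_id = "g1", chrom = "chrX",
#'                        start = c(0, 150), end = c(100, 250)))
#' @export
gene_models <- function(exons) {
  req <- c("gene_id", "chrom", "start", "end")
  missing <- setdiff(req, names(exons))
  if (length(missing) > 0L) {
    stop("exon table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(exons) == 0L) stop("empty exon table", call. = FALSE)
  if (any(exons$end <= exons$start)) {
    stop("exon intervals must satisfy end > start (0-based half-open)",
         call. = FALSE)
  }
  strand <- if ("strand" %in% names(exons)) exons$strand else "+"
  gr <- GenomicRanges::GRanges(
    normalize_chrom(exons$chrom),
    IRanges::IRanges(exons$start + 1L, exons$end),  # BED -> 1-based closed
    strand = strand
  )
  gr$gene_id <- as.character(exons$gene_id)
  # union overlapping exons within each gene
  by_gene <- S4Vectors::split(gr, gr$gene_id)
  red <- GenomicRanges::reduce(by_gene, ignore.strand = FALSE)
  exons_gr <- unlist(red, use.names = FALSE)
  exons_gr$gene_id <- rep(names(red), lengths(red))
  lens <- vapply(split(GenomicRanges::width(exons_gr), exons_gr$gene_id),
                 sum, numeric(1))
  first <- !duplicated(gr$gene_id)
  info <- data.frame(
    gene_id = gr$gene_id[first],
    chrom = as.character(GenomicRanges::seqnames(gr))[first],
    strand = as.character(GenomicRanges::strand(gr))[first],
    stringsAsFactors = FALSE
  )
  info$exonic_length_bp <- as.integer(lens[info$gene_id])
  info$n_exons <- as.integer(table(exons_gr$gene_id)[info$gene_id])
  per_chrom <- tapply(info$chrom, info$gene_id, function(x) length(unique(x)))
  if (any(per_chrom > 1L)) {
    stop("gene(s) with exons on multiple chromosomes: ",
         paste(names(per_chrom)[per_chrom > 1L], collapse = ", "),
         call. = FALSE)
  }
  out <- list(genes = info, exons_gr = exons_gr)
  class(out) <- "gene_models"
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      length(x$exons_gr), "reduced exons\n")
  invisible(x)
}

#' Read gene models from a file
#'
#' Accepts either a BED12 file (one line per gene; exons reconstructed from
#' blockStarts/blockSizes) or a TSV of exon intervals with header columns
#' `gene_id`, `chrom`, `start`, `end` (+ optional `strand`). Both use
#' 0-based half-open coordinates.
#'
#' @param path File path.
#' @param format `"auto"` (BED12 if the extension is `.bed`), `"bed12"`, or
#'   `"exon_tsv"`.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "exon_tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path)) "bed12" else "exon_tsv"
  }
  if (format == "exon_tsv") {
    return(gene_models(read_tsv_strict(path, c("gene_id", "chrom", "start", "end"))))
  }
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(bed) < 12L) stop("BED12 requires 12 columns, got ", ncol(bed),
                            call. = FALSE)
  exons <- do.call(rbind, lapply(seq_len(nrow(bed)), function(i) {
    sizes <- as.integer(strsplit(sub(",$", "", bed[i, 11L]), ",")[[1L]])
    starts <- as.integer(strsplit(sub(",$", "", bed[i, 12L]), ",")[[1L]])
    data.frame(gene_id = bed[i, 4L], chrom = bed[i, 1L],
               start = bed[i, 2L] + starts, end = bed[i, 2L] + starts + sizes,
               strand = bed[i, 6L], stringsAsFactors = FALSE)
  }))
  gene_models(exons)
}

#' Write gene models as an exon TSV
#'
#' Inverse of [read_gene_models()] for the `exon_tsv` format (0-based
#' half-open coordinates).
#'
#' @param genes A [gene_models()] object.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  gr <- genes$exons_gr
  df <- data.frame(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}
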