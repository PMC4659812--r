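# SNP catalog: the heterozygous sites that distinguish the two parental
# haplotypes (reference BL6 vs alternate spretus). A catalog is a validated
# data.frame with columns chrom, pos (1-based), ref, alt, exonic.

.valid_bases <- c("A", "C", "G", "T")

#' Construct and validate a SNP catalog
#'
#' A SNP catalog holds one row per heterozygous site with the reference (BL6)
#' and alternate (spretus) alleles. Only biallelic single-nucleotide
#' substitutions are supported; rows whose alleles are not single A/C/G/T
#' bases (e.g. indels) are rejected with an error, or dropped with a counted
#' warning by the file readers.
#'
#' @param chrom Chromosome names (normalized via [normalize_chrom()]).
#' @param pos 1-based genomic positions.
#' @param ref,alt Single-base alleles of the two haplotypes; must differ.
#' @param exonic Logical flag: site lies within an annotated exon. Defaults
#'   to `NA` when unknown; [flag_exonic_snps()] fills it from gene models.
#' @return A `data.frame` of class `snp_catalog` with columns
#'   `chrom`, `pos`, `ref`, `alt`, `exonic`.
#' @examples
#' snp_catalog(c("chrX", "chr1"), c(100L, 200L), c("A", "C"), c("G", "T"))
#' @export
snp_catalog <- function(chrom, pos, ref, alt, exonic = NA) {
  chrom <- normalize_chrom(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  exonic <- rep_len(as.logical(exonic), n)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("SNP positions must be integers >= 1", call. = FALSE)
  }
  bad_allele <- !(ref %in% .valid_bases) | !(alt %in% .valid_bases)
  if (any(bad_allele)) {
    stop(sum(bad_allele), " record(s) with non-SNV alleles ",
         "(only single-base A/C/G/T substitutions are supported)",
         call. = FALSE)
  }
  same <- ref == alt
  if (any(same)) {
    stop("ref allele equals alt allele at ",
         paste(paste0(chrom[same], ":", pos[same])[seq_len(min(5, sum(same)))],
               collapse = ", "),
         call. = FALSE)
  }
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stop("duplicate SNP position(s): ",
         paste(unique(dup)[seq_len(min(5, length(unique(dup))))], collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    exonic = exonic, stringsAsFactors = FALSE)
  class(out) <- c("snp_catalog", "data.frame")
  out
}

#' Read a SNP table from disk
#'
#' Two dialects are accepted: a TSV with header columns `chrom`, `pos`,
#' `ref`, `alt` (plus optional `exonic`), or a minimal VCF-like file whose
#' `#`-prefixed header lines are skipped and whose first five columns are
#' CHROM, POS, ID, REF, ALT. SNP coordinates are 1-based in both dialects
#' (the VCF convention). Rows carrying indel alleles are dropped and counted
#' in a single warning.
#'
#' @param path Path to the SNP table.
#' @param dialect `"auto"` (default; VCF-like if the first line starts with
#'   `#` or the file extension is `.vcf`), `"tsv"`, or `"vcf_like"`.
#' @return A [snp_catalog()].
#' @export
read_snp_table <- function(path, dialect = c("auto", "tsv", "vcf_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (length(first) == 1L && startsWith(first, "#")) "vcf_like"
               else if (grepl("\\.vcf$", path)) "vcf_like" else "tsv"
  }
  if (dialect == "tsv") {
    df <- read_tsv_strict(path, required = c("chrom", "pos", "ref", "alt"))
    line_off <- 1L  # header line
    chrom <- df$chrom; pos <- df$pos; ref <- df$ref; alt <- df$alt
    exonic <- if ("exonic" %in% names(df)) as.logical(df$exonic) else NA
  } else {
    lines <- readLines(path)
    body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
    if (length(body_idx) == 0L) stop("no SNP records in ", path, call. = FALSE)
    fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 5L)) {
      bad <- body_idx[which(nf < 5L)[1L]]
      stop("malformed VCF-like line ", bad, " in ", path,
           " (fewer than 5 tab-separated fields)", call. = FALSE)
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    pos_chr <- vapply(fields, `[[`, "", 2L)
    pos <- suppressWarnings(as.integer(pos_chr))
    if (any(is.na(pos))) {
      bad <- body_idx[which(is.na(pos))[1L]]
      stop("malformed VCF-like line ", bad, " in ", path,
           " (non-integer POS)", call. = FALSE)
    }
    ref <- vapply(fields, `[[`, "", 4L)
    alt <- vapply(fields, `[[`, "", 5L)
    exonic <- NA
    line_off <- 0L
  }
  ref <- toupper(ref); alt <- toupper(alt)
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
         ref %in% .valid_bases & alt %in% .valid_bases
  if (any(!snv)) {
    warning(sum(!snv), " non-SNV record(s) (indels or ambiguous alleles) dropped",
            call. = FALSE)
  }
  keep <- which(snv)
  if (length(keep) == 0L) stop("no valid SNV records in ", path, call. = FALSE)
  exonic_keep <- if (length(exonic) == 1L && is.na(exonic)) NA else exonic[keep]
  snp_catalog(chrom[keep], pos[keep], ref[keep], alt[keep], exonic_keep)
}

#' Swap the two haplotype alleles of a catalog
#'
#' Exchanges ref and alt at every site, i.e. re-labels which parental genome
#' is "reference". Used for orientation-symmetry checks and for constructing
#' the reverse pseudo-genome substitution.
#'
#' @param snps A [snp_catalog()].
#' @return A [snp_catalog()] with ref/alt exchanged.
#' @export
swap_alleles <- function(snps) {
  stopifnot(inherits(snps, "snp_catalog"))
  snp_catalog(snps$chrom, snps$pos, snps$alt, snps$ref, snps$exonic)
}

#' Summarize a SNP catalog by chromosomal location
#'
#' Splits the catalog into X-linked and autosomal SNPs and counts genes that
#' contain at least one exonic catalog SNP, reporting counts and one-decimal
#' percentages (half-away-from-zero rounding). [snp_location_summary()] is
#' the count-level arithmetic; `summarize_snp_catalog()` derives the counts
#' from a catalog plus gene models and then delegates to it.
#'
#' @param snps A [snp_catalog()].
#' @param genes Gene models from [gene_models()]; a gene counts as "with
#'   exonic SNPs" iff at least one catalog SNP falls inside one of its exons.
#' @return See [snp_location_summary()].
#' @export
summarize_snp_catalog <- function(snps, genes) {
  stopifnot(inherits(snps, "snp_catalog"))
  on_x <- is_x_chrom(snps$chrom)
  hit <- genes_with_exonic_snps(snps, genes)
  gene_x <- is_x_chrom(hit$chrom)
  snp_location_summary(n_x = sum(on_x), n_autosomal = sum(!on_x),
                       n_genes_exonic_x = sum(gene_x),
                       n_genes_exonic_autosomal = sum(!gene_x))
}

#' SNP location summary from counts
#'
#' @param n_x,n_autosomal Counts of X-linked and autosomal SNPs.
#' @param n_genes_exonic_x,n_genes_exonic_autosomal Counts of genes with at
#'   least one exonic SNP, by location.
#' @return A list of class `snp_location_summary` with fields `n_x`,
#'   `n_autosomal`, `n_total`, `pct_x`, `pct_autosomal` (one decimal),
#'   `n_genes_exonic_x`, `n_genes_exonic_autosomal`, `n_genes_exonic_total`,
#'   and `empty` (TRUE when the catalog had zero SNPs, in which case the
#'   percentages are reported as 0.0).
#' @examples
#' snp_location_summary(1532011, 33909724, 1099, 27010)
#' @export
snp_location_summary <- function(n_x, n_autosomal,
                                 n_genes_exonic_x = 0L,
                                 n_genes_exonic_autosomal = 0L) {
  stopifnot(n_x >= 0, n_autosomal >= 0)
  n_total <- n_x + n_autosomal
  empty <- n_total == 0
  pct_x <- if (empty) 0 else round_half_up(100 * n_x / n_total, 1)
  pct_autosomal <- if (empty) 0 else round_half_up(100 * n_autosomal / n_total, 1)
  out <- list(n_x = n_x, n_autosomal = n_autosomal, n_total = n_total,
              pct_x = pct_x, pct_autosomal = pct_autosomal,
              n_genes_exonic_x = n_genes_exonic_x,
              n_genes_exonic_autosomal = n_genes_exonic_autosomal,
              n_genes_exonic_total = n_genes_exonic_x + n_genes_exonic_autosomal,
              empty = empty)
  class(out) <- "snp_location_summary"
  out
}

#' @export
print.snp_location_summary <- function(x, ...) {
  cat("SNP location summary\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.snp_location_summary <- function(x, ...) {
  data.frame(
    location = c("X chromosome", "Autosomes", "Both"),
    total_snps = c(x$n_x, x$n_autosomal, x$n_total),
    pct_snps = c(x$pct_x, x$pct_autosomal, if (x$empty) 0 else 100),
    n_genes_exonic = c(x$n_genes_exonic_x, x$n_genes_exonic_autosomal,
                       x$n_genes_exonic_total),
    stringsAsFactors = FALSE
  )
}

#' Flag exonic SNPs and find genes containing them
#'
#' @param snps A [snp_catalog()].
#' @param genes Gene models from [gene_models()].
#' @return `flag_exonic_snps()`: the catalog with `exonic` filled.
#'   `genes_with_exonic_snps()`: the subset of `genes$genes` overlapped by at
#'   least one catalog SNP in an exon.
#' @export
flag_exonic_snps <- function(snps, genes) {
  stopifnot(inherits(snps, "snp_catalog"))
  snps$exonic <- overlaps_exon(snps, genes)
  snps
}

#' @rdname flag_exonic_snps
#' @export
genes_with_exonic_snps <- function(snps, genes) {
  stopifnot(inherits(snps, "snp_catalog"), inherits(genes, "gene_models"))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(genes$exons_gr, snp_gr, ignore.strand = TRUE)
  hit_genes <- unique(genes$exons_gr$gene_id[S4Vectors::queryHits(hits)])
  genes$genes[genes$genes$gene_id %in% hit_genes, , drop = FALSE]
}

overlaps_exon <- function(snps, genes) {
  stopifnot(inherits(genes, "gene_models"))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, width = 1L))
  IRanges::overlapsAny(snp_gr, genes$exons_gr, ignore.strand = TRUE)
}
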