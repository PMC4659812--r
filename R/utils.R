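# Shared internal helpers: chromosome-name normalization, rounding, TSV I/O.

#' Normalize chromosome names
#'
#' Maps the common bare ("X", "1") and prefixed ("chrX", "chr1") spellings onto
#' the canonical prefixed form used throughout the package, so that SNP tables,
#' gene models, reads and peaks from mixed sources join correctly.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector in canonical form ("chrX", "chr1", ...).
#' @examples
#' normalize_chrom(c("X", "chrX", "1", "chr13", "MT"))
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  bare <- !startsWith(chrom, "chr")
  chrom[bare] <- paste0("chr", chrom[bare])
  chrom
}

#' @rdname normalize_chrom
#' @export
is_x_chrom <- function(chrom) normalize_chrom(chrom) == "chrX"

# Half-away-from-zero rounding (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Strict TSV reading: header required, no factors, tab-separated.
read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
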