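# Pseudo-genome substitution: build the alternate-haplotype ("pseudo-spretus")
# chromosome sequence by substituting the catalog's alt alleles into the
# reference sequence. Symmetric allelic mapping in the hybrid relies on this.

#' Substitute catalog SNP alleles into a chromosome sequence
#'
#' Replaces the base at every catalog position on `chrom` with the alternate
#' allele, after verifying (case-insensitively) that the input carries the
#' reference allele there; a mismatch signals a catalog/genome-build
#' disagreement and is an error naming the offending positions. The returned
#' sequence has unchanged length and differs from the input exactly at the
#' SNP positions. Substituting with a [swap_alleles()]-swapped catalog
#' inverts the operation.
#'
#' @param sequence A single chromosome sequence: a character string or a
#'   [Biostrings::DNAString].
#' @param snps A [snp_catalog()]; only records on `chrom` are used.
#' @param chrom Chromosome name of `sequence`.
#' @return Same type as `sequence` (character in, character out), with alt
#'   alleles substituted. Case is uppercased.
#' @examples
#' substitute_pseudo_genome("ACGT", snp_catalog("chr1", 2, "C", "T"), "chr1")
#' @export
substitute_pseudo_genome <- function(sequence, snps, chrom) {
  stopifnot(inherits(snps, "snp_catalog"), length(chrom) == 1L)
  chrom <- normalize_chrom(chrom)
  as_char <- is.character(sequence)
  dna <- if (as_char) Biostrings::DNAString(toupper(sequence)) else sequence
  here <- snps[snps$chrom == chrom, , drop = FALSE]
  if (nrow(here) == 0L) {
    return(if (as_char) as.character(dna) else dna)
  }
  if (max(here$pos) > length(dna)) {
    stop("SNP position ", max(here$pos), " beyond ", chrom,
         " sequence length ", length(dna), call. = FALSE)
  }
  at <- here$pos
  have <- toupper(as.character(Biostrings::extractAt(
    dna, IRanges::IRanges(at, width = 1L))))
  bad <- have != here$ref
  if (any(bad)) {
    stop("reference-base mismatch at ",
         paste(paste0(chrom, ":", at[bad], " (catalog ref ", here$ref[bad],
                      ", sequence ", have[bad], ")")[seq_len(min(5, sum(bad)))],
               collapse = "; "),
         call. = FALSE)
  }
  out <- Biostrings::replaceLetterAt(dna, at, here$alt)
  if (as_char) as.character(out) else out
}

#' Build a pseudo-genome FASTA from a reference FASTA
#'
#' Applies [substitute_pseudo_genome()] to every sequence of a reference
#' FASTA and writes the result. Sequence names are matched to catalog
#' chromosomes via [normalize_chrom()]; sequences without catalog SNPs are
#' copied unchanged.
#'
#' @param fasta_in,fasta_out Input reference and output pseudo-genome paths.
#' @param snps A [snp_catalog()].
#' @return Invisibly, `fasta_out`.
#' @export
write_pseudo_genome_fasta <- function(fasta_in, snps, fasta_out) {
  genome <- Biostrings::readDNAStringSet(fasta_in)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- genome
  for (i in seq_along(genome)) {
    out[[i]] <- substitute_pseudo_genome(genome[[i]], snps,
                                         normalize_chrom(names(genome)[i]))
  }
  Biostrings::writeXStringSet(out, fasta_out)
  invisible(fasta_out)
}
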