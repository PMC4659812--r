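# Allelic read assignment: segregate high-quality (MAPQ >= 30) uniquely
# mapped reads into BL6-SNP, spretus-SNP and allele-uncertain categories by
# comparing read bases to the catalog alleles at every overlapped SNP.

#' Construct a table of aligned-read summaries
#'
#' The minimal per-read information the classifier needs: where the read's
#' bases sit on the reference and how confidently it mapped. `start` is
#' 0-based; the read is taken as an ungapped end-to-end alignment of
#' `sequence` covering `[start, start + nchar(sequence))`. Spliced or
#' indel-containing alignments must be split into ungapped segments first
#' ([read_sam_minimal()] does this from the CIGAR).
#'
#' @param read_id Read identifiers.
#' @param chrom Chromosome names.
#' @param start 0-based alignment start positions.
#' @param sequence Read base strings (aligned orientation).
#' @param mapq Mapping qualities (integer, >= 0).
#' @param unique Logical best-hit uniqueness flags.
#' @return A data.frame of class `aligned_reads`.
#' @export
aligned_reads <- function(read_id, chrom, start, sequence, mapq, unique = TRUE) {
  n <- length(read_id)
  start <- as.integer(start)
  mapq <- as.integer(mapq)
  sequence <- toupper(as.character(sequence))
  unique <- rep_len(as.logical(unique), n)
  chrom <- rep_len(chrom, n)
  stopifnot(length(start) == n, length(sequence) == n, length(mapq) == n)
  if (any(mapq < 0L)) stop("mapq must be >= 0", call. = FALSE)
  if (any(start < 0L)) stop("start must be >= 0", call. = FALSE)
  if (any(!nzchar(sequence))) stop("empty read sequence", call. = FALSE)
  out <- data.frame(read_id = as.character(read_id),
                    chrom = normalize_chrom(chrom),
                    start = start, sequence = sequence, mapq = mapq,
                    unique = unique, stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

#' Read a minimal SAM file into aligned-read segments
#'
#' Parses the QNAME, FLAG, RNAME, POS, MAPQ, CIGAR and SEQ fields of a text
#' SAM file and expands each alignment's CIGAR into ungapped reference-space
#' segments (M/=/X consume both; I/S consume query only; D/N consume
#' reference only; H/P consume neither), so that base-vs-allele comparison
#' can use simple reference offsets. Multi-segment reads keep one row per
#' segment sharing the read_id; a read's MAPQ/uniqueness applies to all its
#' segments. Uniqueness is taken from the absence of tags that the caller
#' maps to multi-mapping (by default reads are treated as unique; pass a
#' `unique_fn` to derive the flag from the optional fields, e.g. from
#' `XT:A:R` or `NH:i:` tags — the mapping is data-dependent, not hard-coded).
#'
#' @param path SAM file path.
#' @param unique_fn Optional `function(opt_fields_character) -> logical(1)`
#'   deciding uniqueness from a read's optional-field strings.
#' @return An [aligned_reads()] table (unmapped reads, FLAG 0x4, skipped).
#' @export
read_sam_minimal <- function(path, unique_fn = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) stop("no alignments in ", path, call. = FALSE)
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L) stop("malformed SAM line (", length(f), " fields)",
                              call. = FALSE)
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    uniq <- if (is.null(unique_fn)) TRUE else isTRUE(unique_fn(f[-(1:11)]))
    seg <- cigar_segments(as.integer(f[4L]) - 1L, f[6L], f[10L])
    if (nrow(seg) == 0L) next
    rows[[i]] <- data.frame(read_id = f[1L], chrom = f[3L], start = seg$start,
                            sequence = seg$seq, mapq = as.integer(f[5L]),
                            unique = uniq, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no mapped alignments in ", path, call. = FALSE)
  df <- do.call(rbind, rows)
  aligned_reads(df$read_id, df$chrom, df$start, df$sequence, df$mapq, df$unique)
}

# Expand a CIGAR into ungapped (reference_start0, segment_sequence) pieces.
cigar_segments <- function(start0, cigar, seq) {
  if (cigar == "*") {
    return(data.frame(start = start0, seq = seq, stringsAsFactors = FALSE))
  }
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  n_op <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("\\d+", "", ops)
  ref_pos <- start0
  q_pos <- 1L
  starts <- integer(0); seqs <- character(0)
  for (j in seq_along(op)) {
    len <- n_op[j]
    if (op[j] %in% c("M", "=", "X")) {
      starts <- c(starts, ref_pos)
      seqs <- c(seqs, substr(seq, q_pos, q_pos + len - 1L))
      ref_pos <- ref_pos + len
      q_pos <- q_pos + len
    } else if (op[j] %in% c("I", "S")) {
      q_pos <- q_pos + len
    } else if (op[j] %in% c("D", "N")) {
      ref_pos <- ref_pos + len
    }  # H, P: consume neither
  }
  data.frame(start = starts, seq = seqs, stringsAsFactors = FALSE)
}

#' Assign reads to parental haplotypes via catalog SNPs
#'
#' Each retained read (MAPQ >= `mapq_min` and uniquely mapped) is compared to
#' the catalog at every SNP its alignment covers. A read matching only
#' BL6 (reference) alleles is `bl6_snp`; only spretus (alternate) alleles,
#' `spretus_snp`; reads covering no catalog SNP, covering SNPs whose bases
#' match neither allele (sequencing error), or carrying conflicting evidence
#' from both haplotypes are `uncertain`. Reads failing the MAPQ/uniqueness
#' filter are `discarded`. Multi-segment reads (one read_id, several rows)
#' pool their SNP evidence.
#'
#' @param reads An [aligned_reads()] table.
#' @param snps A [snp_catalog()].
#' @param mapq_min Minimum mapping quality to retain a read (default 30).
#' @return A data.frame of class `allele_assignments` with one row per read:
#'   `read_id`, `category` (bl6_snp / spretus_snp / uncertain / discarded),
#'   `n_bl6_matches`, `n_spretus_matches`, `n_mismatch_other`.
#' @export
assign_reads <- function(reads, snps, mapq_min = 30L) {
  stopifnot(inherits(reads, "aligned_reads"), inherits(snps, "snp_catalog"))
  read_ids <- unique(reads$read_id)
  # per-segment SNP overlap via interval matching
  seg_gr <- GenomicRanges::GRanges(
    reads$chrom,
    IRanges::IRanges(reads$start + 1L, reads$start + nchar(reads$sequence)))
  snp_gr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(seg_gr, snp_gr)
  seg_i <- S4Vectors::queryHits(hits)
  snp_i <- S4Vectors::subjectHits(hits)
  base <- substr(reads$sequence[seg_i],
                 snps$pos[snp_i] - reads$start[seg_i],
                 snps$pos[snp_i] - reads$start[seg_i])
  m_bl6 <- base == snps$ref[snp_i]
  m_spr <- base == snps$alt[snp_i]
  id_at_hit <- reads$read_id[seg_i]
  nb <- tapply(m_bl6, id_at_hit, sum)
  ns <- tapply(m_spr, id_at_hit, sum)
  no <- tapply(!m_bl6 & !m_spr, id_at_hit, sum)
  get0i <- function(tab, ids) {
    v <- as.integer(tab[ids]); v[is.na(v)] <- 0L; v
  }
  n_bl6 <- get0i(nb, read_ids)
  n_spr <- get0i(ns, read_ids)
  n_oth <- get0i(no, read_ids)
  # read-level retention: worst segment decides
  min_mapq <- tapply(reads$mapq, reads$read_id, min)[read_ids]
  all_uniq <- tapply(reads$unique, reads$read_id, all)[read_ids]
  retained <- min_mapq >= mapq_min & all_uniq
  category <- rep("uncertain", length(read_ids))
  category[n_bl6 >= 1L & n_spr == 0L] <- "bl6_snp"
  category[n_spr >= 1L & n_bl6 == 0L] <- "spretus_snp"
  category[!retained] <- "discarded"
  out <- data.frame(read_id = read_ids, category = category,
                    n_bl6_matches = n_bl6, n_spretus_matches = n_spr,
                    n_mismatch_other = n_oth, stringsAsFactors = FALSE)
  class(out) <- c("allele_assignments", "data.frame")
  out
}

#' Tabulate read assignments into a segregation table
#'
#' Summarizes an experiment the way mapped-read summaries are reported:
#' counts per category and percentages of retained (high-MAPQ unique) reads
#' falling in the BL6, spretus and uncertain classes, the percentages
#' rounded to integers.
#'
#' @param assignments An `allele_assignments` table from [assign_reads()].
#' @param experiment_id Optional label for the row.
#' @return A one-row data.frame: `experiment_id`, `n_retained`,
#'   `n_discarded`, `n_bl6`, `n_spretus`, `n_uncertain`, `pct_bl6`,
#'   `pct_spretus`, `pct_uncertain`.
#' @export
tabulate_assignments <- function(assignments, experiment_id = "experiment") {
  stopifnot(inherits(assignments, "allele_assignments"))
  tab <- table(factor(assignments$category,
                      levels = c("bl6_snp", "spretus_snp", "uncertain", "discarded")))
  n_ret <- sum(tab[c("bl6_snp", "spretus_snp", "uncertain")])
  if (n_ret == 0L) stop("zero retained reads: empty experiment", call. = FALSE)
  pct <- function(k) as.numeric(round_half_up(100 * k / n_ret, 0))
  data.frame(experiment_id = experiment_id,
             n_retained = as.integer(n_ret),
             n_discarded = as.integer(tab[["discarded"]]),
             n_bl6 = as.integer(tab[["bl6_snp"]]),
             n_spretus = as.integer(tab[["spretus_snp"]]),
             n_uncertain = as.integer(tab[["uncertain"]]),
             pct_bl6 = pct(tab[["bl6_snp"]]),
             pct_spretus = pct(tab[["spretus_snp"]]),
             pct_uncertain = pct(tab[["uncertain"]]),
             stringsAsFactors = FALSE)
}
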