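# Read segregation into BL6-SNP / spretus-SNP / uncertain / discarded.

snps2 <- snp_catalog(c("chr1", "chr1"), c(105L, 115L),
                     c("A", "C"), c("G", "T"))

# Build a 20 bp read over chr1:100-120 (0-based start 100) whose bases at
# the two SNPs (offsets 5 and 15) are chosen per pattern.
read_with <- function(b105, b115, mapq = 60L, unique = TRUE,
                      id = "r1") {
  s <- rep("G", 20)  # G matches neither catalog allele except SNP1's alt
  s[5] <- b105; s[15] <- b115  # offsets of pos 105/115 from 0-based start 100
  aligned_reads(id, "chr1", 100L, paste(s, collapse = ""), mapq, unique)
}

test_that("single reads are categorized by their SNP evidence", {
  one <- function(reads) assign_reads(reads, snps2)$category
  # covering one BL6 allele only (second SNP base matches neither allele)
  expect_equal(one(read_with("A", "G")), "bl6_snp")
  # both spretus alleles
  expect_equal(one(read_with("G", "T")), "spretus_snp")
  # no catalog SNP covered
  far <- aligned_reads("r", "chr1", 500L, "ACGTACGTAC", 60L)
  expect_equal(one(far), "uncertain")
  # below MAPQ 30
  expect_equal(one(read_with("A", "C", mapq = 29L)), "discarded")
  # not uniquely mapped
  expect_equal(one(read_with("A", "C", unique = FALSE)), "discarded")
  # conflicting evidence, one SNP from each haplotype
  expect_equal(one(read_with("A", "T")), "uncertain")
})

test_that("all two-SNP base patterns follow the category rules", {
  # enumeration oracle: base at each SNP is ref, alt, or other
  choices1 <- c(ref = "A", alt = "G", other = "C")
  choices2 <- c(ref = "C", alt = "T", other = "G")
  for (c1 in names(choices1)) for (c2 in names(choices2)) {
    asg <- assign_reads(read_with(choices1[[c1]], choices2[[c2]]), snps2)
    n_ref <- sum(c(c1, c2) == "ref")
    n_alt <- sum(c(c1, c2) == "alt")
    expected <- if (n_ref >= 1 && n_alt == 0) "bl6_snp"
                else if (n_alt >= 1 && n_ref == 0) "spretus_snp"
                else "uncertain"
    expect_equal(asg$category, expected,
                 info = paste(c1, c2))
    expect_equal(asg$n_bl6_matches, n_ref)
    expect_equal(asg$n_spretus_matches, n_alt)
    expect_equal(asg$n_mismatch_other, sum(c(c1, c2) == "other"))
  }
})

test_that("assignment partitions reads and respects swap/mapq properties", {
  tr <- simulate_toy_reads(n_reads = 400L, seed = 9L)
  asg <- assign_reads(tr$reads, tr$snps)
  # partition: one category per read, counts conserved
  expect_equal(nrow(asg), length(unique(tr$reads$read_id)))
  expect_true(all(asg$category %in%
                    c("bl6_snp", "spretus_snp", "uncertain", "discarded")))
  # allelic calls never contradict the simulated haplotype of origin
  m <- merge(asg, tr$truth, by = "read_id")
  expect_true(all(m$origin[m$category == "bl6_snp"] == "bl6"))
  expect_true(all(m$origin[m$category == "spretus_snp"] == "spretus"))

  # swapping catalog alleles swaps the two allelic categories exactly
  asg_sw <- assign_reads(tr$reads, swap_alleles(tr$snps))
  t1 <- table(asg$category); t2 <- table(asg_sw$category)
  expect_equal(t1[["bl6_snp"]], t2[["spretus_snp"]])
  expect_equal(t1[["spretus_snp"]], t2[["bl6_snp"]])
  expect_equal(t1[["uncertain"]], t2[["uncertain"]])
  expect_equal(t1[["discarded"]], t2[["discarded"]])

  # raising mapq_min never decreases the discarded count
  disc <- vapply(c(0L, 10L, 30L, 50L, 61L), function(q) {
    sum(assign_reads(tr$reads, tr$snps, mapq_min = q)$category == "discarded")
  }, 0)
  expect_true(all(diff(disc) >= 0))
})

test_that("segregation tables report percentages of retained reads", {
  categories <- c(rep("bl6_snp", 11), rep("spretus_snp", 10),
                  rep("uncertain", 79), rep("discarded", 15))
  asg <- data.frame(read_id = sprintf("r%03d", seq_along(categories)),
                    category = categories,
                    n_bl6_matches = 0L, n_spretus_matches = 0L,
                    n_mismatch_other = 0L, stringsAsFactors = FALSE)
  class(asg) <- c("allele_assignments", "data.frame")
  tab <- tabulate_assignments(asg, "patski_rep1")
  expect_equal(tab$n_retained, 100L)
  expect_equal(c(tab$pct_bl6, tab$pct_spretus, tab$pct_uncertain),
               c(11, 10, 79))

  asg$category <- "uncertain"
  tab2 <- tabulate_assignments(asg)
  expect_equal(c(tab2$pct_bl6, tab2$pct_spretus, tab2$pct_uncertain),
               c(0, 0, 100))

  asg$category <- "discarded"
  expect_error(tabulate_assignments(asg), "zero retained")
})

test_that("percentages equal an independent recount on a random fixture", {
  set.seed(31)
  cats <- sample(c("bl6_snp", "spretus_snp", "uncertain", "discarded"),
                 1000L, replace = TRUE, prob = c(.15, .12, .6, .13))
  asg <- data.frame(read_id = sprintf("r%04d", 1:1000), category = cats,
                    n_bl6_matches = 0L, n_spretus_matches = 0L,
                    n_mismatch_other = 0L, stringsAsFactors = FALSE)
  class(asg) <- c("allele_assignments", "data.frame")
  tab <- tabulate_assignments(asg)
  ret <- cats[cats != "discarded"]
  expect_equal(tab$pct_bl6, round(100 * sum(ret == "bl6_snp") / length(ret)))
  expect_equal(tab$pct_spretus,
               round(100 * sum(ret == "spretus_snp") / length(ret)))
  expect_equal(tab$n_retained + tab$n_discarded, 1000L)
})

test_that("the SAM reader expands CIGARs into ungapped segments", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    # simple match: covers 0-based [99, 109)
    "r1\t0\tchr1\t100\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    # spliced: 4M 100N 4M with 2S clipped tail
    "r2\t0\tchr1\t100\t60\t4M100N4M2S\t*\t0\t0\tAAAACCCCGG\t*",
    # unmapped: skipped
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*"
  ), sam)
  reads <- read_sam_minimal(sam)
  expect_equal(sort(unique(reads$read_id)), c("r1", "r2"))
  r1 <- reads[reads$read_id == "r1", ]
  expect_equal(r1$start, 99L)
  expect_equal(r1$sequence, "ACGTACGTAC")
  r2 <- reads[reads$read_id == "r2", ]
  expect_equal(r2$start, c(99L, 203L))       # second segment after the 100N gap
  expect_equal(r2$sequence, c("AAAA", "CCCC"))  # soft clip dropped
})

test_that("segments from a spliced read pool their SNP evidence", {
  snps <- snp_catalog(c("chr1", "chr1"), c(101L, 205L), c("A", "C"),
                      c("G", "T"))
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chr1\tLN:10000",
               "r1\t0\tchr1\t100\t60\t4M100N4M\t*\t0\t0\tAAAACCCC\t*"), sam)
  reads <- read_sam_minimal(sam)
  asg <- assign_reads(reads, snps)
  expect_equal(nrow(asg), 1L)
  expect_equal(asg$n_bl6_matches, 2L)  # both exon segments match BL6 alleles
  expect_equal(asg$category, "bl6_snp")
})
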