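# Allele-specific peak classification against a pooled background.

test_that("the X background is the pooled BL6 read fraction", {
  pk <- peak_regions(c("p1", "p2"), "chrX", c(0, 1000), c(500, 1500),
                     n_bl = c(200, 100), n_sp = c(60, 40))
  bg <- estimate_x_background(pk)
  expect_equal(bg$p0, 0.75)

  even <- peak_regions("p", "chrX", 0, 100, 100, 100)
  expect_equal(estimate_x_background(even)$p0, 0.5)

  # brute-force pooled recount on a random fixture
  set.seed(17)
  nb <- rpois(40, 25); ns <- rpois(40, 15)
  pk <- peak_regions(sprintf("p%02d", 1:40), "chrX",
                     seq(0, by = 1000, length.out = 40),
                     seq(500, by = 1000, length.out = 40), nb, ns)
  expect_equal(estimate_x_background(pk)$p0, sum(nb) / (sum(nb) + sum(ns)))

  zero <- peak_regions("p", "chrX", 0, 100, 0, 0)
  expect_error(estimate_x_background(zero), "zero pooled")
  auto <- peak_regions("p", "chr5", 0, 100, 5, 5)
  expect_error(estimate_x_background(auto), "X-linked peaks only")
})

test_that("exact binomial tails are inclusive and satisfy the pmf identity", {
  t <- exact_binomial_tails(10, 10, 0.5)
  expect_equal(t$p_upper, 2^-10)
  expect_equal(t$p_lower, 1)

  t0 <- exact_binomial_tails(0, 7, 0.3)
  expect_equal(t0$p_lower, 0.7^7)
  expect_equal(t0$p_upper, 1)

  # p_upper + p_lower = 1 + P(K = k)
  set.seed(3)
  for (i in 1:30) {
    n <- sample(1:60, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    t <- exact_binomial_tails(k, n, p0)
    expect_equal(t$p_upper + t$p_lower, 1 + dbinom(k, n, p0),
                 tolerance = 1e-12)
  }

  expect_error(exact_binomial_tails(5, 3, 0.5), "k must")
  t_na <- exact_binomial_tails(0, 0, 0.5)
  expect_true(is.na(t_na$p_upper) && is.na(t_na$p_lower))
})

test_that("peaks are classified into preference categories", {
  bg <- fixed_background(0.5, "chrX")
  one <- function(n_bl, n_sp, lib = 1e7) {
    pk <- peak_regions("p", "chrX", 0, 100, n_bl, n_sp)
    classify_peaks(pk, bg, lib)$calls
  }
  expect_equal(one(10, 0)$category, "bl6_preferred")      # p_upper = 2^-10
  expect_equal(one(0, 10)$category, "spretus_preferred")
  expect_equal(one(5, 5)$category, "both_preferred")      # both tails 0.623
  expect_equal(one(8, 2)$category, "ambiguous")           # p_upper 0.0547
  expect_equal(one(0, 0)$category, "not_assessable")

  # coverage filter scales with library size: ceil(total / 1e7) reads
  expect_equal(one(1, 1, lib = 2.5e7)$category, "not_assessable")
  expect_equal(one(5, 0, lib = 2.5e7)$category, "bl6_preferred")
})

test_that("every assessable peak gets exactly one of the four categories", {
  set.seed(19)
  n <- rpois(300, 12)
  k <- rbinom(300, n, 0.55)
  pk <- peak_regions(sprintf("p%03d", 1:300), "chrX",
                     seq(0, by = 500, length.out = 300),
                     seq(200, by = 500, length.out = 300), k, n - k)
  calls <- classify_peaks(pk, fixed_background(0.55), 1e7)$calls
  assessable <- calls$category != "not_assessable"
  expect_true(all(calls$category[assessable] %in%
                    c("bl6_preferred", "spretus_preferred",
                      "both_preferred", "ambiguous")))
  expect_equal(sum(assessable), sum(n >= 1))
})

test_that("haplotype swap mirrors the classification exactly", {
  set.seed(23)
  n <- rpois(200, 20)
  k <- rbinom(200, n, 0.7)
  pk <- peak_regions(sprintf("p%03d", 1:200), "chrX",
                     seq(0, by = 500, length.out = 200),
                     seq(200, by = 500, length.out = 200), k, n - k)
  pk_sw <- peak_regions(pk$peak_id, pk$chrom, pk$start, pk$end,
                        pk$n_sp, pk$n_bl)
  a <- classify_peaks(pk, fixed_background(0.7), 1e7)$calls
  b <- classify_peaks(pk_sw, fixed_background(0.3), 1e7)$calls
  map <- c(bl6_preferred = "spretus_preferred",
           spretus_preferred = "bl6_preferred",
           both_preferred = "both_preferred",
           ambiguous = "ambiguous",
           not_assessable = "not_assessable")
  expect_equal(unname(map[a$category]), b$category)
})

test_that("peak summaries map haplotype labels through the Xi orientation", {
  pk <- peak_regions(c("p1", "p2", "p3"), "chrX", c(0, 500, 1000),
                     c(200, 700, 1200), c(30, 0, 6), c(0, 30, 6))
  calls <- classify_peaks(pk, fixed_background(0.5), 1e7)
  # Xi = spretus: BL6-preferred peaks sit on the active X
  s1 <- summarize_peak_calls(calls, "spretus", n_total_peaks = 50)
  expect_equal(s1$n_total_peaks, 50L)
  expect_equal(s1$n_x_peaks, 3L)
  expect_equal(s1$n_xa_preferred, 1L)
  expect_equal(s1$n_xi_preferred, 1L)
  expect_equal(s1$n_both_preferred, 1L)
  # Patski orientation flips the labels
  s2 <- summarize_peak_calls(calls, "bl6")
  expect_equal(s2$n_xa_preferred, 1L)
  expect_equal(s2$n_xi_preferred, 1L)
})

test_that("peak intersection keeps reciprocally overlapping intervals", {
  a <- data.frame(chrom = "chr1", start = c(0, 1000, 5000),
                  end = c(500, 1400, 5100))
  b <- data.frame(chrom = "chr1", start = c(499, 2000), end = c(600, 2100))
  expect_equal(intersect_peaks(a, b)$start, 0)  # 1 bp overlap suffices
  expect_equal(nrow(intersect_peaks(b, a)), 1L)
})
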