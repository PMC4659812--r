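# Binomial escape model: estimator, Wald limits, bias correction,
# three-criterion classification, replicate concordance.

test_that("the proportion estimate is the Xi read fraction", {
  expect_equal(estimate_proportion(5, 5), 0.5)
  expect_equal(estimate_proportion(0, 17), 0)
  expect_equal(estimate_proportion(20, 80), 0.2)
  expect_true(is.na(estimate_proportion(0, 0)))
})

test_that("Wald limits match the closed form at alpha = 0.01", {
  # frozen two-step oracle: z_{0.005} = 2.5758293035, half-width
  # 2.5758293035 * sqrt(0.25/100) = 0.1287914652
  ci <- wald_ci(0.5, 100, 0.01)
  expect_equal(ci$lower, 0.3712085348, tolerance = 1e-8)
  expect_equal(ci$upper, 0.6287914652, tolerance = 1e-8)

  # zero variance at the boundary
  ci0 <- wald_ci(0, 50, 0.01)
  expect_equal(c(ci0$lower, ci0$upper), c(0, 0))

  # quadrupling n halves the half-width exactly
  h <- function(n) {
    ci <- wald_ci(0.3, n, 0.05); (ci$upper - ci$lower) / 2
  }
  expect_equal(h(100), 2 * h(400))

  expect_error(wald_ci(0.5, 100, 1.2), "alpha")
})

test_that("bias correction obeys its algebraic identities", {
  # rm = 1 is the identity on a dense grid
  grid <- expand.grid(n_xi = 0:25, n_xa = 0:25)
  grid <- grid[grid$n_xi + grid$n_xa > 0, ]
  expect_equal(bias_correct(grid$n_xi, grid$n_xa, 1),
               estimate_proportion(grid$n_xi, grid$n_xa))

  expect_equal(bias_correct(20, 80, 1.25), 20 / 120)

  # the two printed forms agree to machine precision
  for (rm in c(0.8, 1, 1.04, 1.1, 1.43, 2)) {
    p_hat <- estimate_proportion(grid$n_xi, grid$n_xa)
    form1 <- bias_correct(grid$n_xi, grid$n_xa, rm)
    form2 <- p_hat / (p_hat + rm * (1 - p_hat))
    expect_lt(max(abs(form1 - form2)), 1e-12)
  }

  # fixed points at p_hat 0 and 1, any rm
  expect_equal(bias_correct(0, 10, 1.3), 0)
  expect_equal(bias_correct(10, 0, 1.3), 1)

  # strictly decreasing in rm for interior p_hat
  rms <- seq(0.5, 2, by = 0.1)
  vals <- bias_correct(7, 13, rms)
  expect_true(all(diff(vals) < 0))

  expect_error(bias_correct(5, 5, 0), "rm")
})

test_that("corrected limits transform the Wald limits monotonically", {
  # rm = 1: corrected limits equal the clamped raw limits
  cc <- corrected_ci(3, 7, rm = 1, alpha = 0.01)
  expect_equal(cc$lower, max(cc$raw_lower, 0))
  expect_equal(cc$upper, min(cc$raw_upper, 1))

  # two-step oracle at n_xi = 10, n_xa = 90, rm = 1.1 (frozen values
  # computed as f(clamped Wald limits of p_hat = 0.1, n = 100))
  cc2 <- corrected_ci(10, 90, rm = 1.1, alpha = 0.01)
  expect_equal(cc2$raw_lower, 0.0227251209, tolerance = 1e-8)
  expect_equal(cc2$lower, 0.0207019694, tolerance = 1e-8)
  expect_equal(cc2$upper, 0.1637987449, tolerance = 1e-8)

  # bracketing: lower <= p_bar <= upper over a random grid
  set.seed(8)
  for (i in 1:50) {
    n_xi <- sample(0:40, 1); n_xa <- sample(0:40, 1)
    if (n_xi + n_xa == 0) n_xa <- 1
    rm <- runif(1, 0.8, 1.5)
    cc <- corrected_ci(n_xi, n_xa, rm, 0.01)
    pb <- bias_correct(n_xi, n_xa, rm)
    expect_lte(cc$lower, pb + 1e-12)
    expect_gte(cc$upper, pb - 1e-12)
  }
})

test_that("the three escape criteria drive the classification", {
  genes <- fix_gene_x()           # 1 kb exon
  lib <- fix_lib(total = 1e7)     # srpm(n) = n, rpkm(d) = d / 10
  cls <- function(n_xi, n_xa, n_diploid, gene = genes) {
    classify_escape("geneX", n_xi, n_xa, n_diploid, gene, lib)
  }
  # high escape: CI lower > 0, RPKM 2, Xi-SRPM 6
  call <- cls(6, 14, 20)
  expect_equal(call$category, "high_escape")
  expect_true(call$ci_positive && call$expressed && call$srpm_high_met)

  # low escape at the inclusive Xi-SRPM = 2 boundary
  call <- cls(2, 0, 20)
  expect_equal(call$xi_srpm, 2)
  expect_equal(call$category, "low_escape")

  # n_xi = 0: the Wald lower limit cannot exceed zero
  call <- cls(0, 50, 60)
  expect_equal(call$category, "not_escape")
  expect_false(call$ci_positive)

  # expression floor: silences the call despite strong allelic signal
  big_gene <- fix_gene_x(len = 10000L)
  call <- classify_escape("geneX", 10, 0, 10, big_gene, lib)
  expect_equal(call$rpkm, 0.1)
  expect_equal(call$category, "not_escape")
  expect_true(call$srpm_high_met && !call$expressed)

  # no allele-specific reads at all: not assessable
  call <- cls(0, 0, 30)
  expect_equal(call$category, "not_assessable")

  # autosomal genes are never classified
  auto_gene <- gene_models(data.frame(gene_id = "geneX", chrom = "chr2",
                                      start = 0L, end = 1000L))
  expect_error(classify_escape("geneX", 5, 5, 10, auto_gene, lib), "non-X")
})

test_that("escape criterion 1 is invariant to the bias transform", {
  # f is monotone with f(0) = 0, so corrected-lower > 0 iff raw-lower > 0
  set.seed(21)
  for (i in 1:100) {
    n_xi <- sample(0:30, 1); n_xa <- sample(0:30, 1)
    if (n_xi + n_xa == 0) n_xi <- 1
    rm <- runif(1, 0.7, 1.6)
    cc <- corrected_ci(n_xi, n_xa, rm, 0.01)
    expect_equal(cc$lower > 0, cc$raw_lower > 0)
  }
})

test_that("fit methods expose estimates, limits and residuals", {
  counts <- allelic_counts(c("g1", "g2", "g3"), c(10, 0, 0), c(30, 40, 0),
                           c(50, 45, 5))
  genes <- gene_models(data.frame(gene_id = c("g1", "g2", "g3"),
                                  chrom = "chrX", start = c(0, 2000, 4000),
                                  end = c(1000, 3000, 5000)))
  fit <- xci_escape(counts, genes, fix_lib(rm = 1.1))
  expect_s3_class(fit, "xci_escape")
  expect_equal(unname(coef(fit)), c(10 / (10 + 1.1 * 30), 0, NA))
  ci <- confint(fit)
  expect_equal(rownames(ci), c("g1", "g2", "g3"))
  expect_true(ci["g1", "lower"] <= coef(fit)[["g1"]])
  r <- residuals(fit)
  expect_false(is.na(r[[1]]))
  expect_true(is.na(r[[2]]))         # degenerate fitted proportion (p_bar = 0)
  expect_true(is.na(r[[3]]))         # not assessable
  s <- summary(fit)
  expect_equal(sum(s$category_counts), 3L)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(3L, 2L))
  expect_true(all(sims[1:2, ] <= fit$calls$n[1:2]))
})

test_that("replicate concordance is a scale-free R^2", {
  mk <- function(xi_srpm) {
    data.frame(gene_id = sprintf("g%02d", seq_along(xi_srpm)),
               xi_srpm = xi_srpm, stringsAsFactors = FALSE)
  }
  a <- mk(c(0, 1, 2, 5, 10, 20))
  expect_equal(replicate_concordance(a, a), 1)
  b <- mk(2 * c(0, 1, 2, 5, 10, 20))
  expect_equal(replicate_concordance(a, b), 1)
  expect_error(replicate_concordance(mk(c(1, 1, 1)), mk(c(1, 1, 1))),
               "constant|undefined")
  expect_error(replicate_concordance(mk(1:2), mk(1:2)), "fewer than 3")
})
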