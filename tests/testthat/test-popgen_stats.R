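test_that("count reconstruction inverts printed percentages", {
  expect_equal(counts_from_percentages(c(36.4, 59.1, 4.5), 22), c(8L, 13L, 1L))
  expect_equal(counts_from_percentages(c(100, 0, 0), 17), c(17L, 0L, 0L))
  expect_equal(counts_from_percentages(c(9.1, 31.9, 59.1), 22), c(2L, 7L, 13L))
  # independent exhaustive oracle on random true counts
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    truth <- as.vector(rmultinom(1, n, runif(3, 0.05, 1)))
    pcts <- round(100 * truth / n, 1)
    got <- counts_from_percentages(pcts, n)
    # brute-force argmin over all triples
    best <- NULL; best_dev <- Inf
    for (a in 0:n) for (b in 0:(n - a)) {
      dev <- max(abs(c(a, b, n - a - b) - n * pcts / 100))
      if (dev < best_dev) { best_dev <- dev; best <- c(a, b, n - a - b) }
    }
    expect_equal(got, best)
    expect_equal(got, truth)
  }
  expect_error(counts_from_percentages(c(50, 50, 50), 10), "sum")
  # tied reconstructions are refused, not guessed: (4,3,3) and (3,4,3)
  # deviate equally from (3.5, 3.5, 3.0)
  expect_error(counts_from_percentages(c(35, 35, 30), 10), "ambiguous")
})

test_that("allele frequencies follow the gene-counting formula", {
  expect_equal(allele_frequencies(c(2, 7, 13))[["p_alt"]], 33 / 44)  # 75% deleted
  expect_equal(allele_frequencies(c(10, 7, 0))[["p_ref"]], 27 / 34)  # 79.41% intact
  expect_equal(allele_frequencies(c(0, 0, 5))[["p_alt"]], 1)
  expect_error(allele_frequencies(c(0, 0, 0)), "no individuals")
})

test_that("HWE chi-square is the uncorrected 1-df statistic", {
  yri <- hwe_chi2(c(8, 13, 1))
  expect_equal(yri$chi2, 2.18, tolerance = 0.005)
  expect_equal(yri$p_value, 0.14, tolerance = 0.005)
  expect_equal(yri$df, 1L)
  expect_equal(sum(yri$expected), 22)

  expect_equal(hwe_chi2(c(25, 50, 25))$chi2, 0)
  expect_equal(hwe_chi2(c(10, 0, 10))$chi2, 20)  # no-het case gives chi2 = n
  expect_equal(hwe_chi2(c(17, 23, 4))$chi2, 0.93, tolerance = 0.005)

  mono <- hwe_chi2(c(12, 0, 0))
  expect_true(mono$monomorphic)
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p_value, 1)
})

test_that("HWE statistic is invariant under swapping homozygote labels", {
  set.seed(31)
  for (rep in 1:50) {
    cts <- as.vector(rmultinom(1, sample(10:60, 1), runif(3, 0.05, 1)))
    expect_equal(hwe_chi2(cts)$chi2, hwe_chi2(rev(cts))$chi2, tolerance = 1e-12)
  }
})

test_that("chi2 is zero iff observed counts equal HWE expectations", {
  exact <- hwe_chi2(c(9, 12, 4))  # p = 0.6 -> expected (9, 12, 4) at n = 25
  expect_equal(exact$chi2, 0)
  off <- hwe_chi2(c(10, 10, 5))
  expect_gt(off$chi2, 0)
})

test_that("Spearman correlation uses midranks and the t approximation", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_correlation(x, x)$rho, 1)
  expect_equal(spearman_correlation(x, -2 * x + 5)$rho, -1)
  expect_equal(spearman_correlation(x, x)$p_value, .Machine$double.xmin)

  # ties: rho equals the Pearson correlation of brute-force midranks
  xt <- c(1, 2, 2, 3, 4, 4, 4)
  yt <- c(5, 5, 7, 8, 8, 10, 11)
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  expect_equal(spearman_correlation(xt, yt)$rho, cor(midrank(xt), midrank(yt)))

  # invariance under strictly monotone transforms
  set.seed(41)
  a <- rnorm(15); b <- rnorm(15)
  base <- spearman_correlation(a, b)
  expect_equal(spearman_correlation(exp(a), b)$rho, base$rho)
  expect_equal(spearman_correlation(a, b^3 + 10)$rho, base$rho)
  expect_true(abs(base$rho) <= 1)

  # t-approximate p agrees with the closed form
  tstat <- base$rho * sqrt(13 / (1 - base$rho^2))
  expect_equal(base$p_value, 2 * pt(abs(tstat), 13, lower.tail = FALSE))

  # exact permutation p-value is a valid probability consistent at alpha ~ .05
  ex <- spearman_correlation(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5), exact = TRUE)
  expect_true(ex$p_value > 0 && ex$p_value <= 1)

  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("population summaries assemble per-locus statistics with missing data", {
  gt <- toy_genotypes(cnv = c(rep("+/+", 9), rep("+/-", 12), rep("-/-", 4)),
                      snp = c(rep("AA", 9), rep("AG", 12), rep("GG", 4)),
                      population = "EQ")
  # p = 0.6 at n = 25: exact HWE proportions
  s <- population_summaries(gt)
  expect_equal(nrow(s), 1L)
  expect_equal(s$hwe_chi2, 0)
  expect_equal(s$cnv_minus_pct, 40)
  expect_equal(s$ld_r2, 1, tolerance = 1e-9)

  # a sample missing the SNP still contributes to CNV statistics
  gt2 <- as.data.frame(gt)
  gt2$snp_genotype[1] <- NA
  s2 <- population_summaries(genotype_table(gt2))
  expect_equal(s2$n_cnv, 25L)
  expect_equal(s2$n_snp, 24L)
  expect_equal(s2$cnv_minus_pct, 40)
})

test_that("summary allele frequencies recover generating values on a 31-population panel", {
  sizes <- c(rep(25L, 24), rep(24L, 7))
  p_minus <- seq(0.2, 0.8, length.out = 31)
  models <- lapply(1:31, function(i)
    population_model(sprintf("P%02d", i), sizes[i],
                     haplotype_freqs_for_r2(p_minus[i], 0.5, 0.25)))
  gt <- simulate_genotype_set(models, seed = 17)
  s <- population_summaries(gt)
  expect_equal(nrow(s), 31L)
  for (i in 1:31) {
    se <- sqrt(p_minus[i] * (1 - p_minus[i]) / (2 * sizes[i]))
    expect_lt(abs(s$cnv_minus_pct[i] / 100 - p_minus[i]), 3 * se + 1e-9)
  }
})
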