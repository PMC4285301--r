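test_that("ecotype differences average replicate crab-minus-wave frequencies", {
  design <- demo_design(countries = "SP")
  snps <- snps_from_freq(list(
    c(SP_crab1 = 0.9, SP_crab2 = 0.9, SP_wave1 = 0.1, SP_wave2 = 0.1),
    c(SP_crab1 = 0.5, SP_crab2 = 0.5, SP_wave1 = 0.5, SP_wave2 = 0.5),
    c(SP_crab1 = 0.9, SP_crab2 = 0.8, SP_wave1 = 0.6, SP_wave2 = 0.5)
  ))
  d <- ecotype_allele_diff(snps, design)
  expect_equal(d$diff, c(0.8, 0, 0.3), tolerance = 1e-12)
})

test_that("flipping the reference allele negates the difference exactly", {
  design <- demo_design(countries = "SP")
  snps <- snps_from_freq(list(
    c(SP_crab1 = 0.9, SP_crab2 = 0.7, SP_wave1 = 0.2, SP_wave2 = 0.4)
  ))
  flipped <- snps
  flipped$major <- snps$minor
  flipped$minor <- snps$major
  flipped$major_count <- snps$minor_count
  flipped$minor_count <- snps$major_count
  expect_equal(ecotype_allele_diff(flipped, design)$diff,
               -ecotype_allele_diff(snps, design)$diff, tolerance = 1e-12)
})

make_diffs <- function(dA, dB, contig = "c1",
                       countries = c("SP", "SW")) {
  dplyr::bind_rows(
    tibble::tibble(contig = contig, position = seq_along(dA),
                   country = countries[1], diff = dA),
    tibble::tibble(contig = contig, position = seq_along(dB),
                   country = countries[2], diff = dB)
  )
}

test_that("per-contig correlations hit the closed-form cases", {
  r1 <- contig_correlation(make_diffs(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15)))
  expect_equal(r1$r, 1, tolerance = 1e-9)
  expect_equal(r1$n_snps, 3L)

  r2 <- contig_correlation(make_diffs(c(0.1, 0.2, 0.3), -c(0.1, 0.2, 0.3)))
  expect_equal(r2$r, -1, tolerance = 1e-9)

  # zero variance in one country: contig excluded and counted
  r3 <- contig_correlation(make_diffs(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3)))
  expect_equal(nrow(r3), 0)
  expect_equal(attr(r3, "n_excluded")[["zero_variance"]], 1L)

  # fewer than three SNPs: excluded
  r4 <- contig_correlation(make_diffs(c(0.1, 0.2), c(0.1, 0.2)))
  expect_equal(nrow(r4), 0)
  expect_equal(attr(r4, "n_excluded")[["few_snps"]], 1L)
})

test_that("correlations agree with stats::cor on random vectors", {
  withr::with_seed(5, {
    for (i in 1:10) {
      k <- sample(3:12, 1)
      dA <- runif(k, -1, 1)
      dB <- runif(k, -1, 1)
      got <- contig_correlation(make_diffs(dA, dB))$r
      expect_equal(got, cor(dA, dB), tolerance = 1e-9)
    }
  })
})

test_that("polarization symmetry: joint flips preserve r, single flips negate", {
  withr::with_seed(9, {
    dA <- runif(5, -1, 1)
    dB <- runif(5, -1, 1)
    base <- contig_correlation(make_diffs(dA, dB))$r
    expect_equal(contig_correlation(make_diffs(-dA, -dB))$r, base,
                 tolerance = 1e-12)
    expect_equal(contig_correlation(make_diffs(-dA, dB))$r, -base,
                 tolerance = 1e-12)
  })
})

test_that("three-SNP contigs yield an excess of |r| near 1 under the null", {
  withr::with_seed(13, {
    n_contig <- 4000
    r3 <- replicate(n_contig, cor(runif(3, -1, 1), runif(3, -1, 1)))
    diffs <- dplyr::bind_rows(purrr::map(seq_len(n_contig), function(i) {
      make_diffs(runif(3, -1, 1), runif(3, -1, 1),
                 contig = sprintf("c%05d", i))
    }))
    got <- contig_correlation(diffs)
    # heavy tails: |r| > 0.9 is far more common than under many-SNP contigs
    frac_extreme <- mean(abs(got$r) > 0.9)
    expect_gt(frac_extreme, 0.15)
    # and matches the independent per-contig oracle rate
    expect_equal(frac_extreme, mean(abs(r3) > 0.9), tolerance = 0.15)
  })
})

test_that("bootstrap test is calibrated at the edges", {
  withr::with_seed(3, {
    all_rs <- runif(500, -1, 1)
    # self-comparison: observed mean is the reference mean
    self <- bootstrap_mean_r_test(all_rs, all_rs, B = 500)
    expect_gt(self$bootstrap_p, 0.9)

    # extreme shift: outliers all at +1 against a symmetric distribution
    shift <- bootstrap_mean_r_test(rep(1, 30), all_rs, B = 10000)
    expect_lte(shift$bootstrap_p, 0.01)

    expect_error(bootstrap_mean_r_test(numeric(), all_rs), "empty")
    expect_warning(bootstrap_mean_r_test(all_rs[1:5], all_rs, B = 50),
                   "coarse")
  })
})

test_that("bootstrap p-values are roughly uniform under the null", {
  withr::with_seed(29, {
    all_rs <- runif(400, -1, 1)
    ps <- replicate(300, {
      focal <- sample(all_rs, 15)
      bootstrap_mean_r_test(focal, all_rs, B = 399)$bootstrap_p
    })
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("chi-square bin test matches hand-computed statistics", {
  # focal identical in distribution to reference: statistic 0, p = 1
  all_rs <- rep(c(-0.75, -0.25, 0.25, 0.75), each = 40)
  same <- chisq_bin_test(all_rs, all_rs)
  expect_equal(same$chi2_stat, 0)
  expect_equal(same$chi2_p, 1)

  # all focal mass in one bin against uniform proportions over 4 bins:
  # statistic = n * 3 with n = 40
  focal <- rep(-0.75, 40)
  conc <- chisq_bin_test(focal, all_rs)
  expect_equal(conc$chi2_stat, 40 * 3, tolerance = 1e-12)
  expect_equal(conc$chi2_df, 3L)
  expect_equal(conc$bin_counts_outliers[[1]], c(40, 0, 0, 0))

  # sum of focal bin counts is the focal size
  expect_equal(sum(conc$bin_counts_outliers[[1]]), 40)
})

test_that("bins with expected count below 5 are merged, degenerate cases NA", {
  # 10 focal contigs, uniform reference: expected 2.5 per bin -> merges
  all_rs <- rep(c(-0.75, -0.25, 0.25, 0.75), each = 40)
  res <- chisq_bin_test(runif(10, -1, 1), all_rs)
  expect_lt(res$n_bins, 4)
  expect_equal(res$n_bins, 2)

  # too few focal contigs to keep two bins: test not computed
  tiny <- chisq_bin_test(runif(4, -1, 1), all_rs)
  expect_true(is.na(tiny$chi2_stat))
})

test_that("chi-square p-values are roughly uniform under the null", {
  withr::with_seed(37, {
    all_rs <- runif(600, -1, 1)
    ps <- replicate(300, {
      focal <- sample(all_rs, 40)
      chisq_bin_test(focal, all_rs)$chi2_p
    })
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
  })
})
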