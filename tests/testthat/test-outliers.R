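# full-enumeration oracle for the hypergeometric overlap null, independent
# of phyper: pmf via products of binomial coefficients
hyper_oracle <- function(N, n_a, n_b) {
  k <- max(0, n_a + n_b - N):min(n_a, n_b)
  pmf <- choose(n_a, k) * choose(N - n_a, n_b - k) / choose(N, n_b)
  cdf <- cumsum(pmf)
  expected <- sum(k * pmf)
  cdf_prev <- c(0, head(cdf, -1))
  eps <- 1e-12
  list(expected = expected,
       ci_low = max(k[cdf_prev <= 0.025 + eps]),
       ci_high = min(k[cdf >= 0.975 - eps]))
}

make_cfst <- function(fst1, fst2, country = "SP",
                      contig = paste0("c", seq_along(fst1))) {
  tibble::tibble(contig = contig, country = country,
                 fst_rep1 = fst1, fst_rep2 = fst2,
                 fst_mean = (fst1 + fst2) / 2)
}

test_that("identical replicate rankings give exactly the top (1-q) share", {
  fst <- seq(0.001, 0.1, length.out = 100)
  cfst <- make_cfst(fst, fst)
  out <- detect_outliers(cfst, q = 0.94)
  expect_equal(nrow(out), 6)
  expect_setequal(out$contig, paste0("c", 95:100))

  # perfectly anti-ranked replicates share no tail
  anti <- make_cfst(fst, rev(fst))
  expect_equal(nrow(detect_outliers(anti, q = 0.94)), 0)

  expect_error(detect_outliers(cfst, q = 1.2), "in \\(0, 1\\)")
})

test_that("raising the quantile never adds outliers", {
  withr::with_seed(31, {
    for (i in 1:5) {
      cfst <- make_cfst(runif(300), runif(300))
      sets <- lapply(c(0.9, 0.94, 0.96, 0.98),
                     function(q) detect_outliers(cfst, q)$contig)
      for (j in seq_len(length(sets) - 1)) {
        expect_true(all(sets[[j + 1]] %in% sets[[j]]))
      }
      # replicate consistency shrinks the marginal sets
      expect_lt(nrow(detect_outliers(cfst, 0.94)), 0.06 * 300)
    }
  })
})

test_that("hypergeometric null matches full enumeration", {
  cases <- expand.grid(N = c(1, 5, 30, 100), frac_a = c(0, 0.1, 0.5, 1),
                       frac_b = c(0.05, 0.3, 1))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]
    n_a <- round(cases$frac_a[i] * N)
    n_b <- round(cases$frac_b[i] * N)
    got <- hypergeometric_null(N, n_a, n_b)
    want <- hyper_oracle(N, n_a, n_b)
    expect_equal(got$expected, want$expected, tolerance = 1e-9)
    expect_equal(got$ci_low, want$ci_low)
    expect_equal(got$ci_high, want$ci_high)
    expect_lte(got$ci_low, got$expected)
    expect_gte(got$ci_high, got$expected)
  }
})

test_that("hypergeometric edge cases are degenerate as expected", {
  full <- hypergeometric_null(50, 50, 20)
  expect_equal(full$expected, 20)
  expect_equal(full$ci_low, 20L)
  expect_equal(full$ci_high, 20L)

  none <- hypergeometric_null(50, 0, 20)
  expect_equal(none$expected, 0)
  expect_equal(none$ci_low, 0L)
  expect_equal(none$ci_high, 0L)

  expect_error(hypergeometric_null(10, 11, 5), "<= N")
})

test_that("expected overlap matches a permutation oracle", {
  withr::with_seed(17, {
    universe <- paste0("c", 1:100)
    draws <- replicate(10000, {
      length(intersect(sample(universe, 10), sample(universe, 20)))
    })
    null <- hypergeometric_null(100, 10, 20)
    expect_equal(null$expected, 2)
    # Monte-Carlo mean within 4 SE of the analytic expectation
    expect_lt(abs(mean(draws) - null$expected),
              4 * sd(draws) / sqrt(length(draws)))
    # CI limits bracket the empirical 2.5% / 97.5% quantiles
    expect_gte(mean(draws >= null$ci_low & draws <= null$ci_high), 0.95)
  })
})

test_that("shared outliers respect set identities", {
  universe <- paste0("c", 1:100)
  out <- tibble::tibble(
    country = rep(c("SP", "SW"), each = 10),
    contig = c(universe[1:10], universe[1:10])
  )
  res <- shared_outliers(out, universe)
  expect_equal(res$observed_shared, 10)
  expect_equal(res$prop_a, 1)

  disjoint <- tibble::tibble(
    country = rep(c("SP", "SW"), each = 10),
    contig = c(universe[1:10], universe[11:20])
  )
  expect_equal(shared_outliers(disjoint, universe)$observed_shared, 0)

  expect_error(shared_outliers(out, universe[1:5]), "universe")
})

test_that("three-way sharing is the triple intersection", {
  out <- tibble::tibble(
    country = rep(c("SP", "SW", "UK"), each = 3),
    contig = c("a", "b", "c", "b", "c", "d", "c", "d", "e")
  )
  expect_equal(three_way_shared(out), "c")
  empty <- out[out$country != "UK" | out$contig == "zz", ]
  expect_length(three_way_shared(rbind(
    out[out$country != "UK", ],
    tibble::tibble(country = "UK", contig = "zz")
  )), 0)

  same <- tibble::tibble(country = rep(c("SP", "SW", "UK"), each = 2),
                         contig = rep(c("a", "b"), 3))
  expect_setequal(three_way_shared(same), c("a", "b"))
})

test_that("three independent random sets overlap near N * f^3", {
  withr::with_seed(23, {
    N <- 7000
    universe <- paste0("c", seq_len(N))
    n_take <- round(0.05 * N)
    triple <- replicate(400, {
      sets <- replicate(3, sample(universe, n_take), simplify = FALSE)
      length(Reduce(intersect, sets))
    })
    expect_equal(mean(triple), N * 0.05^3, tolerance = 0.25)
  })
})

test_that("control sharing mirrors the within-ecotype pseudo replicates", {
  # degenerate: crab-crab and wave-wave FST identical => 100% sharing
  n <- 100
  fst <- tibble::tibble(
    comparison = "within_ecotype",
    pair_id = rep(c("cc", "ww"), each = n),
    country = "SP",
    ecotype = rep(c("crab", "wave"), each = n),
    contig = rep(paste0("c", 1:n), 2),
    fst = rep(seq(0.001, 0.1, length.out = n), 2)
  )
  res <- control_sharing(fst, q = 0.94)
  expect_equal(res$observed_shared, 6)
  expect_equal(res$prop_shared, 1)
})

test_that("replicate sharing reports marginal top-q overlap", {
  fst <- seq(0.001, 0.1, length.out = 100)
  cfst <- make_cfst(fst, fst)
  res <- replicate_sharing(cfst, q = 0.94)
  expect_equal(res$n_a, 6L)
  expect_equal(res$observed_shared, 6)
  expect_equal(res$prop_shared, 1)
  expect_true(res$exceeds_chance)
})
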