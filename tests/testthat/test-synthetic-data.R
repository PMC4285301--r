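test_that("config validation catches inconsistent settings", {
  expect_error(sim_config(frac_shared_selected = 0.7,
                          frac_country_specific = 0.4), "sum to more than 1")
  expect_error(sim_config(effect_delta = 0), "effect_delta")
  expect_error(sim_config(flip_pair = c("SP", "ZZ"),
                          frac_sign_flipped = 0.1), "flip_pair")
  expect_error(sim_config(country_corr = 0.5, corr_pair = c("AA", "BB")),
               "corr_pair")
})

test_that("a fixed seed reproduces byte-identical sync output", {
  cfg <- sim_config(n_contigs = 30)
  sim1 <- simulate_pool_seq(cfg, seed = 123)
  sim2 <- simulate_pool_seq(cfg, seed = 123)
  expect_identical(sim1$sync, sim2$sync)
  expect_identical(sim1$truth, sim2$truth)

  p1 <- withr::local_tempfile(fileext = ".sync")
  p2 <- withr::local_tempfile(fileext = ".sync")
  write_sync(sim1$sync, p1, sim1$design)
  write_sync(sim2$sync, p2, sim2$design)
  expect_identical(readLines(p1), readLines(p2))

  sim3 <- simulate_pool_seq(cfg, seed = 124)
  expect_false(identical(sim1$sync, sim3$sync))
})

test_that("truth tables round trip losslessly and validate labels", {
  sim <- simulate_pool_seq(sim_config(n_contigs = 100), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back, sim$truth, tolerance = 1e-12)

  empty <- sim$truth[0, ]
  write_truth(empty, path)
  expect_equal(nrow(read_truth(path)), 0)

  bad <- sim$truth
  bad$label[1] <- "mystery"
  write_truth(bad, path)
  expect_error(read_truth(path), "unknown truth label")
})

test_that("coverage marginal matches the configured negative binomial", {
  cfg <- sim_config(n_contigs = 3000, coverage_mean = 50,
                    coverage_dispersion = 5)
  sim <- simulate_pool_seq(cfg, seed = 99)
  cov <- sim$sync$a + sim$sync$t + sim$sync$c + sim$sync$g
  # > 1e5 sample-site draws; mean within 2% and overdispersed as configured
  expect_gt(length(cov), 1e5)
  expect_equal(mean(cov), 50 * (1 - cfg$error_rate * 0), tolerance = 0.02)
  expect_gt(stats::var(cov), 50 * 1.5) # far above Poisson variance
})

test_that("selected contigs realize the configured ecotype shift", {
  cfg <- sim_config(n_contigs = 300, drift_sd = 0,
                    ancestral_beta = c(200, 200), # pins pi near 0.5
                    frac_shared_selected = 0.2, frac_country_specific = 0,
                    frac_sign_flipped = 0, effect_delta = 0.3)
  sim <- simulate_pool_seq(cfg, seed = 7)
  shared <- sim$truth[sim$truth$label == "shared_selected", ]
  neutral <- sim$truth[sim$truth$label == "neutral", ]
  for (ct in c("SP", "SW", "UK")) {
    expect_equal(shared[[paste0("delta_", ct)]], rep(0.3, nrow(shared)),
                 tolerance = 1e-9)
    expect_equal(neutral[[paste0("delta_", ct)]], rep(0, nrow(neutral)),
                 tolerance = 1e-9)
  }
})

test_that("sign-flipped contigs have opposite shifts in the flip pair", {
  cfg <- sim_config(n_contigs = 300, drift_sd = 0,
                    ancestral_beta = c(200, 200),
                    frac_shared_selected = 0, frac_country_specific = 0,
                    frac_sign_flipped = 0.2, flip_pair = c("SP", "UK"),
                    effect_delta = 0.3)
  sim <- simulate_pool_seq(cfg, seed = 8)
  flipped <- sim$truth[grepl("^sign_flipped", sim$truth$label), ]
  expect_gt(nrow(flipped), 0)
  expect_equal(flipped$delta_SP, rep(0.3, nrow(flipped)), tolerance = 1e-9)
  expect_equal(flipped$delta_UK, rep(-0.3, nrow(flipped)), tolerance = 1e-9)
  expect_equal(flipped$delta_SW, rep(0, nrow(flipped)), tolerance = 1e-9)
})

test_that("neutral symmetric simulation keeps mean frequency at one half", {
  cfg <- sim_config(n_contigs = 2500, drift_sd = 0, error_rate = 0,
                    ancestral_beta = c(1e6, 1e6),
                    frac_shared_selected = 0, frac_country_specific = 0,
                    frac_sign_flipped = 0)
  sim <- simulate_pool_seq(cfg, seed = 3)
  cov <- sim$sync$a + sim$sync$t + sim$sync$c + sim$sync$g
  # the reference allele's read fraction: expectation 0.5
  ref_count <- ifelse(sim$sync$ref == "A", sim$sync$a,
                ifelse(sim$sync$ref == "T", sim$sync$t,
                 ifelse(sim$sync$ref == "C", sim$sync$c, sim$sync$g)))
  p_hat <- sum(ref_count) / sum(cov)
  # conservative bound: 3 binomial SEs at the realised read depth ignoring
  # the (variance-increasing) pool stage would be too tight; use frequency
  # variance across SNPs instead
  n_snps <- nrow(sim$truth) * 0 + length(unique(paste(sim$sync$contig,
                                                      sim$sync$position)))
  se <- sd(ref_count / pmax(cov, 1)) / sqrt(n_snps)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("selected contigs always carry at least the configured SNP count", {
  cfg <- sim_config(n_contigs = 400, frac_shared_selected = 0.1,
                    selected_min_snps = 3)
  sim <- simulate_pool_seq(cfg, seed = 12)
  sel <- sim$truth[sim$truth$label != "neutral", ]
  expect_true(all(sel$n_snps >= 3))
})

test_that("drift above ecotype effect reproduces the FST rank order", {
  cfg <- sim_config(n_contigs = 600, drift_sd = 1.2, effect_delta = 0.25,
                    frac_shared_selected = 0.10, frac_country_specific = 0,
                    frac_sign_flipped = 0)
  scan <- run_scan(sim = cfg, seed = 5, quantiles = 0.94, bootstrap_B = 200)
  g <- glance(scan)
  expect_lt(g$mean_fst_within_ecotype, g$mean_fst_between_ecotype)
  expect_lt(g$mean_fst_between_ecotype, g$mean_fst_between_country)
})
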