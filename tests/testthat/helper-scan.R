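# Lean single-run pipeline used by the calibration / power tests: simulate,
# preprocess, between-ecotype FST, replicate-consistent outliers, sharing.
# Only the pieces a given study needs are computed.
acceptance_scan <- function(seed, cfg, q = 0.94, control = FALSE,
                            correlations = FALSE) {
  sim <- simulate_pool_seq(cfg, seed = poolscan:::stage_seed(seed, 1))
  sub <- subsample_sync(sim$sync, seed = poolscan:::stage_seed(seed, 2),
                        quiet = TRUE)
  snps <- call_snps(sub, seed = poolscan:::stage_seed(seed, 3))
  comparisons <- c("between_ecotype", if (control) "within_ecotype")
  fst <- pair_fst(snps, design_pairs(sim$design, comparisons = comparisons))
  cfst <- country_fst(fst)
  countries <- unique(sim$design$country)
  tab <- table(cfst$contig)
  universe <- names(tab)[tab == length(countries)]
  cfst_u <- cfst[cfst$contig %in% universe, ]
  out <- detect_outliers(cfst_u, q)
  res <- list(
    truth = sim$truth, design = sim$design, universe = universe,
    cfst = cfst_u, outliers = out,
    sharing = shared_outliers(out, universe, countries = countries),
    rep_sharing = replicate_sharing(cfst_u, q)
  )
  if (control) {
    res$control <- control_sharing(fst[fst$contig %in% universe, ], q)
  }
  if (correlations) {
    diffs <- ecotype_allele_diff(snps, sim$design)
    res$corr <- contig_correlation(diffs)
  }
  res
}

in_ci <- function(sharing) {
  sharing$observed_shared >= sharing$ci_low &
    sharing$observed_shared <= sharing$ci_high
}
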