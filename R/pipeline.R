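#' Run the full parallel-divergence scan
#'
#' Orchestrates the analysis end to end: deletion-site removal, subsampling
#' to even coverage, SNP calling with the global minor-allele-count
#' threshold, per-contig FST for all design pairs, replicate-consistent
#' outlier detection over a set of quantile thresholds, cross-country
#' sharing against the hypergeometric null (with replicate and
#' nonreplicate-control sharing), and SNP-level correlation tests for the
#' shared outliers. Input is either a sync tibble plus design, or a
#' [sim_config()] from which a dataset is simulated first. One top-level
#' seed deterministically derives the per-stage seeds, so identical calls
#' reproduce identical results.
#'
#' @param sync Long sync tibble ([read_sync()]); ignored if `sim` is given.
#' @param design A `pool_design`; ignored if `sim` is given.
#' @param sim Optional [sim_config()]; if supplied the dataset is simulated.
#' @param seed Integer seed for all stochastic stages.
#' @param target_coverage,min_coverage,min_minor_count Preprocessing
#'   parameters (see [subsample_sync()], [call_snps()]).
#' @param quantiles Outlier threshold quantiles.
#' @param bootstrap_B Bootstrap samples for the SNP-correlation test.
#' @param bin_edges Chi-square bin edges.
#' @param min_snps Minimum SNPs per contig for SNP correlations.
#' @return An object of class `pool_scan`: a list with elements `design`,
#'   `truth` (simulated runs only), `fst` (per-contig per-pair),
#'   `fst_summary`, `country_fst`, `correlations`
#'   ([replicate_correlation()]), `between_country`, `outliers`,
#'   `sharing`, `replicate_sharing`, `control_sharing`, `three_way` (all
#'   indexed by quantile), `snp_correlations`, `parallelism`, `manifest`
#'   and `params`.
#' @export
run_scan <- function(sync = NULL, design = NULL, sim = NULL, seed = 1L,
                     target_coverage = 20, min_coverage = 10,
                     min_minor_count = 24,
                     quantiles = c(0.94, 0.95, 0.96, 0.97, 0.98),
                     bootstrap_B = 10000,
                     bin_edges = c(-1, -0.5, 0, 0.5, 1),
                     min_snps = 3) {
  truth <- NULL
  if (!is.null(sim)) {
    simulated <- simulate_pool_seq(sim, seed = stage_seed(seed, 10L))
    sync <- simulated$sync
    design <- simulated$design
    truth <- simulated$truth
  }
  if (is.null(sync) || is.null(design)) {
    stop("run_scan needs either (sync, design) or a sim config", call. = FALSE)
  }
  design <- pool_design(design)

  sites_read <- dplyr::n_distinct(paste(sync$contig, sync$position))
  clean <- drop_deletion_sites(sync, quiet = TRUE)
  sub <- subsample_sync(clean, target_coverage = target_coverage,
                        min_coverage = min_coverage,
                        seed = stage_seed(seed, 20L), quiet = TRUE)
  snps <- call_snps(sub, min_minor_count = min_minor_count,
                    seed = stage_seed(seed, 30L))

  fst <- all_pair_fst(snps, design)
  cfst <- country_fst(fst)
  universe <- sort(unique(cfst$contig[stats::ave(
    seq_along(cfst$contig), cfst$contig, FUN = length) ==
      length(unique(cfst$country))]))
  # contigs with both replicate estimates in every country: the common
  # universe N for the sharing nulls
  cfst_u <- cfst[cfst$contig %in% universe, ]

  outliers <- list(); sharing <- list(); rep_share <- list()
  ctrl_share <- list(); three <- list(); para <- list()
  corr <- NULL
  diffs <- ecotype_allele_diff(snps, design)
  corr <- contig_correlation(diffs, min_snps = min_snps)
  for (q in quantiles) {
    key <- sprintf("%g", q)
    out_q <- detect_outliers(cfst_u, q)
    outliers[[key]] <- out_q
    sharing[[key]] <- shared_outliers(out_q, universe,
                                      countries = unique(design$country))
    rep_share[[key]] <- replicate_sharing(cfst_u, q)
    ctrl_share[[key]] <- control_sharing(fst[fst$contig %in% universe, ], q)
    three[[key]] <- three_way_shared(out_q,
                                     countries = unique(design$country))
    para[[key]] <- snp_parallelism(corr, sharing[[key]], B = bootstrap_B,
                                   bin_edges = bin_edges,
                                   seed = stage_seed(seed, 40L))
  }

  manifest <- tibble::tibble(
    stage = c("sites_read", "deletion_dropped", "low_coverage_dropped",
              "snps_called", "contigs_with_fst", "n_universe"),
    count = c(sites_read,
              attr(clean, "n_dropped") %||% 0L,
              attr(sub, "n_low_coverage") %||% 0L,
              dplyr::n_distinct(paste(snps$contig, snps$position)),
              dplyr::n_distinct(fst$contig),
              length(universe))
  )
  structure(list(
    design = design, truth = truth, fst = fst,
    fst_summary = fst_summary(fst),
    country_fst = cfst_u,
    correlations = replicate_correlation(cfst_u),
    between_country = between_country_fst(fst),
    outliers = outliers, sharing = sharing,
    replicate_sharing = rep_share, control_sharing = ctrl_share,
    three_way = three, snp_correlations = corr, parallelism = para,
    manifest = manifest,
    params = list(seed = seed, target_coverage = target_coverage,
                  min_coverage = min_coverage,
                  min_minor_count = min_minor_count, quantiles = quantiles,
                  bootstrap_B = bootstrap_B, bin_edges = bin_edges,
                  min_snps = min_snps)
  ), class = "pool_scan")
}

#' @export
print.pool_scan <- function(x, ...) {
  cat("pool_scan:", x$manifest$count[x$manifest$stage == "n_universe"],
      "contigs in the common universe\n")
  cat("  quantiles:", paste(names(x$outliers), collapse = ", "), "\n")
  cat("  pairs with FST:", dplyr::n_distinct(x$fst$pair_id), "\n")
  invisible(x)
}

#' Tidy a pool_scan: per-country-pair sharing results
#'
#' One row per country pair per quantile with the observed and
#' chance-expected outlier sharing.
#'
#' @param x A `pool_scan` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pool_scan
#' @export
tidy.pool_scan <- function(x, ...) {
  purrr::map_dfr(names(x$sharing), function(q) {
    res <- x$sharing[[q]]
    res$q <- as.numeric(q)
    res[setdiff(names(res), "shared_contigs")]
  })
}

#' Glance at a pool_scan: one-row headline summary
#'
#' @param x A `pool_scan` object.
#' @param ... Unused.
#' @return A one-row tibble: universe size, mean FST by comparison class,
#'   mean replicate FST correlation, outlier counts and sharing summary at
#'   the lowest quantile.
#' @method glance pool_scan
#' @export
glance.pool_scan <- function(x, ...) {
  q1 <- names(x$outliers)[1]
  by_class <- x$fst |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(m = mean(.data$fst), .groups = "drop")
  cls <- setNames(by_class$m, by_class$comparison)
  rep_r <- x$correlations$r[x$correlations$comparison == "replicates"]
  tibble::tibble(
    n_universe = x$manifest$count[x$manifest$stage == "n_universe"],
    mean_fst_within_ecotype = unname(cls["within_ecotype"]),
    mean_fst_between_ecotype = unname(cls["between_ecotype"]),
    mean_fst_between_country = unname(cls["between_country"]),
    mean_replicate_r = mean(rep_r, na.rm = TRUE),
    q = as.numeric(q1),
    n_outliers = nrow(x$outliers[[q1]]),
    n_shared_pairs_exceeding_chance = sum(x$sharing[[q1]]$exceeds_chance),
    n_three_way_shared = length(x$three_way[[q1]])
  )
}

#' Single-JSON-able summary of a scan
#'
#' Flattens the headline numbers of a `pool_scan` (per-pair mean and SE of
#' FST, replicate and between-country FST correlations, outlier counts and
#' sharing proportions per quantile, mean correlations and p-values per
#' country pair) into one nested list, suitable for
#' `jsonlite::write_json()`.
#'
#' @param scan A `pool_scan` object.
#' @return A named list.
#' @export
summarize_scan <- function(scan) {
  stopifnot(inherits(scan, "pool_scan"))
  list(
    manifest = as.list(setNames(scan$manifest$count, scan$manifest$stage)),
    fst_summary = scan$fst_summary,
    fst_correlations = scan$correlations,
    sharing = tidy(scan),
    replicate_sharing = purrr::map_dfr(names(scan$replicate_sharing),
      function(q) dplyr::mutate(
        scan$replicate_sharing[[q]][setdiff(names(scan$replicate_sharing[[q]]),
                                            "shared_contigs")],
        q = as.numeric(q))),
    control_sharing = purrr::map_dfr(names(scan$control_sharing),
      function(q) dplyr::mutate(
        scan$control_sharing[[q]][setdiff(names(scan$control_sharing[[q]]),
                                          "shared_contigs")],
        q = as.numeric(q))),
    three_way_shared = purrr::map_int(scan$three_way, length),
    parallelism = purrr::map_dfr(names(scan$parallelism), function(q) {
      res <- scan$parallelism[[q]]
      res$q <- as.numeric(q)
      res[setdiff(names(res),
                  c("bin_edges", "bin_counts_outliers", "bin_counts_all"))]
    })
  )
}
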