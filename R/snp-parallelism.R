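#' Per-SNP ecotype allele-frequency differences per country
#'
#' For each SNP and country, the difference between the crab and wave
#' frequencies of a fixed reference allele, averaged over the two replicate
#' pools: `d = mean_r(freq_crab_r - freq_wave_r)`, in `[-1, 1]`. The
#' reference allele is the SNP's overall major allele (the grand-total major
#' across all pools fixed by [call_snps()]), a deterministic polarization
#' that makes difference signs comparable across countries: flipping the
#' reference allele negates every `d` exactly.
#'
#' @param snps SNP tibble from [call_snps()].
#' @param design A `pool_design` tibble.
#' @return A tibble `contig`, `position`, `country`, `diff`.
#' @export
ecotype_allele_diff <- function(snps, design) {
  design <- pool_design(design)
  fm <- freq_matrix(snps)
  n_reps <- length(unique(design$replicate))
  countries <- unique(design$country)
  purrr::map_dfr(countries, function(ct) {
    crab <- design$sample_id[design$country == ct & design$ecotype == "crab"]
    wave <- design$sample_id[design$country == ct & design$ecotype == "wave"]
    d <- (rowSums(fm$freq[, crab, drop = FALSE]) -
            rowSums(fm$freq[, wave, drop = FALSE])) / n_reps
    tibble::tibble(contig = fm$contig, position = fm$position,
                   country = ct, diff = d)
  }) |>
    dplyr::arrange(.data$contig, .data$position, .data$country)
}

#' Per-contig correlation of SNP differences between two countries
#'
#' Pearson correlation, per contig, of the per-SNP ecotype difference
#' vectors of two countries. A positive correlation means the same alleles
#' are associated with the crab ecotype in both countries; a negative one
#' means the associations are reversed; differences driven by different
#' SNPs give correlations scattered around zero. Contigs with fewer than
#' `min_snps` SNPs, or zero variance in either country's differences, are
#' excluded (counts in the `"n_excluded"` attribute). Note that with very
#' few SNPs per contig, correlations near -1 and 1 arise by chance, so only
#' the overall distribution — not individual contigs — is interpretable.
#'
#' @param diffs Difference tibble from [ecotype_allele_diff()].
#' @param min_snps Minimum SNPs per contig (default 3, i.e. more than two).
#' @return A tibble `contig`, `country_pair`, `n_snps`, `r`, one row per
#'   contig per country pair.
#' @export
contig_correlation <- function(diffs, min_snps = 3) {
  countries <- sort(unique(diffs$country))
  if (length(countries) < 2) {
    stop("contig_correlation needs differences for at least two countries",
         call. = FALSE)
  }
  wide <- diffs |>
    tidyr::pivot_wider(names_from = "country", values_from = "diff")
  combos <- utils::combn(countries, 2, simplify = FALSE)
  n_excluded <- c(few_snps = 0L, zero_variance = 0L)
  out <- purrr::map_dfr(combos, function(cc) {
    dA <- wide[[cc[1]]]
    dB <- wide[[cc[2]]]
    ok <- !is.na(dA) & !is.na(dB)
    dA <- dA[ok]; dB <- dB[ok]
    contig_f <- factor(wide$contig[ok], levels = unique(wide$contig[ok]))
    # Pearson r per contig from grouped sums
    s <- rowsum(cbind(1, dA, dB, dA * dB, dA^2, dB^2), contig_f,
                reorder = FALSE)
    n <- s[, 1]
    cov_xy <- n * s[, 4] - s[, 2] * s[, 3]
    var_x <- n * s[, 5] - s[, 2]^2
    var_y <- n * s[, 6] - s[, 3]^2
    # clip tiny negative values from floating cancellation
    var_x <- pmax(var_x, 0); var_y <- pmax(var_y, 0)
    tol <- 1e-12 * pmax(n, 1)
    r <- ifelse(var_x > tol & var_y > tol,
                cov_xy / sqrt(var_x * var_y), NA_real_)
    r <- pmin(pmax(r, -1), 1)
    enough <- n >= min_snps
    defined <- !is.na(r)
    n_excluded["few_snps"] <<- n_excluded["few_snps"] + sum(!enough)
    n_excluded["zero_variance"] <<- n_excluded["zero_variance"] +
      sum(enough & !defined)
    keep <- enough & defined
    tibble::tibble(
      contig = rownames(s)[keep],
      country_pair = paste(cc[1], cc[2], sep = "-"),
      n_snps = as.integer(n[keep]),
      r = r[keep]
    )
  })
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Bootstrap test for the mean correlation of outlier contigs
#'
#' Tests whether the mean per-contig correlation of a focal set (e.g.
#' shared outlier contigs) differs from that of all contigs: `B` samples of
#' the focal set's size are drawn with replacement from all contigs'
#' correlations, and the two-tailed Monte-Carlo p-value with continuity
#' correction is `p = (1 + #{|mean_b - mean_all| >= |mean_obs -
#' mean_all|}) / (B + 1)`.
#'
#' @param outlier_rs Correlations of the focal contigs (non-empty).
#' @param all_rs Correlations of all contigs.
#' @param B Number of bootstrap samples (default 10000; fewer than 100
#'   triggers a warning).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `n_outliers`, `mean_r_outliers`, `mean_r_all`,
#'   `bootstrap_p`, `B`.
#' @export
bootstrap_mean_r_test <- function(outlier_rs, all_rs, B = 10000, seed = NULL) {
  if (length(outlier_rs) == 0) {
    stop("outlier_rs is empty", call. = FALSE)
  }
  if (B < 100) warning("B < 100 gives a very coarse p-value")
  mean_obs <- mean(outlier_rs)
  mean_all <- mean(all_rs)
  k <- length(outlier_rs)
  boot_means <- with_stage_seed(seed, 3L, {
    draws <- matrix(sample(all_rs, k * B, replace = TRUE), nrow = k)
    colMeans(draws)
  })
  p <- (1 + sum(abs(boot_means - mean_all) >= abs(mean_obs - mean_all))) /
    (B + 1)
  tibble::tibble(
    n_outliers = k,
    mean_r_outliers = mean_obs,
    mean_r_all = mean_all,
    bootstrap_p = min(p, 1),
    B = as.integer(B)
  )
}

#' Chi-square test on binned correlation coefficients
#'
#' Bins the per-contig correlations of the focal set and of all contigs on
#' a common partition of `[-1, 1]` and tests whether the focal distribution
#' across bins differs from the all-contig proportions. Bins with expected
#' focal count below 5 are merged with their nearest neighbour until all
#' expectations are valid; if fewer than two bins remain the test is not
#' computed and `NA`s are returned.
#'
#' @param outlier_rs Correlations of the focal contigs.
#' @param all_rs Correlations of all contigs.
#' @param bin_edges Increasing break points partitioning `[-1, 1]`
#'   (default `c(-1, -0.5, 0, 0.5, 1)`); intervals are right-closed with
#'   the lowest left-closed.
#' @return A one-row tibble: `chi2_stat`, `chi2_df`, `chi2_p`, `n_bins`,
#'   plus list-columns `bin_edges`, `bin_counts_outliers`,
#'   `bin_counts_all`.
#' @export
chisq_bin_test <- function(outlier_rs, all_rs,
                           bin_edges = c(-1, -0.5, 0, 0.5, 1)) {
  stopifnot(length(bin_edges) >= 3, !is.unsorted(bin_edges))
  cut_counts <- function(x) {
    tabulate(cut(x, breaks = bin_edges, include.lowest = TRUE, right = TRUE,
                 labels = FALSE), nbins = length(bin_edges) - 1)
  }
  obs <- cut_counts(outlier_rs)
  all_counts <- cut_counts(all_rs)
  edges <- bin_edges

  prop <- all_counts / sum(all_counts)
  expected <- length(outlier_rs) * prop
  # merge undersized bins with their nearest (smaller-expected) neighbour
  while (length(obs) > 1 && any(expected < 5)) {
    i <- which.min(expected)
    j <- if (i == 1) 2
         else if (i == length(obs)) i - 1
         else if (expected[i - 1] <= expected[i + 1]) i - 1 else i + 1
    lo <- min(i, j); hi <- max(i, j)
    obs[lo] <- obs[lo] + obs[hi]
    all_counts[lo] <- all_counts[lo] + all_counts[hi]
    expected[lo] <- expected[lo] + expected[hi]
    obs <- obs[-hi]; all_counts <- all_counts[-hi]; expected <- expected[-hi]
    edges <- edges[-hi]
  }
  base <- tibble::tibble(
    chi2_stat = NA_real_, chi2_df = NA_integer_, chi2_p = NA_real_,
    n_bins = length(obs),
    bin_edges = list(edges),
    bin_counts_outliers = list(obs),
    bin_counts_all = list(all_counts)
  )
  if (length(obs) < 2) return(base)
  stat <- sum((obs - expected)^2 / expected)
  base$chi2_stat <- stat
  base$chi2_df <- length(obs) - 1L
  base$chi2_p <- pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
  base
}

#' Correlation tests for shared outlier contigs
#'
#' Convenience wrapper combining [contig_correlation()],
#' [bootstrap_mean_r_test()] and [chisq_bin_test()] for each country pair:
#' the focal set is the pair's shared outlier contigs (with at least
#' `min_snps` SNPs and defined correlation) and the reference distribution
#' is all such contigs.
#'
#' @param corr Per-contig correlation tibble from [contig_correlation()].
#' @param sharing Sharing tibble from [shared_outliers()] (uses the
#'   `shared_contigs` list-column).
#' @param B Bootstrap samples.
#' @param bin_edges Chi-square bin edges.
#' @param seed Optional integer seed.
#' @return A tibble with one row per country pair: `country_pair`,
#'   `n_contigs_all`, plus the columns of [bootstrap_mean_r_test()] and
#'   [chisq_bin_test()].
#' @export
snp_parallelism <- function(corr, sharing, B = 10000,
                            bin_edges = c(-1, -0.5, 0, 0.5, 1), seed = NULL) {
  purrr::map_dfr(seq_len(nrow(sharing)), function(i) {
    pair <- paste(sort(c(sharing$set_a[i], sharing$set_b[i])), collapse = "-")
    sub <- corr[corr$country_pair == pair, ]
    focal <- sub$r[sub$contig %in% sharing$shared_contigs[[i]]]
    head_cols <- tibble::tibble(country_pair = pair,
                                n_contigs_all = nrow(sub))
    if (length(focal) == 0 || nrow(sub) == 0) {
      return(dplyr::bind_cols(head_cols, tibble::tibble(
        n_outliers = length(focal), mean_r_outliers = NA_real_,
        mean_r_all = if (nrow(sub)) mean(sub$r) else NA_real_,
        bootstrap_p = NA_real_, B = as.integer(B),
        chi2_stat = NA_real_, chi2_df = NA_integer_, chi2_p = NA_real_,
        n_bins = NA_integer_
      )))
    }
    boot <- bootstrap_mean_r_test(focal, sub$r, B = B, seed = seed)
    chi <- chisq_bin_test(focal, sub$r, bin_edges = bin_edges)
    dplyr::bind_cols(head_cols, boot, chi)
  })
}
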