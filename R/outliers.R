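#' Replicate-consistent FST outlier detection
#'
#' Within each country, the outlier threshold for each replicate is the
#' empirical `q`-quantile (linear interpolation between order statistics) of
#' that replicate's per-contig between-ecotype FST distribution; a contig is
#' an outlier only when it is strictly above the threshold in *both*
#' replicates. Requiring both replicates trims the marginal top-`(1 - q)`
#' sets to a more robust candidate list.
#'
#' @param cfst Country-level replicate FST tibble from [country_fst()].
#' @param q Quantile threshold in `(0, 1)` (the analyses here use 0.94 to
#'   0.98).
#' @return A tibble of outlier contigs (`country`, `contig`, `fst_rep1`,
#'   `fst_rep2`, `fst_mean`, `q`); the per-country replicate thresholds are
#'   in the `"thresholds"` attribute (tibble `country`, `threshold_rep1`,
#'   `threshold_rep2`, `n_universe`).
#' @export
detect_outliers <- function(cfst, q = 0.94) {
  if (length(q) != 1 || !is.finite(q) || q <= 0 || q >= 1) {
    stop("q must be a single number in (0, 1)", call. = FALSE)
  }
  thresholds <- cfst |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      threshold_rep1 = quantile(.data$fst_rep1, q, names = FALSE),
      threshold_rep2 = quantile(.data$fst_rep2, q, names = FALSE),
      n_universe = dplyr::n(),
      .groups = "drop"
    )
  out <- cfst |>
    dplyr::left_join(thresholds, by = "country") |>
    dplyr::filter(.data$fst_rep1 > .data$threshold_rep1,
                  .data$fst_rep2 > .data$threshold_rep2) |>
    dplyr::mutate(q = q) |>
    dplyr::select("country", "contig", "fst_rep1", "fst_rep2", "fst_mean", "q")
  attr(out, "thresholds") <- thresholds
  out
}

#' Hypergeometric null for the overlap of two outlier sets
#'
#' If two sets of sizes `n_a` and `n_b` are drawn at random from a universe
#' of `N` contigs, their overlap follows a hypergeometric distribution with
#' expectation `n_a * n_b / N`. The discrete 95% confidence limits are
#' `ci_low`, the largest overlap `k` whose lower tail `P(K <= k - 1)` is at
#' most 0.025, and `ci_high`, the smallest `k` with `P(K <= k) >= 0.975`.
#' Observed sharing above `ci_high` indicates more reuse of the same contigs
#' than chance alone produces.
#'
#' @param N Universe size (contigs entering both scans).
#' @param n_a,n_b Sizes of the two outlier sets.
#' @return A one-row tibble: `N`, `n_a`, `n_b`, `expected`, `ci_low`,
#'   `ci_high`.
#' @export
#' @examples
#' hypergeometric_null(100, 10, 20) # expected overlap 2
hypergeometric_null <- function(N, n_a, n_b) {
  stopifnot(length(N) == 1, length(n_a) == 1, length(n_b) == 1)
  if (N < 0 || n_a < 0 || n_b < 0 || n_a > N || n_b > N) {
    stop("need 0 <= n_a, n_b <= N", call. = FALSE)
  }
  if (N == 0) {
    return(tibble::tibble(N = 0L, n_a = 0L, n_b = 0L, expected = 0,
                          ci_low = 0L, ci_high = 0L))
  }
  k <- max(0, n_a + n_b - N):min(n_a, n_b)
  cdf <- phyper(k, n_a, N - n_a, n_b)
  cdf_prev <- phyper(k - 1, n_a, N - n_a, n_b)
  eps <- 1e-12
  tibble::tibble(
    N = as.integer(N), n_a = as.integer(n_a), n_b = as.integer(n_b),
    expected = n_a * n_b / N,
    ci_low = as.integer(max(k[cdf_prev <= 0.025 + eps])),
    ci_high = as.integer(min(k[cdf >= 0.975 - eps]))
  )
}

sharing_row <- function(id_a, id_b, set_a, set_b, universe) {
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("outlier sets contain contigs outside the shared universe",
         call. = FALSE)
  }
  shared <- intersect(set_a, set_b)
  null <- hypergeometric_null(length(universe), length(set_a), length(set_b))
  tibble::tibble(
    set_a = id_a, set_b = id_b,
    N = null$N, n_a = null$n_a, n_b = null$n_b,
    observed_shared = length(shared),
    expected_shared = null$expected,
    ci_low = null$ci_low, ci_high = null$ci_high,
    exceeds_chance = length(shared) > null$ci_high,
    prop_a = ifelse(null$n_a > 0, length(shared) / null$n_a, NA_real_),
    prop_b = ifelse(null$n_b > 0, length(shared) / null$n_b, NA_real_),
    jaccard = ifelse(length(union(set_a, set_b)) > 0,
                     length(shared) / length(union(set_a, set_b)), NA_real_),
    shared_contigs = list(shared)
  )
}

#' Outlier sharing between countries versus the chance expectation
#'
#' For every pair of countries, intersects the replicate-consistent outlier
#' sets and compares the observed overlap with the hypergeometric chance
#' null ([hypergeometric_null()]) conditioned on the realised set sizes.
#' Sharing proportions are reported relative to each focal country's outlier
#' count (the scale on which sharing fractions such as "13-20% of a
#' country's outliers" are quoted), plus the symmetric Jaccard index.
#'
#' @param outliers Outlier tibble from [detect_outliers()].
#' @param universe Character vector of all contigs entering the scan in
#'   every country (the common universe `N`); typically
#'   `unique(cfst$contig)` for a complete [country_fst()] table.
#' @param countries Countries to compare (default: those present in
#'   `outliers`; pass the design's country list explicitly so that empty
#'   outlier sets are still compared).
#' @return A tibble with one row per country pair: `set_a`, `set_b`, `N`,
#'   `n_a`, `n_b`, `observed_shared`, `expected_shared`, `ci_low`,
#'   `ci_high`, `exceeds_chance`, `prop_a`, `prop_b`, `jaccard`, and the
#'   list-column `shared_contigs`.
#' @export
shared_outliers <- function(outliers, universe,
                            countries = sort(unique(outliers$country))) {
  sets <- lapply(setNames(countries, countries),
                 function(ct) outliers$contig[outliers$country == ct])
  if (length(countries) < 2) {
    stop("shared_outliers needs outlier sets from at least two countries",
         call. = FALSE)
  }
  combos <- utils::combn(countries, 2, simplify = FALSE)
  purrr::map_dfr(combos, function(cc) {
    sharing_row(cc[1], cc[2], sets[[cc[1]]], sets[[cc[2]]], universe)
  })
}

#' Contigs outlying in all countries
#'
#' @param outliers Outlier tibble from [detect_outliers()].
#' @param countries Countries to intersect (default: those present in
#'   `outliers`; pass the full design list so a country with no outliers
#'   forces an empty intersection).
#' @return Character vector: the intersection of all countries' outlier
#'   sets.
#' @export
three_way_shared <- function(outliers,
                             countries = sort(unique(outliers$country))) {
  if (length(countries) == 0) return(character())
  sets <- lapply(countries,
                 function(ct) outliers$contig[outliers$country == ct])
  Reduce(intersect, sets)
}

#' Sharing of marginal outlier sets between replicate sample pairs
#'
#' Within each country, takes the top-`q` contigs of each replicate's
#' between-ecotype FST distribution separately (no consistency requirement)
#' and reports their overlap against the hypergeometric null. Real
#' divergent selection makes the two replicate sets agree far beyond
#' chance; lack of agreement reflects experimental noise.
#'
#' @param cfst Country-level FST tibble from [country_fst()].
#' @param q Quantile threshold.
#' @return Sharing tibble (one row per country) in the format of
#'   [shared_outliers()], with `prop_shared` = observed overlap divided by
#'   the mean marginal set size.
#' @export
replicate_sharing <- function(cfst, q = 0.94) {
  purrr::map_dfr(split(cfst, cfst$country), function(sub) {
    thr1 <- quantile(sub$fst_rep1, q, names = FALSE)
    thr2 <- quantile(sub$fst_rep2, q, names = FALSE)
    set1 <- sub$contig[sub$fst_rep1 > thr1]
    set2 <- sub$contig[sub$fst_rep2 > thr2]
    row <- sharing_row(paste0(sub$country[1], "_rep1"),
                       paste0(sub$country[1], "_rep2"),
                       set1, set2, sub$contig)
    row$country <- sub$country[1]
    row$prop_shared <- row$observed_shared / mean(c(row$n_a, row$n_b))
    row
  })
}

#' Negative-control sharing between nonreplicate sample pairs
#'
#' Within each country, treats the two within-ecotype FST tables
#' (crab1-crab2 and wave1-wave2) as a pseudo-replicate pair: no real
#' ecotype-divergence outliers can exist in either, so their top-`q` sets
#' should overlap only as much as chance allows. Reported in the format of
#' [shared_outliers()].
#'
#' @param fst Per-contig FST tibble from [all_pair_fst()] (the
#'   within-ecotype rows are used).
#' @param q Quantile threshold.
#' @return Sharing tibble with one row per country (`set_a` = crab pair,
#'   `set_b` = wave pair), including `prop_shared` as in
#'   [replicate_sharing()].
#' @export
control_sharing <- function(fst, q = 0.94) {
  within <- fst[fst$comparison == "within_ecotype", ]
  wide <- within |>
    dplyr::select("contig", "country", "ecotype", "fst") |>
    tidyr::pivot_wider(names_from = "ecotype", values_from = "fst") |>
    dplyr::filter(!is.na(.data$crab), !is.na(.data$wave))
  purrr::map_dfr(split(wide, wide$country), function(sub) {
    thr_c <- quantile(sub$crab, q, names = FALSE)
    thr_w <- quantile(sub$wave, q, names = FALSE)
    set_c <- sub$contig[sub$crab > thr_c]
    set_w <- sub$contig[sub$wave > thr_w]
    row <- sharing_row(paste0(sub$country[1], "_crab.crab"),
                       paste0(sub$country[1], "_wave.wave"),
                       set_c, set_w, sub$contig)
    row$country <- sub$country[1]
    row$prop_shared <- row$observed_shared / mean(c(row$n_a, row$n_b))
    row
  })
}
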