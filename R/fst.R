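#' Per-SNP expected heterozygosities for a pool pair
#'
#' For a biallelic SNP with allele frequencies `p1` and `p2` in two pools,
#' the within-pool expected heterozygosity is the average of the two
#' single-pool values, `hw = (2 p1 (1 - p1) + 2 p2 (1 - p2)) / 2`, and the
#' total expected heterozygosity treats the two pools as one population at
#' the mean frequency, `ht = 2 pbar (1 - pbar)` with `pbar = (p1 + p2) / 2`.
#' `ht - hw = (p1 - p2)^2 / 2 >= 0` always, and both quantities are
#' invariant to which allele's frequency is tracked.
#'
#' @param p1,p2 Numeric vectors of allele frequencies in `[0, 1]`.
#' @return A tibble with columns `hw` and `ht`.
#' @export
#' @examples
#' snp_heterozygosities(1, 0.5) # hw = 0.25, ht = 0.375
snp_heterozygosities <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  pbar <- (p1 + p2) / 2
  tibble::tibble(
    hw = (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2,
    ht = 2 * pbar * (1 - pbar)
  )
}

# per-SNP frequency of the major allele in each sample
snp_frequencies <- function(snps) {
  snps$major_count / (snps$major_count + snps$minor_count)
}

# site x sample matrix of major-allele frequencies, plus the contig of each
# site; the shared internal layout of the FST and SNP-difference engines
freq_matrix <- function(snps) {
  site_key <- paste(snps$contig, snps$position, sep = "\r")
  sites <- !duplicated(site_key)
  site_ids <- site_key[sites]
  samples <- unique(snps$sample_id)
  m <- matrix(NA_real_, nrow = length(site_ids), ncol = length(samples),
              dimnames = list(NULL, samples))
  m[cbind(match(site_key, site_ids), match(snps$sample_id, samples))] <-
    snp_frequencies(snps)
  list(freq = m, contig = snps$contig[sites], position = snps$position[sites])
}

#' Per-contig FST between sample pairs
#'
#' Computes, for every contig and every requested pool pair, the Nei-style
#' fixation index from heterozygosities averaged over the contig's SNPs:
#' `fst = (ht_mean - hw_mean) / ht_mean`, a ratio of averages rather than an
#' average of per-SNP ratios. Contigs whose `ht_mean` is zero for a pair are
#' excluded for that pair (their count is in the `"n_zero_ht"` attribute).
#'
#' @param snps SNP tibble from [call_snps()].
#' @param pairs Tibble of pool pairs with at least `pair_id`, `sample_1`,
#'   `sample_2` (see [design_pairs()]); any additional columns are carried
#'   through.
#' @return A tibble with one row per contig per pair: the `pairs` metadata
#'   plus `contig`, `hw_mean`, `ht_mean`, `fst`, `n_snps`.
#' @export
pair_fst <- function(snps, pairs) {
  stopifnot(all(c("pair_id", "sample_1", "sample_2") %in% names(pairs)))
  fm <- freq_matrix(snps)
  contig_f <- factor(fm$contig, levels = unique(fm$contig))

  one_pair <- function(i) {
    p1 <- fm$freq[, pairs$sample_1[i]]
    p2 <- fm$freq[, pairs$sample_2[i]]
    ok <- !is.na(p1) & !is.na(p2)
    pbar <- (p1[ok] + p2[ok]) / 2
    hw <- p1[ok] * (1 - p1[ok]) + p2[ok] * (1 - p2[ok])
    ht <- 2 * pbar * (1 - pbar)
    sums <- rowsum(cbind(hw, ht, 1), contig_f[ok], reorder = FALSE)
    per_contig <- tibble::tibble(
      contig = rownames(sums),
      hw_mean = sums[, 1] / sums[, 3],
      ht_mean = sums[, 2] / sums[, 3],
      n_snps = as.integer(sums[, 3])
    )
    dplyr::bind_cols(
      pairs[rep(i, nrow(per_contig)),
            setdiff(names(pairs), c("sample_1", "sample_2"))],
      per_contig
    )
  }
  out <- purrr::map_dfr(seq_len(nrow(pairs)), one_pair)
  zero_ht <- out$ht_mean <= 0
  res <- out[!zero_ht, ]
  res$fst <- (res$ht_mean - res$hw_mean) / res$ht_mean
  attr(res, "n_zero_ht") <- sum(zero_ht)
  res
}

#' FST for all design-implied sample pairs
#'
#' Convenience wrapper running [pair_fst()] over all pairs enumerated by
#' [design_pairs()]: replicate-matched between-ecotype pairs per country,
#' within-ecotype control pairs, and the four ecotype/replicate-matched
#' between-country pairs per country pair.
#'
#' @param snps SNP tibble from [call_snps()].
#' @param design A `pool_design` tibble.
#' @return Per-contig per-pair FST tibble (see [pair_fst()]), with the
#'   `comparison`, `country`, `replicate` and `ecotype` metadata of
#'   [design_pairs()].
#' @export
all_pair_fst <- function(snps, design) {
  pair_fst(snps, design_pairs(design))
}

#' Summarise FST across contigs
#'
#' Mean FST with its standard error across contigs (sample SD divided by the
#' square root of the number of contigs), per pair and per comparison class.
#'
#' @param fst Per-contig FST tibble from [all_pair_fst()].
#' @return A tibble with one row per pair (`comparison`, `pair_id`,
#'   `country`, `mean_fst`, `se_fst`, `n_contigs`).
#' @export
fst_summary <- function(fst) {
  fst |>
    dplyr::group_by(.data$comparison, .data$pair_id, .data$country) |>
    dplyr::summarise(
      mean_fst = mean(.data$fst),
      se_fst = sd(.data$fst) / sqrt(dplyr::n()),
      n_contigs = dplyr::n(),
      .groups = "drop"
    )
}

#' Replicate between-ecotype FST estimates per country
#'
#' Reshapes the between-ecotype rows of [all_pair_fst()] into one row per
#' contig per country with both replicate estimates and their mean. Only
#' contigs with both replicate estimates defined are returned.
#'
#' @param fst Per-contig FST tibble from [all_pair_fst()].
#' @return A tibble `contig`, `country`, `fst_rep1`, `fst_rep2`,
#'   `fst_mean`.
#' @export
country_fst <- function(fst) {
  fst |>
    dplyr::filter(.data$comparison == "between_ecotype") |>
    dplyr::select("contig", "country", "replicate", "fst") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "fst",
                       names_prefix = "fst_rep") |>
    dplyr::filter(!is.na(.data$fst_rep1), !is.na(.data$fst_rep2)) |>
    dplyr::mutate(fst_mean = (.data$fst_rep1 + .data$fst_rep2) / 2)
}

#' Per-contig between-country FST
#'
#' Averages, per contig and country pair, the FST of the four
#' ecotype/replicate-matched cross-country pool pairs, giving one
#' between-country estimate per contig with balanced ecotype composition.
#'
#' @param fst Per-contig FST tibble from [all_pair_fst()].
#' @return A tibble `contig`, `country_pair`, `fst`, `n_pairs`.
#' @export
between_country_fst <- function(fst) {
  fst |>
    dplyr::filter(.data$comparison == "between_country") |>
    dplyr::group_by(contig = .data$contig, country_pair = .data$country) |>
    dplyr::summarise(n_pairs = dplyr::n(), fst = mean(.data$fst),
                     .groups = "drop")
}

#' Correlation of FST estimates between replicates and between countries
#'
#' Pearson correlations of per-contig between-ecotype FST: between the two
#' replicate estimates within each country (a reliability check — strongly
#' correlated replicates indicate that pool noise is under control), and
#' between the replicate-averaged estimates of each country pair (weak
#' correlations are expected when the loci responding to selection differ
#' between locations). Requires at least 3 shared contigs; comparisons with
#' zero variance in either vector are reported as `NA`.
#'
#' @param cfst Country-level FST tibble from [country_fst()].
#' @return A tibble with columns `comparison` (`"replicates"` or
#'   `"countries"`), `id` (country or country pair), `r`, `n`.
#' @export
replicate_correlation <- function(cfst) {
  safe_cor <- function(x, y) {
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  reps <- cfst |>
    dplyr::group_by(id = .data$country) |>
    dplyr::summarise(comparison = "replicates",
                     r = safe_cor(.data$fst_rep1, .data$fst_rep2),
                     n = dplyr::n(), .groups = "drop")
  countries <- sort(unique(cfst$country))
  cross <- tibble::tibble()
  if (length(countries) >= 2) {
    wide <- cfst |>
      dplyr::select("contig", "country", "fst_mean") |>
      tidyr::pivot_wider(names_from = "country", values_from = "fst_mean")
    combos <- utils::combn(countries, 2, simplify = FALSE)
    cross <- purrr::map_dfr(combos, function(cc) {
      both <- wide[!is.na(wide[[cc[1]]]) & !is.na(wide[[cc[2]]]), ]
      tibble::tibble(
        id = paste(cc[1], cc[2], sep = "-"),
        comparison = "countries",
        r = safe_cor(both[[cc[1]]], both[[cc[2]]]),
        n = nrow(both)
      )
    })
  }
  dplyr::bind_rows(reps, cross)[c("comparison", "id", "r", "n")]
}
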