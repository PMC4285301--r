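#' Configuration for the synthetic pool-seq generator
#'
#' Builds a validated configuration emulating a replicated two-ecotype
#' pooled transcriptome study: three countries, two ecotypes, two replicate
#' pools of `pool_individuals` diploid females each, short contigs carrying
#' few SNPs, and RNA-seq-like overdispersed coverage.
#'
#' @param n_contigs Number of contigs.
#' @param snp_mean Mean SNPs per contig; counts are drawn from a geometric
#'   distribution on 1, 2, ... truncated at `snp_max`.
#' @param snp_max Maximum SNPs per contig.
#' @param countries Character vector of country codes.
#' @param pool_individuals Diploid individuals per pool (default 40).
#' @param ancestral_beta Shape parameters `c(a, b)` of the Beta distribution
#'   of ancestral allele frequencies.
#' @param drift_sd Standard deviation, on the logit scale, of the
#'   per-country perturbation of each SNP's ancestral frequency (shared by
#'   both ecotypes; generates between-country differentiation).
#' @param country_corr Correlation of the drift deviates between the two
#'   countries in `corr_pair` (emulating a shared colonization history);
#'   0 disables it.
#' @param corr_pair The country pair subject to `country_corr`.
#' @param frac_shared_selected Fraction of contigs under divergent ecotype
#'   selection in the same direction in all countries.
#' @param frac_country_specific Fraction under selection in a single country
#'   (assigned round-robin across countries).
#' @param frac_sign_flipped Fraction under selection with opposite direction
#'   in the two countries of `flip_pair` (and neutral elsewhere).
#' @param flip_pair The country pair with opposite-direction selection.
#' @param effect_delta Ecotype allele-frequency shift at selected contigs'
#'   SNPs: crab and wave frequencies are the country frequency plus and
#'   minus `effect_delta / 2` (times the contig's per-country sign).
#' @param selected_min_snps Minimum SNPs per selected contig (selected loci
#'   are modelled as multi-SNP contigs, where linked differentiation makes
#'   the contig-level signal detectable).
#' @param coverage_mean,coverage_dispersion Mean and dispersion (`size`) of
#'   the negative binomial read coverage per sample and site.
#' @param error_rate Per-read probability of a miscall, redistributed
#'   uniformly over the other three nucleotides.
#' @param contig_length Contig length in bp over which SNP positions are
#'   placed (default 660, a short transcriptome-assembly contig).
#' @return A validated list with class `sim_config`.
#' @export
sim_config <- function(n_contigs = 2000,
                       snp_mean = 3,
                       snp_max = 20,
                       countries = c("SP", "SW", "UK"),
                       pool_individuals = 40,
                       ancestral_beta = c(1, 1),
                       drift_sd = 0.5,
                       country_corr = 0,
                       corr_pair = c("SW", "UK"),
                       frac_shared_selected = 0.02,
                       frac_country_specific = 0.06,
                       frac_sign_flipped = 0.02,
                       flip_pair = c("SP", "UK"),
                       effect_delta = 0.3,
                       selected_min_snps = 3,
                       coverage_mean = 50,
                       coverage_dispersion = 5,
                       error_rate = 0.002,
                       contig_length = 660) {
  cfg <- list(
    n_contigs = as.integer(n_contigs), snp_mean = snp_mean,
    snp_max = as.integer(snp_max), countries = as.character(countries),
    pool_individuals = as.integer(pool_individuals),
    ancestral_beta = as.numeric(ancestral_beta), drift_sd = drift_sd,
    country_corr = country_corr, corr_pair = as.character(corr_pair),
    frac_shared_selected = frac_shared_selected,
    frac_country_specific = frac_country_specific,
    frac_sign_flipped = frac_sign_flipped,
    flip_pair = as.character(flip_pair),
    effect_delta = effect_delta,
    selected_min_snps = as.integer(selected_min_snps),
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    error_rate = error_rate, contig_length = as.integer(contig_length)
  )
  stopifnot(
    cfg$n_contigs >= 1, cfg$snp_mean >= 1, cfg$snp_max >= 1,
    length(cfg$countries) >= 1, !anyDuplicated(cfg$countries),
    cfg$pool_individuals >= 1,
    length(cfg$ancestral_beta) == 2, all(cfg$ancestral_beta > 0),
    cfg$drift_sd >= 0, abs(cfg$country_corr) <= 1,
    cfg$frac_shared_selected >= 0, cfg$frac_country_specific >= 0,
    cfg$frac_sign_flipped >= 0,
    cfg$effect_delta > 0, cfg$effect_delta <= 0.5,
    cfg$coverage_mean > 0, cfg$coverage_dispersion > 0,
    cfg$error_rate >= 0, cfg$error_rate < 1,
    cfg$contig_length >= cfg$snp_max
  )
  total_frac <- cfg$frac_shared_selected + cfg$frac_country_specific +
    cfg$frac_sign_flipped
  if (total_frac > 1) {
    stop("selected-contig fractions sum to more than 1", call. = FALSE)
  }
  if (cfg$frac_sign_flipped > 0 &&
      !all(cfg$flip_pair %in% cfg$countries)) {
    stop("flip_pair countries must be in countries", call. = FALSE)
  }
  if (cfg$country_corr != 0 && !all(cfg$corr_pair %in% cfg$countries)) {
    stop("corr_pair countries must be in countries", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

clamp_freq <- function(p, lo = 0.02, hi = 0.98) pmin(pmax(p, lo), hi)

# contig labels in the truth-table vocabulary
assign_labels <- function(cfg) {
  n <- cfg$n_contigs
  n_shared <- round(cfg$frac_shared_selected * n)
  n_specific <- round(cfg$frac_country_specific * n)
  n_flip <- round(cfg$frac_sign_flipped * n)
  labels <- rep("neutral", n)
  sel <- sample.int(n, n_shared + n_specific + n_flip)
  if (n_shared > 0) labels[sel[seq_len(n_shared)]] <- "shared_selected"
  if (n_specific > 0) {
    idx <- sel[n_shared + seq_len(n_specific)]
    labels[idx] <- paste0("country_specific:",
                          rep_len(cfg$countries, n_specific))
  }
  if (n_flip > 0) {
    idx <- sel[n_shared + n_specific + seq_len(n_flip)]
    labels[idx] <- paste0("sign_flipped:", cfg$flip_pair[1], ":",
                          cfg$flip_pair[2])
  }
  labels
}

# per-contig per-country selection sign (+1: crab allele up, 0: neutral)
label_signs <- function(labels, countries) {
  signs <- matrix(0, nrow = length(labels), ncol = length(countries),
                  dimnames = list(NULL, countries))
  signs[labels == "shared_selected", ] <- 1
  specific <- stringr::str_match(labels, "^country_specific:(.+)$")[, 2]
  for (ct in countries) signs[!is.na(specific) & specific == ct, ct] <- 1
  flip <- stringr::str_match(labels, "^sign_flipped:([^:]+):([^:]+)$")
  has_flip <- !is.na(flip[, 1])
  if (any(has_flip)) {
    for (i in which(has_flip)) {
      signs[i, flip[i, 2]] <- 1
      signs[i, flip[i, 3]] <- -1
    }
  }
  signs
}

# distinct SNP positions per contig
draw_positions <- function(contig_idx, contig_length) {
  pos <- sample.int(contig_length, length(contig_idx), replace = TRUE)
  repeat {
    dup <- duplicated(paste(contig_idx, pos, sep = "\r"))
    if (!any(dup)) break
    pos[dup] <- sample.int(contig_length, sum(dup), replace = TRUE)
  }
  pos
}

#' Simulate a replicated pooled transcriptome-scan dataset
#'
#' Generates sync-format allele counts, the matching pool design and a
#' per-contig truth table under a hierarchical model: ancestral allele
#' frequencies are Beta-distributed; each country perturbs them on the
#' logit scale (normal deviates with SD `drift_sd`, optionally correlated
#' for one designated country pair); selected contigs shift the crab and
#' wave frequencies apart by `effect_delta` at every SNP (complete linkage
#' within the short contig), with per-country signs given by the contig's
#' label; each replicate pool's allele frequency is a binomial draw of
#' `2 * pool_individuals` allele copies; read coverage per pool and site is
#' negative binomial; and read counts are binomial in the pool frequency
#' with a fraction `error_rate` of reads miscalled uniformly to the other
#' three nucleotides. All frequencies are clamped to `[0.02, 0.98]`.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; the same seed yields byte-identical sync
#'   output.
#' @return A list of class `pool_sim`: `sync` (long sync tibble), `design`
#'   (`pool_design`), `truth` (tibble `contig`, `label`, one realized mean
#'   crab-minus-wave frequency difference column `delta_<country>` per
#'   country, and `n_snps`).
#' @export
simulate_pool_seq <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_stage_seed(seed, 0L, {
    countries <- cfg$countries
    n_country <- length(countries)
    design <- pool_design(tibble::tibble(
      sample_id = paste0(rep(countries, each = 4), "_",
                         rep(c("crab", "crab", "wave", "wave"), n_country),
                         rep(c(1, 2, 1, 2), n_country)),
      country = rep(countries, each = 4),
      ecotype = rep(c("crab", "crab", "wave", "wave"), n_country),
      replicate = rep(c(1L, 2L, 1L, 2L), n_country)
    ))

    contigs <- sprintf("contig_%05d", seq_len(cfg$n_contigs))
    labels <- assign_labels(cfg)
    signs <- label_signs(labels, countries)
    k <- pmin(1L + rgeom(cfg$n_contigs, 1 / cfg$snp_mean), cfg$snp_max)
    selected <- labels != "neutral"
    k[selected] <- pmax(k[selected], cfg$selected_min_snps)

    contig_idx <- rep(seq_len(cfg$n_contigs), times = k)
    n_snps <- length(contig_idx)
    position <- draw_positions(contig_idx, cfg$contig_length)

    pi0 <- clamp_freq(rbeta(n_snps, cfg$ancestral_beta[1], cfg$ancestral_beta[2]))
    eps <- matrix(rnorm(n_snps * n_country, sd = cfg$drift_sd),
                  ncol = n_country, dimnames = list(NULL, countries))
    if (cfg$country_corr != 0 && cfg$drift_sd > 0) {
      a <- cfg$corr_pair[1]; b <- cfg$corr_pair[2]
      eps[, b] <- cfg$country_corr * eps[, a] +
        sqrt(1 - cfg$country_corr^2) * eps[, b]
    }
    f_country <- plogis(qlogis(pi0) + eps) # n_snps x n_country

    # ecotype frequencies per SNP x country
    s <- signs[contig_idx, , drop = FALSE]
    f_crab <- clamp_freq(f_country + s * cfg$effect_delta / 2)
    f_wave <- clamp_freq(f_country - s * cfg$effect_delta / 2)

    # expand to one row per SNP x pool
    n_pools <- nrow(design)
    pool_country <- match(design$country, countries)
    idx_snp <- rep(seq_len(n_snps), times = n_pools)
    idx_pool <- rep(seq_len(n_pools), each = n_snps)
    f_eco <- ifelse(design$ecotype[idx_pool] == "crab",
                    f_crab[cbind(idx_snp, pool_country[idx_pool])],
                    f_wave[cbind(idx_snp, pool_country[idx_pool])])
    copies <- 2L * cfg$pool_individuals
    f_pool <- rbinom(length(f_eco), copies, f_eco) / copies

    coverage <- rnbinom(length(f_pool), mu = cfg$coverage_mean,
                        size = cfg$coverage_dispersion)
    n1 <- rbinom(length(f_pool), coverage, f_pool)
    n2 <- coverage - n1

    # nucleotide identities per SNP: allele 1 (reference) and allele 2
    nuc1 <- sample.int(4L, n_snps, replace = TRUE)
    nuc2 <- 1L + (nuc1 - 1L + sample.int(3L, n_snps, replace = TRUE)) %% 4L

    counts <- matrix(0L, nrow = length(f_pool), ncol = 4)
    others_of <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                       c(1L, 2L, 3L))
    miscall <- function(src_count, src_nuc) {
      e <- rbinom(length(src_count), src_count, cfg$error_rate)
      # split errors uniformly over the three other nucleotides
      e1 <- rbinom(length(e), e, 1 / 3)
      e2 <- rbinom(length(e), e - e1, 1 / 2)
      e3 <- e - e1 - e2
      list(kept = src_count - e,
           dest = others_of[src_nuc, , drop = FALSE], err = cbind(e1, e2, e3))
    }
    snp_of_row <- idx_snp
    m1 <- miscall(n1, nuc1[snp_of_row])
    m2 <- miscall(n2, nuc2[snp_of_row])
    rows <- seq_along(f_pool)
    add <- function(col_idx, val) {
      counts[cbind(rows, col_idx)] <<- counts[cbind(rows, col_idx)] + val
    }
    add(nuc1[snp_of_row], m1$kept)
    add(nuc2[snp_of_row], m2$kept)
    for (j in 1:3) {
      add(m1$dest[, j], m1$err[, j])
      add(m2$dest[, j], m2$err[, j])
    }

    sync <- tibble::tibble(
      contig = rep(contigs[contig_idx], times = n_pools),
      position = rep(position, times = n_pools),
      ref = rep(NUCLEOTIDES[nuc1], times = n_pools),
      sample_id = design$sample_id[idx_pool],
      a = counts[, 1], t = counts[, 2], c = counts[, 3], g = counts[, 4],
      n = 0L, del = 0L
    )
    # sync files are ordered by site, samples across columns
    ord <- order(contig_idx[idx_snp], position[idx_snp], idx_pool,
                 method = "radix")
    sync <- sync[ord, ]

    realized <- f_crab - f_wave # population-level, before pool sampling
    truth <- tibble::tibble(contig = contigs, label = labels,
                            n_snps = as.integer(k))
    for (ci in seq_along(countries)) {
      truth[[paste0("delta_", countries[ci])]] <-
        as.numeric(rowsum(realized[, ci], contig_idx) / k)
    }
    structure(list(sync = sync, design = design, truth = truth),
              class = "pool_sim")
  })
}

truth_label_pattern <-
  "^(neutral|shared_selected|country_specific:[A-Za-z0-9]+|sign_flipped:[A-Za-z0-9]+:[A-Za-z0-9]+)$"

#' Write / read a simulation truth table
#'
#' Lossless TSV round trip of the per-contig truth labels and realized
#' ecotype frequency differences from [simulate_pool_seq()].
#'
#' @param truth Truth tibble.
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   validated tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), label = readr::col_character(),
    n_snps = readr::col_integer(), .default = readr::col_double()
  ), progress = FALSE)
  bad <- !grepl(truth_label_pattern, truth$label)
  if (any(bad)) {
    stop("unknown truth label: ", truth$label[which(bad)[1]], call. = FALSE)
  }
  truth
}
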