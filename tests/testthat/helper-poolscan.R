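# Shared fixture builders: everything is constructed in code at test time.

# the canonical 3 countries x 2 ecotypes x 2 replicates design
demo_design <- function(countries = c("SP", "SW", "UK")) {
  pool_design(tibble::tibble(
    sample_id = paste0(rep(countries, each = 4), "_",
                       rep(c("crab", "crab", "wave", "wave"),
                           length(countries)),
                       rep(c(1, 2, 1, 2), length(countries))),
    country = rep(countries, each = 4),
    ecotype = rep(c("crab", "crab", "wave", "wave"), length(countries)),
    replicate = rep(c(1L, 2L, 1L, 2L), length(countries))
  ))
}

# long sync tibble for one or more sites; counts is a list of named lists,
# one per site, each mapping sample_id -> c(a, t, c, g, n, del)
make_sync <- function(counts, contig = "c1", positions = seq_along(counts),
                      ref = "A") {
  purrr::map_dfr(seq_along(counts), function(i) {
    site <- counts[[i]]
    m <- do.call(rbind, site)
    tibble::tibble(
      contig = contig, position = positions[i], ref = ref,
      sample_id = names(site),
      a = m[, 1], t = m[, 2], c = m[, 3], g = m[, 4], n = m[, 5],
      del = m[, 6]
    )
  })
}

# SNP tibble directly from per-sample major-allele frequencies:
# freqs is a named list site_id -> named numeric vector (sample -> p);
# counts are exact at the given coverage, so frequencies are recovered
# without sampling noise
snps_from_freq <- function(freqs, contig = "c1", coverage = 20,
                           major = "A", minor = "T") {
  purrr::map_dfr(seq_along(freqs), function(i) {
    p <- freqs[[i]]
    stopifnot(all(abs(p * coverage - round(p * coverage)) < 1e-9))
    tibble::tibble(
      contig = contig, position = i, major = major, minor = minor,
      sample_id = names(p),
      major_count = as.integer(round(p * coverage)),
      minor_count = as.integer(coverage - round(p * coverage))
    )
  })
}

# multi-contig variant: freqs_by_contig is a named list contig -> list of
# sites as in snps_from_freq
snps_table <- function(freqs_by_contig, coverage = 20) {
  purrr::map_dfr(names(freqs_by_contig), function(ct) {
    snps_from_freq(freqs_by_contig[[ct]], contig = ct, coverage = coverage)
  })
}
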