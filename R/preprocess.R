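#' Remove positions containing deletions
#'
#' Any position at which any pool has at least one deletion-supporting read
#' is dropped entirely, mirroring the removal of deletion-containing
#' positions during sync-file generation. The number of dropped positions is
#' recorded in the `"n_dropped"` attribute and reported via a message.
#'
#' @param sync Long sync tibble ([read_sync()]).
#' @param quiet Suppress the message.
#' @return Filtered sync tibble; attribute `n_dropped` holds the number of
#'   removed positions.
#' @export
drop_deletion_sites <- function(sync, quiet = FALSE) {
  site_key <- paste(sync$contig, sync$position, sep = "\r")
  bad_sites <- unique(site_key[sync$del > 0])
  keep <- !site_key %in% bad_sites
  out <- sync[keep, ]
  if (!quiet && length(bad_sites) > 0) {
    message(length(bad_sites), " position(s) with deletion reads removed")
  }
  attr(out, "n_dropped") <- length(bad_sites)
  out
}

# Vectorised multinomial draw by sequential conditional binomials:
# size[i] trials over 4 cells with probabilities proportional to
# (a, t, c, g)[i]. Exact multinomial sampling, vectorised over rows.
rmultinom4 <- function(size, a, t, c, g) {
  tot <- a + t + c + g
  pa <- ifelse(tot > 0, a / tot, 0)
  xa <- rbinom(length(size), size, pa)
  rem <- size - xa
  den <- tot - a
  xt <- rbinom(length(size), rem, ifelse(den > 0, t / den, 0))
  rem <- rem - xt
  den <- den - t
  xc <- rbinom(length(size), rem, ifelse(den > 0, c / den, 0))
  xg <- rem - xc
  list(a = xa, t = xt, c = xc, g = xg)
}

#' Subsample counts to even coverage
#'
#' RNA-seq derived pool data have strongly variable coverage across loci and
#' samples; to keep FST estimates comparable every retained position is
#' resampled to the same target coverage, drawing reads with replacement
#' with probabilities proportional to the observed A/T/C/G counts
#' (multinomial resampling). Positions where any sample's coverage is below
#' `min_coverage` are excluded entirely so that all pools share one site
#' set. N and deletion counts are zeroed by construction.
#'
#' @param sync Long sync tibble.
#' @param target_coverage Coverage after resampling (default 20).
#' @param min_coverage Minimum observed coverage (per sample) for a position
#'   to be retained (default 10). May be below `target_coverage`: drawing
#'   with replacement allows upsampling.
#' @param seed Optional integer seed for the resampling stage.
#' @param quiet Suppress the filter message.
#' @return Sync tibble with every retained row having
#'   `a + t + c + g == target_coverage`; attribute `n_low_coverage` counts
#'   excluded positions.
#' @export
subsample_sync <- function(sync, target_coverage = 20, min_coverage = 10,
                           seed = NULL, quiet = FALSE) {
  stopifnot(target_coverage >= 1, min_coverage >= 1)
  site_key <- paste(sync$contig, sync$position, sep = "\r")
  cov <- sync$a + sync$t + sync$c + sync$g
  low_sites <- unique(site_key[cov < min_coverage])
  keep <- !site_key %in% low_sites
  out <- sync[keep, ]
  draws <- with_stage_seed(seed, 1L, rmultinom4(
    rep.int(as.integer(target_coverage), nrow(out)),
    out$a, out$t, out$c, out$g
  ))
  out$a <- draws$a
  out$t <- draws$t
  out$c <- draws$c
  out$g <- draws$g
  out$n <- 0L
  out$del <- 0L
  if (!quiet && length(low_sites) > 0) {
    message(length(low_sites), " position(s) below coverage ", min_coverage,
            " excluded before subsampling")
  }
  attr(out, "n_low_coverage") <- length(low_sites)
  out
}

#' Call biallelic SNPs with a global minor-allele-count threshold
#'
#' Allele counts are summed over all pools at each position; the two
#' nucleotides with the highest grand totals become the major and minor
#' allele (ties broken in the fixed order A < T < C < G). A position is
#' retained as a SNP only if the minor allele's grand total reaches
#' `min_minor_count` — with 12 pools subsampled to coverage 20 the default
#' of 24 equals 10% of all 240 reads — which filters residual sequencing
#' errors and uninformative near-monomorphic sites. Monomorphic positions
#' are always dropped. Reads supporting a third or fourth allele are
#' discarded and the per-sample counts of the two retained alleles are
#' rescaled to the target coverage by a binomial redraw over the two
#' alleles, so that `major_count + minor_count` is constant across samples
#' and sites.
#'
#' @param sync Subsampled sync tibble ([subsample_sync()]); all rows must
#'   have equal coverage.
#' @param min_minor_count Minimum summed minor-allele count (default 24).
#' @param seed Optional integer seed for the third-allele rescaling draw.
#' @return A SNP tibble with columns `contig`, `position`, `major`, `minor`
#'   (nucleotides), `sample_id`, `major_count`, `minor_count`.
#' @export
call_snps <- function(sync, min_minor_count = 24, seed = NULL) {
  cov <- sync$a + sync$t + sync$c + sync$g
  target <- cov[1]
  if (nrow(sync) > 0 && any(cov != target)) {
    stop("call_snps requires equal coverage across all rows; run subsample_sync first",
         call. = FALSE)
  }
  empty <- tibble::tibble(
    contig = character(), position = integer(),
    major = character(), minor = character(), sample_id = character(),
    major_count = integer(), minor_count = integer()
  )
  if (nrow(sync) == 0) return(empty)

  site_key <- paste(sync$contig, sync$position, sep = "\r")
  site_f <- factor(site_key, levels = unique(site_key))
  totals <- rowsum(cbind(sync$a, sync$t, sync$c, sync$g), site_f,
                   reorder = FALSE)
  # top two nucleotides per site; max.col(ties.method = "first") realises
  # the A < T < C < G tie-break because columns are in that order
  top1 <- max.col(totals, ties.method = "first")
  masked <- totals
  masked[cbind(seq_len(nrow(totals)), top1)] <- -1L
  top2 <- max.col(masked, ties.method = "first")
  minor_total <- masked[cbind(seq_len(nrow(totals)), top2)]
  keep_site <- minor_total >= max(min_minor_count, 1)

  if (!any(keep_site)) return(empty)
  site_idx <- as.integer(site_f)
  keep_row <- keep_site[site_idx]
  out <- sync[keep_row, c("contig", "position", "sample_id")]
  counts <- cbind(sync$a, sync$t, sync$c, sync$g)[keep_row, , drop = FALSE]
  rows <- seq_len(nrow(out))
  maj_col <- top1[site_idx][keep_row]
  min_col <- top2[site_idx][keep_row]
  maj <- counts[cbind(rows, maj_col)]
  mnr <- counts[cbind(rows, min_col)]

  # rescale samples carrying third-allele reads back to target coverage
  short <- maj + mnr < target
  if (any(short)) {
    two <- maj[short] + mnr[short]
    p_major <- ifelse(two > 0, maj[short] / two, 0.5)
    maj[short] <- with_stage_seed(seed, 2L,
      rbinom(sum(short), as.integer(target), p_major))
    mnr[short] <- target - maj[short]
  }
  out$major <- NUCLEOTIDES[maj_col]
  out$minor <- NUCLEOTIDES[min_col]
  out$major_count <- as.integer(maj)
  out$minor_count <- as.integer(mnr)
  out[c("contig", "position", "major", "minor", "sample_id",
        "major_count", "minor_count")]
}
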