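#' Construct and validate a pool sampling design
#'
#' A pool design maps the sample columns of a sync file, in order, to the
#' factors of a replicated two-ecotype study: each pool is one
#' (country, ecotype, replicate) combination. The canonical design of the
#' analyses in this package is three countries x two ecotypes ("crab",
#' "wave") x two replicate pools per combination, i.e. twelve pools, but any
#' fully crossed design with the same ecotype labels and at least one
#' country is accepted.
#'
#' @param design A data frame with columns `sample_id`, `country`,
#'   `ecotype` and `replicate`. Row order must match the order of the count
#'   columns in the sync file the design describes.
#' @return A validated tibble with class `pool_design` prepended, columns
#'   `sample_id` (character), `country` (character), `ecotype` (character,
#'   `"crab"` or `"wave"`) and `replicate` (integer).
#' @export
#' @examples
#' pool_design(data.frame(
#'   sample_id = c("SP_crab1", "SP_crab2", "SP_wave1", "SP_wave2"),
#'   country = "SP",
#'   ecotype = rep(c("crab", "wave"), each = 2),
#'   replicate = c(1, 2, 1, 2)
#' ))
pool_design <- function(design) {
  required <- c("sample_id", "country", "ecotype", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(design)[required]
  out$sample_id <- as.character(out$sample_id)
  out$country <- as.character(out$country)
  out$ecotype <- as.character(out$ecotype)
  rep_num <- suppressWarnings(as.integer(out$replicate))
  if (anyNA(rep_num)) {
    stop("design replicate labels must be integers", call. = FALSE)
  }
  out$replicate <- rep_num

  bad_eco <- setdiff(unique(out$ecotype), c("crab", "wave"))
  if (length(bad_eco) > 0) {
    stop("unknown ecotype label(s): ", paste(bad_eco, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(out$sample_id)) {
    stop("duplicated sample_id in design", call. = FALSE)
  }
  triple <- paste(out$country, out$ecotype, out$replicate, sep = "\r")
  if (anyDuplicated(triple)) {
    dup <- out[duplicated(triple), ]
    stop("duplicated (country, ecotype, replicate) triple: ",
         paste(dup$country, dup$ecotype, dup$replicate, collapse = "; "),
         call. = FALSE)
  }
  # every country must be fully crossed with the same ecotypes and replicates
  reps <- sort(unique(out$replicate))
  for (ctry in unique(out$country)) {
    sub <- out[out$country == ctry, ]
    expected <- expand.grid(ecotype = c("crab", "wave"), replicate = reps,
                            stringsAsFactors = FALSE)
    have <- paste(sub$ecotype, sub$replicate)
    want <- paste(expected$ecotype, expected$replicate)
    miss <- setdiff(want, have)
    if (length(miss) > 0) {
      stop("country ", ctry, " is missing pool(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  class(out) <- c("pool_design", class(out))
  out
}

#' Read a pool design table
#'
#' Reads a tab-separated design file with header
#' `sample_id  country  ecotype  replicate`, whose row order mirrors the
#' sample column order of the matching sync file, and validates it with
#' [pool_design()].
#'
#' @param path Path to the design TSV.
#' @return A validated `pool_design` tibble.
#' @export
read_design <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  pool_design(raw)
}

#' Write a pool design table
#'
#' @param design A `pool_design` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  design <- pool_design(design)
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

# sample_id of the pool for one (country, ecotype, replicate)
design_sample <- function(design, country, ecotype, replicate) {
  hit <- design$sample_id[design$country == country &
                            design$ecotype == ecotype &
                            design$replicate == replicate]
  if (length(hit) != 1) {
    stop("no unique pool for (", country, ", ", ecotype, ", ", replicate, ")",
         call. = FALSE)
  }
  hit
}

#' Enumerate the sample pairs implied by a design
#'
#' Between-ecotype pairs are the replicate-matched crab/wave pairs within
#' each country (crab1-wave1, crab2-wave2), the pairs whose FST carries the
#' divergent-selection signal. Within-ecotype pairs (crab1-crab2,
#' wave1-wave2) measure experimental noise. Between-country pairs are the
#' ecotype- and replicate-matched pools of two countries (4 pairs per
#' country pair), keeping ecotype composition balanced.
#'
#' @param design A `pool_design` tibble.
#' @param comparisons Which pair classes to enumerate (default all three).
#' @return A tibble with columns `comparison` (`"between_ecotype"`,
#'   `"within_ecotype"` or `"between_country"`), `pair_id`, `country`
#'   (or the country pair `"A-B"` for between-country rows), `replicate`
#'   (between-ecotype rows), `ecotype` (within-ecotype rows), `sample_1`,
#'   `sample_2`.
#' @export
design_pairs <- function(design,
                         comparisons = c("between_ecotype", "within_ecotype",
                                         "between_country")) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  design <- pool_design(design)
  countries <- unique(design$country)
  reps <- sort(unique(design$replicate))

  between <- purrr::map_dfr(countries, function(ctry) {
    purrr::map_dfr(reps, function(r) {
      tibble::tibble(
        comparison = "between_ecotype",
        country = ctry,
        replicate = r,
        ecotype = NA_character_,
        sample_1 = design_sample(design, ctry, "crab", r),
        sample_2 = design_sample(design, ctry, "wave", r)
      )
    })
  })
  within <- purrr::map_dfr(countries, function(ctry) {
    purrr::map_dfr(c("crab", "wave"), function(eco) {
      tibble::tibble(
        comparison = "within_ecotype",
        country = ctry,
        replicate = NA_integer_,
        ecotype = eco,
        sample_1 = design_sample(design, ctry, eco, reps[1]),
        sample_2 = design_sample(design, ctry, eco, reps[2])
      )
    })
  })
  cross <- tibble::tibble()
  if (length(countries) >= 2) {
    combos <- utils::combn(countries, 2, simplify = FALSE)
    cross <- purrr::map_dfr(combos, function(cc) {
      purrr::map_dfr(c("crab", "wave"), function(eco) {
        purrr::map_dfr(reps, function(r) {
          tibble::tibble(
            comparison = "between_country",
            country = paste(cc[1], cc[2], sep = "-"),
            replicate = r,
            ecotype = eco,
            sample_1 = design_sample(design, cc[1], eco, r),
            sample_2 = design_sample(design, cc[2], eco, r)
          )
        })
      })
    })
  }
  pairs <- dplyr::bind_rows(between, within, cross)
  pairs <- pairs[pairs$comparison %in% comparisons, ]
  pairs$pair_id <- paste(pairs$sample_1, pairs$sample_2, sep = ".")
  pairs[c("comparison", "pair_id", "country", "replicate", "ecotype",
          "sample_1", "sample_2")]
}
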