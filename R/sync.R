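#' Parse popoolation2-style count fields
#'
#' A sync count field is a colon-separated string of six non-negative
#' integers giving, in fixed order, the number of reads supporting A, T, C,
#' G, an ambiguous base (N), and a deletion at one position in one pool.
#' Site coverage is defined as `a + t + c + g`; N and deletion reads never
#' count towards coverage.
#'
#' @param text Character vector of count fields, e.g. `"10:0:5:0:0:0"`.
#' @return A tibble with one row per element of `text` and integer columns
#'   `a`, `t`, `c`, `g`, `n`, `del`, plus `coverage = a + t + c + g`.
#' @export
#' @examples
#' parse_count_field(c("10:0:5:0:0:0", "0:0:0:0:0:0"))
parse_count_field <- function(text) {
  parts <- stringr::str_split(text, stringr::fixed(":"))
  n_fields <- lengths(parts)
  if (any(n_fields != 6)) {
    bad <- which(n_fields != 6)[1]
    stop("count field ", bad, " ('", text[bad], "') has ", n_fields[bad],
         " fields; expected 6 (A:T:C:G:N:del)", call. = FALSE)
  }
  flat <- unlist(parts, use.names = FALSE)
  vals <- suppressWarnings(as.integer(flat))
  bad <- is.na(vals) | flat != as.character(vals) | vals < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop("count field ", ceiling(i / 6), " ('", text[ceiling(i / 6)],
         "'): '", flat[i], "' is not a non-negative integer", call. = FALSE)
  }
  m <- matrix(vals, ncol = 6, byrow = TRUE)
  tibble::tibble(
    a = m[, 1], t = m[, 2], c = m[, 3], g = m[, 4], n = m[, 5], del = m[, 6],
    coverage = m[, 1] + m[, 2] + m[, 3] + m[, 4]
  )
}

format_count_field <- function(counts) {
  sprintf("%d:%d:%d:%d:%d:%d",
          counts$a, counts$t, counts$c, counts$g, counts$n, counts$del)
}

#' Read a sync allele-count file
#'
#' Reads a tab-separated sync file (no header): reference contig, 1-based
#' position, reference base, then one `A:T:C:G:N:del` count field per pool,
#' in the order given by `design`. The result is a long tibble with one row
#' per position per pool, the layout every downstream stage of the package
#' consumes.
#'
#' @param path Path to the sync file.
#' @param design A `pool_design` tibble ([pool_design()]); the number of
#'   count columns in the file must equal `nrow(design)`.
#' @return A tibble with columns `contig`, `position`, `ref`, `sample_id`,
#'   `a`, `t`, `c`, `g`, `n`, `del`, ordered by file line then design sample
#'   order.
#' @export
read_sync <- function(path, design) {
  design <- pool_design(design)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[lines != ""]
  empty <- tibble::tibble(
    contig = character(), position = integer(), ref = character(),
    sample_id = character(),
    a = integer(), t = integer(), c = integer(), g = integer(),
    n = integer(), del = integer()
  )
  if (length(lines) == 0) return(empty)

  fields <- stringr::str_split(lines, stringr::fixed("\t"))
  n_cols <- lengths(fields)
  expected <- 3L + nrow(design)
  if (any(n_cols != expected)) {
    bad <- which(n_cols != expected)[1]
    stop("sync line ", bad, " has ", n_cols[bad], " columns; design with ",
         nrow(design), " pools requires ", expected, call. = FALSE)
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = expected, byrow = TRUE)
  position <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(position) || any(position < 1)) {
    bad <- which(is.na(position) | position < 1)[1]
    stop("sync line ", bad, ": position '", m[bad, 2],
         "' is not a positive integer", call. = FALSE)
  }
  ref <- toupper(m[, 3])
  bad_ref <- !ref %in% c(NUCLEOTIDES, "N")
  if (any(bad_ref)) {
    bad <- which(bad_ref)[1]
    stop("sync line ", bad, ": reference base '", m[bad, 3], "' is not one of A,T,C,G,N",
         call. = FALSE)
  }

  n_lines <- length(lines)
  n_samples <- nrow(design)
  # one row per line x sample, sample fastest (matches design column order)
  count_text <- as.vector(t(m[, -(1:3), drop = FALSE]))
  counts <- withCallingHandlers(
    parse_count_field(count_text),
    error = function(e) e
  )
  if (inherits(counts, "error")) {
    stop("while parsing sync count fields: ", conditionMessage(counts),
         call. = FALSE)
  }
  tibble::tibble(
    contig = rep(m[, 1], each = n_samples),
    position = rep(position, each = n_samples),
    ref = rep(ref, each = n_samples),
    sample_id = rep(design$sample_id, times = n_lines),
    a = counts$a, t = counts$t, c = counts$c, g = counts$g,
    n = counts$n, del = counts$del
  )
}

#' Write a sync allele-count file
#'
#' Inverse of [read_sync()]: a well-formed sync tibble written with
#' `write_sync()` and read back yields the identical table, and for files
#' produced elsewhere the round trip is byte-identical up to a trailing
#' newline.
#'
#' @param sync Long sync tibble as produced by [read_sync()] or
#'   [simulate_pool_seq()].
#' @param path Output path.
#' @param design Optional `pool_design` fixing the sample column order;
#'   defaults to order of first appearance in `sync`.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path, design = NULL) {
  sample_order <- if (is.null(design)) unique(sync$sample_id) else design$sample_id
  field <- format_count_field(sync)
  idx <- match(sync$sample_id, sample_order)
  if (anyNA(idx)) {
    stop("sync contains sample_id values not present in the design",
         call. = FALSE)
  }
  site_key <- paste(sync$contig, sync$position, sep = "\r")
  sites <- !duplicated(site_key)
  site_ids <- site_key[sites]
  wide <- matrix(NA_character_, nrow = length(site_ids), ncol = length(sample_order))
  wide[cbind(match(site_key, site_ids), idx)] <- field
  if (anyNA(wide)) {
    stop("sync is missing count fields for some (site, sample) combinations",
         call. = FALSE)
  }
  lines <- paste(sync$contig[sites], sync$position[sites], sync$ref[sites],
                 apply(wide, 1, paste, collapse = "\t"), sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}
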