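# Intra-exon direct-repeat detection by mismatch-tolerant offset scan.
#
# For each offset d (>= min_len), positions i and i + d are compared and
# maximal windows with at most max_mismatch mismatches are extracted.
# Window length is capped at d so the two copies never overlap. A window is
# maximal when no one-base extension to the left or right stays in bounds,
# within the mismatch budget, and within the length cap. Windows at the
# same offset that are strictly contained in a longer reported window are
# suppressed; distinct offsets are reported independently.

# Maximal windows (0-based [start, end) over the comparison vector) with at
# most m mismatches and length at most cap, via a two-pointer sweep.
maximal_mismatch_windows <- function(mismatch, m, cap) {
  n <- length(mismatch)
  if (n == 0) return(tibble::tibble(start = integer(), end = integer(),
                                    mismatches = integer()))
  cum <- cumsum(c(0L, mismatch))
  mm <- function(l, r) cum[r + 1L] - cum[l + 1L]   # mismatches in [l, r)
  res_start <- integer(0); res_end <- integer(0); res_mm <- integer(0)
  r <- 0L
  for (l in 0:(n - 1L)) {
    if (r < l) r <- l
    while (r < n && mm(l, r + 1L) <= m && (r + 1L - l) <= cap) r <- r + 1L
    # window [l, r) is right-maximal for this l
    len <- r - l
    if (len == 0L) next
    # left-maximal: extending to l-1 must fail
    left_ok <- l > 0L && mm(l - 1L, r) <= m && (r - (l - 1L)) <= cap
    if (!left_ok) {
      res_start <- c(res_start, l); res_end <- c(res_end, r)
      res_mm <- c(res_mm, mm(l, r))
    }
  }
  tibble::tibble(start = res_start, end = res_end, mismatches = res_mm)
}

#' Find intra-sequence direct duplications
#'
#' Detects pairs of equal-length, non-overlapping intervals whose
#' substrings match up to a mismatch budget (Hamming distance; no gaps).
#' Pairs are maximal (no one-base extension of both intervals stays within
#' budget, bounds and non-overlap), deduplicated within each offset by
#' containment, and sorted by decreasing length, then by start.
#'
#' @param seq Nucleotide string of length >= `2 * min_len`
#'   (case-insensitive).
#' @param min_len Minimum duplication length in nt (default 20).
#' @param max_mismatch Maximum mismatches between the two copies
#'   (default 2).
#' @param seq_id Identifier carried into the output.
#' @return A tibble with one row per pair: `seq_id`, `a_start`, `a_end`,
#'   `b_start`, `b_end` (0-based half-open), `length`, `mismatches`,
#'   `sep_start`, `sep_end` (the separator interval between the copies,
#'   empty when tandem).
#' @examples
#' find_intraexon_duplications("ACGTACGT", min_len = 4, max_mismatch = 0)
#' @export
find_intraexon_duplications <- function(seq, min_len = 20L, max_mismatch = 2L,
                                        seq_id = "seq") {
  s <- normalize_seq(seq)
  n <- nchar(s)
  min_len <- as.integer(min_len)
  if (min_len < 2L) abort("min_len must be >= 2", class = "doubletscan_dup_error")
  if (n < 2L * min_len) {
    abort(sprintf("sequence length %d < 2 * min_len = %d", n, 2L * min_len),
          class = "doubletscan_dup_error")
  }
  ch <- seq_chars(s)
  out <- vector("list", 0L)
  for (d in min_len:(n - min_len)) {
    idx <- seq_len(n - d)
    mism <- as.integer(ch[idx] != ch[idx + d])
    win <- maximal_mismatch_windows(mism, max_mismatch, cap = d)
    win <- win[win$end - win$start >= min_len, , drop = FALSE]
    if (nrow(win) == 0) next
    # suppress windows strictly contained in a longer window at this offset
    keep <- rep(TRUE, nrow(win))
    for (i in seq_len(nrow(win))) {
      keep[i] <- !any(win$start <= win$start[i] & win$end >= win$end[i] &
                        (win$end - win$start) > (win$end[i] - win$start[i]))
    }
    win <- win[keep, , drop = FALSE]
    if (nrow(win) == 0) next
    out[[length(out) + 1L]] <- tibble::tibble(
      seq_id = seq_id,
      a_start = win$start, a_end = win$end,
      b_start = win$start + d, b_end = win$end + d,
      length = win$end - win$start,
      mismatches = win$mismatches
    )
  }
  if (length(out) == 0) {
    res <- tibble::tibble(seq_id = character(), a_start = integer(),
                          a_end = integer(), b_start = integer(),
                          b_end = integer(), length = integer(),
                          mismatches = integer())
  } else {
    res <- dplyr::bind_rows(out)
  }
  res$sep_start <- res$a_end
  res$sep_end <- res$b_start
  dplyr::arrange(res, dplyr::desc(.data$length), .data$a_start, .data$b_start)
}

#' Annotate the separator between a duplication pair
#'
#' Reports the interval strictly between the two copies, its length and its
#' purine fraction (NA for an empty separator).
#'
#' @param pair One row of [find_intraexon_duplications()] output (a
#'   one-row data frame or a list with `a_end` and `b_start`).
#' @param seq The sequence the pair was found in.
#' @return A one-row tibble: `sep_start`, `sep_end`, `sep_length`,
#'   `sep_purine_fraction`, `sep_seq`.
#' @export
annotate_separator <- function(pair, seq) {
  a_end <- pair$a_end[1]
  b_start <- pair$b_start[1]
  len <- b_start - a_end
  tibble::tibble(
    sep_start = a_end,
    sep_end = b_start,
    sep_length = len,
    sep_purine_fraction = if (len > 0) purine_fraction(seq, a_end, b_start) else NA_real_,
    sep_seq = if (len > 0) substr(normalize_seq(seq), a_end + 1L, b_start) else ""
  )
}
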