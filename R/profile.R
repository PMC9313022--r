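# Per-nucleotide ESE/ESSseq score profiles.
#
# Each position of a sequence is covered by up to six overlapping hexamers
# (those starting at offsets i-5 .. i that are in bounds). The profile score
# at a position is the arithmetic mean of the scores of all in-bounds,
# scorable hexamers covering it; the coverage count records how many
# contributed. Positions covered only by unscorable hexamers (ambiguity
# codes such as N) carry NA, never a silent zero.

#' Per-nucleotide ESE/ESSseq profile of a sequence
#'
#' @param seq A nucleotide string, length >= 6. Case-insensitive; `U` is
#'   read as `T`; bases outside \{A,C,G,T,U\} make the hexamers that contain
#'   them unscorable.
#' @param table A [hexamer_score_table()].
#' @param seq_id Identifier carried into the output.
#' @return A tibble of class `nucleotide_profile` with one row per position:
#'   `position` (0-based), `base`, `score` (NA where coverage is 0) and
#'   `coverage` (0--6). The input sequence is attached as attribute
#'   `sequence`.
#' @examples
#' tab <- generate_score_table(seed = 1)
#' per_nucleotide_profile("AGAAGAAGAAGA", tab)
#' @export
per_nucleotide_profile <- function(seq, table, seq_id = "seq") {
  stopifnot(inherits(table, "hexamer_score_table"))
  raw <- seq
  s <- normalize_seq(seq)
  n <- nchar(s)
  if (n < 6L) {
    abort("sequence shorter than 6 nt cannot be profiled",
          class = "doubletscan_profile_error")
  }
  lut <- score_lookup(table)
  starts <- seq_len(n - 5L)                       # 1-based hexamer starts
  hex <- substring(s, starts, starts + 5L)
  hs <- unname(lut[hex])                          # NA for unscorable
  num <- numeric(n)
  cov <- integer(n)
  ok <- !is.na(hs)
  hs0 <- ifelse(ok, hs, 0)
  for (k in 0:5) {
    idx <- starts + k
    num[idx] <- num[idx] + hs0
    cov[idx] <- cov[idx] + ok
  }
  score <- ifelse(cov > 0, num / pmax(cov, 1L), NA_real_)
  out <- tibble::tibble(
    seq_id = seq_id,
    position = 0:(n - 1L),
    base = seq_chars(raw),
    score = score,
    coverage = cov
  )
  attr(out, "sequence") <- raw
  class(out) <- c("nucleotide_profile", class(out))
  out
}

#' Profile an exon with optional flanking context
#'
#' Profiles the exon plus `flank` nucleotides of context on each side (taken
#' from the host sequence, clipped at its ends), so edge positions of the
#' exon see their true overlapping hexamers. Output positions are
#' exon-relative: negative positions are the 5' flank.
#'
#' @param seq Host sequence containing the exon.
#' @param exon_start,exon_end 0-based half-open exon interval in `seq`.
#' @param table A [hexamer_score_table()].
#' @param flank Nucleotides of context per side (default 0).
#' @inheritParams per_nucleotide_profile
#' @return A `nucleotide_profile` tibble with exon-relative `position` and a
#'   logical `in_exon` column.
#' @export
exon_profile <- function(seq, exon_start, exon_end, table, flank = 0,
                         seq_id = "exon") {
  n <- nchar(seq)
  check_interval(exon_start, exon_end, n, "exon")
  a <- max(0L, exon_start - flank)
  b <- min(n, exon_end + flank)
  sub <- substr(seq, a + 1L, b)
  prof <- per_nucleotide_profile(sub, table, seq_id = seq_id)
  prof$position <- prof$position + a - exon_start
  prof$in_exon <- prof$position >= 0 & prof$position < (exon_end - exon_start)
  prof
}

#' Mean profile score over an interval
#'
#' @param profile A `nucleotide_profile`.
#' @param start,end 0-based half-open interval in profile `position`
#'   coordinates.
#' @return A one-row tibble with `mean` (over non-missing scores) and `n`
#'   (contributing positions). Errors if the interval is empty or holds no
#'   covered position.
#' @export
region_mean <- function(profile, start, end) {
  pos <- profile$position
  if (start >= end || !any(pos >= start & pos < end)) {
    abort("empty interval for region_mean",
          class = "doubletscan_profile_error")
  }
  sel <- profile$score[pos >= start & pos < end]
  sel <- sel[!is.na(sel)]
  if (length(sel) == 0) {
    abort("interval has no covered positions",
          class = "doubletscan_profile_error")
  }
  tibble::tibble(mean = mean(sel), n = length(sel))
}

# Centered moving average with edge shrinkage: each position averages the
# non-missing values within the in-bounds half-window.
smooth_profile <- function(score, window) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(score)
  n <- length(score)
  half <- (window - 1L) %/% 2L
  v <- ifelse(is.na(score), 0, score)
  w <- as.integer(!is.na(score))
  cs_v <- cumsum(c(0, v))
  cs_w <- cumsum(c(0, w))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  num <- cs_v[hi + 1L] - cs_v[lo]
  den <- cs_w[hi + 1L] - cs_w[lo]
  ifelse(den > 0, num / den, NA_real_)
}

#' Call peaks in a profile relative to a baseline
#'
#' The profile is smoothed by a centered moving average of `smooth_window`
#' positions (1 = no smoothing), then split into maximal runs where the
#' smoothed value strictly exceeds `baseline`; each run contributes one
#' peak at its maximum (leftmost on ties).
#'
#' @param profile A `nucleotide_profile`.
#' @param baseline Baseline score, e.g. a control-exon mean; no default is
#'   assumed.
#' @param smooth_window Odd integer >= 1; default 7.
#' @return A tibble with one row per peak: `peak_position` (0-based),
#'   `value` (smoothed score at the peak), `start`, `end` (the exceedance
#'   run, half-open).
#' @export
find_peaks <- function(profile, baseline, smooth_window = 7L) {
  stopifnot(is.numeric(baseline), length(baseline) == 1L)
  n <- nrow(profile)
  if (smooth_window > n) {
    abort("smooth_window exceeds profile length",
          class = "doubletscan_profile_error")
  }
  sm <- smooth_profile(profile$score, as.integer(smooth_window))
  above <- !is.na(sm) & sm > baseline
  runs <- logical_runs(above)
  if (nrow(runs) == 0) {
    return(tibble::tibble(peak_position = integer(), value = double(),
                          start = integer(), end = integer()))
  }
  purrr::pmap_dfr(runs, function(start, end) {
    idx <- (start + 1L):end                 # 1-based rows of the run
    best <- idx[which.max(sm[idx])]
    tibble::tibble(
      peak_position = profile$position[best],
      value = sm[best],
      start = profile$position[start + 1L],
      end = profile$position[end] + 1L
    )
  })
}

#' Write a profile as tab-separated text
#'
#' Columns: seq_id, position (0-based), base, score, coverage.
#'
#' @param profile A `nucleotide_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(
    tibble::as_tibble(profile)[, c("seq_id", "position", "base", "score",
                                   "coverage")],
    path
  )
  invisible(path)
}
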