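# G-quadruplex propensity scoring and canonical motif matching.
#
# Two run-based scorers are implemented from their defining rules so the
# pipeline is self-contained:
#
#   * G4Hunter-style score: each base inside a maximal run of k consecutive
#     G contributes +min(k, 4), inside a run of k consecutive C contributes
#     -min(k, 4), all other bases 0; the score is the mean over positions.
#   * cGcC ratio: run-length-weighted consecutive-G content over
#     consecutive-C content. Each base in a run of k identical G (or C)
#     receives a weight that grows with k (default 10*k, so a run of length
#     k contributes 10*k^2); the weight table is data, passed as an
#     argument, so it can be corrected or swapped without touching code.
#     When the sequence has no C-run content the denominator is replaced by
#     a pseudocount of 1 and the score equals the cG value.
#
# The canonical G4 motif is four G-runs of length >= 3 separated by three
# loops of 1-7 arbitrary nucleotides.

# Per-base run-identity vector: maximal run length of the base at each
# position, for a given base letter.
run_lengths_of <- function(chars, base) {
  r <- rle(chars == base)
  rep(ifelse(r$values, r$lengths, 0L), r$lengths)
}

#' G4Hunter-style run score of a sequence
#'
#' @param seq Non-empty nucleotide string over \{A,C,G,T,U,N\}
#'   (case-insensitive). `N` scores 0 and breaks runs.
#' @return The mean per-base run score, a single double. Positive values
#'   indicate G-quadruplex propensity on the given strand.
#' @examples
#' g4hunter_score("GGGG")     # 4
#' g4hunter_score("GGGGCCCC") # 0
#' @export
g4hunter_score <- function(seq) {
  s <- normalize_seq(seq)
  if (nchar(s) == 0) {
    abort("empty sequence", class = "doubletscan_g4_error")
  }
  ch <- seq_chars(s)
  g <- pmin(run_lengths_of(ch, "G"), 4L)
  c_ <- pmin(run_lengths_of(ch, "C"), 4L)
  mean(g - c_)
}

#' Default cGcC run-weight table
#'
#' Per-base weight for a base sitting in a maximal run of `run_len`
#' identical nucleotides: `10 * run_len`. Runs longer than `max_len` extend
#' linearly by the same rule.
#'
#' @param max_len Largest tabulated run length.
#' @return A tibble with columns `run_len`, `weight_per_base`.
#' @export
cgcc_run_weights <- function(max_len = 20L) {
  tibble::tibble(run_len = seq_len(max_len),
                 weight_per_base = 10 * seq_len(max_len))
}

# Sum of run-weighted content for one base letter.
run_weighted_content <- function(chars, base, weights) {
  r <- rle(chars == base)
  lens <- r$lengths[r$values]
  if (length(lens) == 0) return(0)
  k_max <- max(weights$run_len)
  slope <- weights$weight_per_base[weights$run_len == k_max] / k_max
  per_base <- ifelse(lens <= k_max,
                     weights$weight_per_base[match(lens, weights$run_len)],
                     slope * lens)
  sum(per_base * lens)
}

#' cGcC score of a sequence
#'
#' Ratio of run-length-weighted consecutive-G content over consecutive-C
#' content; the denominator is replaced by the pseudocount 1 when the
#' sequence holds no C, so a C-free sequence scores exactly its cG value.
#'
#' @inheritParams g4hunter_score
#' @param weights Run-weight table, see [cgcc_run_weights()].
#' @return A single non-negative double.
#' @export
cgcc_score <- function(seq, weights = cgcc_run_weights()) {
  s <- normalize_seq(seq)
  if (nchar(s) == 0) {
    abort("empty sequence", class = "doubletscan_g4_error")
  }
  ch <- seq_chars(s)
  cg <- run_weighted_content(ch, "G", weights)
  cc <- run_weighted_content(ch, "C", weights)
  cg / max(cc, 1)
}

#' Canonical G4 motif matches
#'
#' Finds leftmost non-overlapping, shortest-first matches of the canonical
#' pattern: four G-runs of >= 3 separated by three loops of 1-7 arbitrary
#' nucleotides (`N` counts as arbitrary).
#'
#' @inheritParams g4hunter_score
#' @return A tibble of 0-based half-open intervals (`start`, `end`,
#'   `match`), possibly empty.
#' @examples
#' canonical_g4_scan("GGGAGGGAGGGAGGG")
#' @export
canonical_g4_scan <- function(seq) {
  s <- normalize_seq(seq)
  pat <- "G{3,}?(?:[ACGTN]{1,7}?G{3,}?){3}"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(start = integer(), end = integer(),
                          match = character()))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  tibble::tibble(start = start, end = end,
                 match = substring(s, start + 1L, end))
}

#' G4 scan configuration
#'
#' Window length and step follow the screening convention (60 nt windows,
#' 10 nt step); threshold calls are strict (`score > threshold`). The
#' neural-network score used by some screeners (threshold 0.5) is a trained
#' model, not a formula, and is not computed here.
#'
#' @param window_length Window size in nt (default 60).
#' @param window_step Step between window starts in nt (default 10).
#' @param cgcc_threshold Call threshold for the cGcC score (default 4.5).
#' @param g4h_threshold Call threshold for the G4Hunter score (default 0.9).
#' @return A list of class `g4_scan_config`.
#' @export
g4_scan_config <- function(window_length = 60L, window_step = 10L,
                           cgcc_threshold = 4.5, g4h_threshold = 0.9) {
  if (window_length < 1L || window_step < 1L || window_step > window_length ||
      !is.finite(cgcc_threshold) || !is.finite(g4h_threshold)) {
    abort("invalid G4 scan configuration", class = "doubletscan_g4_error")
  }
  structure(list(window_length = as.integer(window_length),
                 window_step = as.integer(window_step),
                 cgcc_threshold = cgcc_threshold,
                 g4h_threshold = g4h_threshold),
            class = "g4_scan_config")
}

# Window start positions (0-based) for a sequence of length n: multiples of
# step while a full window fits; if the tail is not flush, one extra
# full-length window anchored at n - window_length. A sequence shorter than
# the window yields a single whole-sequence window.
g4_window_starts <- function(n, config) {
  w <- config$window_length
  if (n <= w) return(0L)
  starts <- seq.int(0L, n - w, by = config$window_step)
  if ((n - w) %% config$window_step != 0L) starts <- c(starts, n - w)
  starts
}

#' Sliding-window G4 propensity scan
#'
#' Tiles the sequence with fixed-length windows, scores each with the
#' G4Hunter-style and cGcC scorers, applies the configured strict
#' thresholds, and attaches canonical G4 motif matches for the whole
#' sequence.
#'
#' @inheritParams g4hunter_score
#' @param config A [g4_scan_config()].
#' @param both_strands If `TRUE`, the reverse complement is scanned too and
#'   its windows appended with `strand == "-"` (coordinates on the given
#'   strand).
#' @param seq_id Identifier carried into the output.
#' @return A tibble of class `g4_scan` with one row per window: `seq_id`,
#'   `strand`, `start`, `end` (0-based half-open), `g4h`, `cgcc`,
#'   `g4h_call`, `cgcc_call`. Canonical matches are attached as the
#'   `canonical` attribute (a tibble), and the config as `config`.
#' @export
g4_scan <- function(seq, config = g4_scan_config(), both_strands = FALSE,
                    seq_id = "seq") {
  stopifnot(inherits(config, "g4_scan_config"))
  s <- normalize_seq(seq)
  n <- nchar(s)
  if (n == 0) abort("empty sequence", class = "doubletscan_g4_error")
  scan_one <- function(str, strand) {
    starts <- g4_window_starts(n, config)
    ends <- pmin(starts + config$window_length, n)
    win <- substring(str, starts + 1L, ends)
    tibble::tibble(
      seq_id = seq_id,
      strand = strand,
      start = starts,
      end = ends,
      g4h = vapply(win, g4hunter_score, 0, USE.NAMES = FALSE),
      cgcc = vapply(win, cgcc_score, 0, USE.NAMES = FALSE)
    )
  }
  out <- scan_one(s, "+")
  if (both_strands) out <- dplyr::bind_rows(out, scan_one(reverse_complement(s), "-"))
  out$g4h_call <- out$g4h > config$g4h_threshold
  out$cgcc_call <- out$cgcc > config$cgcc_threshold
  attr(out, "canonical") <- canonical_g4_scan(s)
  attr(out, "config") <- config
  class(out) <- c("g4_scan", class(out))
  out
}

#' Canonical motif matches attached to a scan
#'
#' @param scan A `g4_scan` result.
#' @return The tibble of canonical G4 motif intervals.
#' @export
canonical_matches <- function(scan) {
  attr(scan, "canonical")
}

#' Purine fraction of a sequence interval
#'
#' @inheritParams g4hunter_score
#' @param start,end 0-based half-open interval; defaults to the whole
#'   sequence.
#' @return (count A + count G) / interval length, in \[0, 1\].
#' @examples
#' purine_fraction("AGAGAG") # 1
#' purine_fraction("ACGT")   # 0.5
#' @export
purine_fraction <- function(seq, start = 0L, end = nchar(seq)) {
  s <- normalize_seq(seq)
  check_interval(start, end, nchar(s), "purine interval")
  ch <- seq_chars(substr(s, start + 1L, end))
  mean(ch %in% c("A", "G"))
}
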