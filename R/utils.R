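# Internal sequence helpers shared across modules.

#' @importFrom rlang abort .data :=
NULL

# Normalize a nucleotide string for scoring: uppercase, U -> T.
# Leaves ambiguity codes (N etc.) untouched so callers can flag them.
normalize_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("U", "T", toupper(seq))
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

#' Reverse complement of a DNA/RNA sequence
#'
#' Case-insensitive; `U` is treated as `T`. `N` maps to `N`. Returns an
#' uppercase DNA string.
#'
#' @param seq A single nucleotide string.
#' @return A single character string, the reverse complement.
#' @examples
#' reverse_complement("GGGA")
#' @export
reverse_complement <- function(seq) {
  s <- normalize_seq(seq)
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(seq_chars(comp)), collapse = "")
}

# Validate a 0-based half-open interval against a sequence length.
check_interval <- function(start, end, len, what = "interval") {
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1L ||
      length(end) != 1L || start < 0 || end > len || start >= end) {
    abort(sprintf(
      "%s [%s, %s) is invalid for a sequence of length %d",
      what, format(start), format(end), len
    ), class = "doubletscan_interval_error")
  }
  invisible(TRUE)
}

# Derive a child seed from a master seed, splitmix-style: a fixed odd
# multiplier plus index increment, folded into [0, 2^31). Deterministic and
# independent of R's RNG state.
derive_seed <- function(master, index) {
  stopifnot(length(master) == 1L, length(index) == 1L)
  x <- (as.double(master) %% 2147483647) + 1
  for (k in seq_len(2L)) {
    x <- (x * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  }
  as.integer(floor(x))
}

# Extract maximal runs of a logical vector as a tibble of 0-based
# half-open [start, end) intervals where the condition is TRUE.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & !is.na(r$values)
  tibble::tibble(start = starts[keep], end = ends[keep])
}
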