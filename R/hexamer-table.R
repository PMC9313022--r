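# Hexamer ESE/ESSseq score tables: construction, file I/O and lookup.
#
# A table maps each of the 4096 DNA hexamers to one real-valued ESE/ESSseq
# score (positive = enhancer-like, negative = silencer-like). The table is a
# tibble with columns `hexamer` and `score`, class "hexamer_score_table",
# carrying a `source_label` attribute for provenance.

#' All 4096 DNA hexamers
#'
#' @return A character vector of the 4^6 = 4096 hexamers over \{A,C,G,T\},
#'   in lexicographic order.
#' @export
all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(do.call(paste0, g))
}

#' Build a hexamer score table from vectors
#'
#' Validates completeness (exactly one score per hexamer over \{A,C,G,T\}^6)
#' and finiteness, and returns a `hexamer_score_table` tibble.
#'
#' @param hexamer Character vector of hexamers (case-insensitive; `U`
#'   accepted for `T`).
#' @param score Numeric vector of ESE/ESSseq scores, same length.
#' @param source_label Free-text provenance string.
#' @return A tibble with columns `hexamer`, `score` and class
#'   `hexamer_score_table`.
#' @export
hexamer_score_table <- function(hexamer, score, source_label = "unspecified") {
  if (length(hexamer) != length(score)) {
    abort("hexamer and score must have the same length")
  }
  key <- chartr("U", "T", toupper(hexamer))
  bad <- !grepl("^[ACGT]{6}$", key)
  if (any(bad)) {
    abort(sprintf(
      "invalid hexamer key(s): %s",
      paste(utils::head(hexamer[bad], 5), collapse = ", ")
    ), class = "doubletscan_table_error")
  }
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate hexamer: %s", dup[1]),
          class = "doubletscan_table_error")
  }
  missing <- setdiff(all_hexamers(), key)
  if (length(missing) > 0) {
    abort(sprintf(
      "missing %d hexamer%s (e.g. %s)",
      length(missing), if (length(missing) == 1) "" else "s", missing[1]
    ), class = "doubletscan_table_error")
  }
  if (!all(is.finite(score))) {
    abort("all scores must be finite", class = "doubletscan_table_error")
  }
  out <- tibble::tibble(hexamer = key, score = as.double(score))
  out <- dplyr::arrange(out, .data$hexamer)
  attr(out, "source_label") <- source_label
  class(out) <- c("hexamer_score_table", class(out))
  out
}

#' Read a hexamer score table from a tab-separated file
#'
#' The file has two columns, hexamer and score. A header line is
#' auto-detected (non-numeric second field on the first data line);
#' `#`-prefixed comment lines are ignored. The file must cover all 4096
#' hexamers exactly once.
#'
#' @param path Path to the tab-separated file.
#' @return A `hexamer_score_table`.
#' @export
read_score_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("score table file is empty", class = "doubletscan_table_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    abort(sprintf("line %d does not have two tab-separated fields",
                  which(nf != 2L)[1]),
          class = "doubletscan_table_error")
  }
  first_score <- suppressWarnings(as.numeric(fields[[1]][2]))
  has_header <- is.na(first_score)
  if (has_header) fields <- fields[-1]
  keys <- vapply(fields, `[[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  line_no <- seq_along(keys) + as.integer(has_header)
  bad_key <- !grepl("^[ACGTUacgtu]{6}$", keys)
  if (any(bad_key)) {
    abort(sprintf("line %d: key %s does not match [ACGTU]{6}",
                  line_no[bad_key][1], keys[bad_key][1]),
          class = "doubletscan_table_error")
  }
  if (any(is.na(vals))) {
    abort(sprintf("line %d: score is not numeric", line_no[is.na(vals)][1]),
          class = "doubletscan_table_error")
  }
  hexamer_score_table(keys, vals, source_label = path)
}

#' Write a hexamer score table as tab-separated text
#'
#' Round-trips exactly with [read_score_table()]: all 4096 (hexamer, score)
#' pairs, full precision.
#'
#' @param table A `hexamer_score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "hexamer_score_table"))
  lines <- paste(table$hexamer,
                 format(table$score, digits = 17, trim = TRUE,
                        scientific = FALSE),
                 sep = "\t")
  readr::write_lines(c("hexamer\tscore", lines), path)
  invisible(path)
}

# Internal: named numeric lookup vector for fast repeated queries.
score_lookup <- function(table) {
  stats::setNames(table$score, table$hexamer)
}

#' Look up the score of one hexamer
#'
#' Case-insensitive; `U` is read as `T`. A hexamer containing any symbol
#' outside \{A,C,G,T,U\} (e.g. `N`) is unscorable and raises a classed
#' error (`doubletscan_unscorable`) that profiling code catches.
#'
#' @param table A `hexamer_score_table`.
#' @param hexamer A length-6 nucleotide string.
#' @return The score, a single double.
#' @examples
#' tab <- generate_score_table(seed = 1)
#' score_of(tab, "AGAAGA")
#' @export
score_of <- function(table, hexamer) {
  stopifnot(inherits(table, "hexamer_score_table"))
  key <- chartr("U", "T", toupper(hexamer))
  if (nchar(key) != 6L || !grepl("^[ACGT]{6}$", key)) {
    abort(sprintf("unscorable hexamer: %s", hexamer),
          class = "doubletscan_unscorable")
  }
  unname(score_lookup(table)[key])
}

#' Hexamers attaining the maximum (or minimum) score
#'
#' Ties are all returned, so a unique optimum comes back as one row.
#'
#' @param table A `hexamer_score_table`.
#' @param which `"max"` or `"min"`.
#' @return A tibble with columns `hexamer`, `score` (one row per tied
#'   optimum).
#' @export
score_extremes <- function(table, which = c("max", "min")) {
  which <- match.arg(which)
  target <- if (which == "max") max(table$score) else min(table$score)
  dplyr::filter(tibble::as_tibble(table), .data$score == target)
}

#' @export
print.hexamer_score_table <- function(x, ...) {
  cat(sprintf("<hexamer_score_table> 4096 hexamers, source: %s\n",
              attr(x, "source_label")))
  cat(sprintf("  score range [%.4g, %.4g]\n", min(x$score), max(x$score)))
  NextMethod()
}
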