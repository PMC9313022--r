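# Readers and writers for the standard plain-text carriers: FASTA
# (case-preserving, since exon/intron is encoded as upper/lower case),
# BED (0-based half-open) and the tab-separated report tables.

#' Read sequences from a FASTA file
#'
#' Case is preserved (exonic sequence uppercase, intronic lowercase in
#' gene-model files).
#'
#' @param path FASTA file path.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                          seqonly = FALSE)
  if (length(x) == 0) {
    abort("no sequences in FASTA file", class = "doubletscan_io_error")
  }
  stats::setNames(vapply(x, function(s) as.character(s)[1], ""), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a BED file of 0-based half-open intervals
#'
#' Supports 3-6 columns (chrom, start, end, name, score, strand);
#' `track`/`browser`/comment lines are skipped.
#'
#' @param path BED file path.
#' @return A tibble with columns `chrom`, `start`, `end` and any of
#'   `name`, `score`, `strand` present in the file.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(fields))
  if (nf < 3L) abort("BED needs at least 3 columns",
                     class = "doubletscan_io_error")
  col <- function(i) vapply(fields, `[[`, "", i)
  out <- tibble::tibble(chrom = col(1),
                        start = as.integer(col(2)),
                        end = as.integer(col(3)))
  if (nf >= 4L) out$name <- col(4)
  if (nf >= 5L) out$score <- suppressWarnings(as.numeric(col(5)))
  if (nf >= 6L) out$strand <- col(6)
  if (any(is.na(out$start)) || any(is.na(out$end)) ||
      any(out$start < 0) || any(out$end <= out$start)) {
    abort("malformed BED interval", class = "doubletscan_io_error")
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  readr::write_tsv(intervals[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Write a gene model as FASTA + BED + manifest
#'
#' Three files: `<prefix>.fa` (exon uppercase, intron lowercase),
#' `<prefix>.bed` (all annotations) and `<prefix>.manifest.txt` (every
#' spec field and the seed, flat key=value).
#'
#' @param gene A `gene_model`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default `"gene"`).
#' @return The three paths, invisibly.
#' @export
write_gene_model <- function(gene, dir, prefix = "gene") {
  stopifnot(inherits(gene, "gene_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  bed <- file.path(dir, paste0(prefix, ".bed"))
  man <- file.path(dir, paste0(prefix, ".manifest.txt"))
  write_fasta(stats::setNames(gene$sequence, prefix), fa)
  write_bed(tibble::tibble(chrom = prefix,
                           start = gene$annotations$start,
                           end = gene$annotations$end,
                           name = gene$annotations$name), bed)
  spec <- gene$spec
  spec$pg4_offset <- if (is.null(spec$pg4_offset)) "centered" else spec$pg4_offset
  kv <- vapply(spec[setdiff(names(spec), "")], function(v) paste(v, collapse = ","), "")
  readr::write_lines(c(sprintf("attempt=%d", gene$attempt),
                       paste0(names(kv), "=", kv)), man)
  invisible(c(fasta = fa, bed = bed, manifest = man))
}

#' Write duplication pairs as tab-separated text
#'
#' @param dups Output of [find_intraexon_duplications()].
#' @param seq The sequence the pairs were found in (for separator purine
#'   fractions); optional.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dup_tsv <- function(dups, path, seq = NULL) {
  out <- tibble::as_tibble(dups)
  if (!is.null(seq) && nrow(out) > 0) {
    out$separator_purine_fraction <- vapply(seq_len(nrow(out)), function(i) {
      annotate_separator(out[i, ], seq)$sep_purine_fraction
    }, 0)
  } else {
    out$separator_purine_fraction <- NA_real_
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a G4 scan as tab-separated text
#'
#' @param scan A `g4_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_g4_tsv <- function(scan, path) {
  readr::write_tsv(tibble::as_tibble(scan), path)
  invisible(path)
}
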