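# Seeded generator of Olduvai-like exon-doublet gene models and matched
# synthetic hexamer score tables.
#
# The architecture emulated: a small first exon (52 nt) or its expanded
# version (109 nt) carrying a purine-rich insertion; the insertion holds a
# duplicated block (33 nt, a near-identical copy of a block in the
# ancestral exon), a short purine separator between the copies, and a
# pG4-like G-run-rich segment (68 nt) whose G-runs are capped below the
# canonical G4 requirement; then an intron, a larger second exon, and
# flanking intronic context. Exonic sequence is uppercase, intronic
# lowercase.
#
# Layout of the expanded first exon (lengths for the defaults):
#
#   [head 10][block A 33][separator 7][block A' 33][pad 17][tail 9]
#            |--------------- purine region 90 --------------|(-tail)
#                     |---------- insertion 57 ---------|
#
# Block A' is block A with a planted number of purine-purine mismatches.
# The pG4-like segment is a pg4_len window inside the purine region
# (centered by default; its offset is a parameter because the true overlap
# geometry between pG4, duplication and insertion is a free choice).
# The unexpanded exon is [head][block A][tail] (52 nt): the insertion is
# simply absent.
#
# Generation is deterministic for a given seed. After assembly the model is
# self-checked against its own invariants (exact insertion purine
# composition, planted mismatch count, exact duplication recovery, no
# canonical G4 in the pG4-like segment, at least one scan window over it
# exceeding the G4Hunter threshold); a violated check triggers regeneration
# from a derived attempt seed, with a bounded number of retries.

#' Specification of a synthetic exon-doublet gene
#'
#' Defaults encode the field's reference architecture: 52 nt first exon,
#' 109 nt expanded (57 nt insertion), 33 nt duplicated block, 68 nt
#' pG4-like segment.
#'
#' @param first_exon_len Unexpanded first-exon length (nt).
#' @param expanded Generate the expanded variant?
#' @param insertion_len Insertion length (nt); expanded first exon =
#'   `first_exon_len + insertion_len`.
#' @param dup_block_len Duplicated-block length (nt).
#' @param separator_len Purine separator between the copies (nt).
#' @param pg4_len pG4-like segment length (nt).
#' @param pg4_offset Offset of the pG4-like segment from the start of the
#'   purine region; `NULL` centers it inside the purine region (fully
#'   exonic). Larger offsets let it straddle the exon 3' boundary.
#' @param insertion_purine_fraction Target purine fraction of the
#'   insertion; met exactly up to composition rounding.
#' @param g_run_max Longest G-run allowed in the purine region (must stay
#'   below 3 for the canonical G4 pattern never to match).
#' @param dup_mismatches Planted Hamming distance between the two copies.
#' @param second_exon_len,intron_len,flank_len Remaining architecture
#'   lengths (nt).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `doublet_spec`.
#' @export
doublet_spec <- function(first_exon_len = 52L, expanded = TRUE,
                         insertion_len = 57L, dup_block_len = 33L,
                         separator_len = 7L, pg4_len = 68L,
                         pg4_offset = NULL,
                         insertion_purine_fraction = 0.95,
                         g_run_max = 2L, dup_mismatches = 1L,
                         second_exon_len = 150L, intron_len = 300L,
                         flank_len = 50L, seed = 1L) {
  spec <- list(
    first_exon_len = as.integer(first_exon_len), expanded = isTRUE(expanded),
    insertion_len = as.integer(insertion_len),
    dup_block_len = as.integer(dup_block_len),
    separator_len = as.integer(separator_len),
    pg4_len = as.integer(pg4_len),
    pg4_offset = if (is.null(pg4_offset)) NULL else as.integer(pg4_offset),
    insertion_purine_fraction = insertion_purine_fraction,
    g_run_max = as.integer(g_run_max),
    dup_mismatches = as.integer(dup_mismatches),
    second_exon_len = as.integer(second_exon_len),
    intron_len = as.integer(intron_len),
    flank_len = as.integer(flank_len),
    seed = as.integer(seed)
  )
  class(spec) <- "doublet_spec"
  validate_doublet_spec(spec)
  spec
}

validate_doublet_spec <- function(spec) {
  with(spec, {
    if (any(c(first_exon_len, insertion_len, dup_block_len, separator_len,
              pg4_len, second_exon_len, intron_len, flank_len) <= 0)) {
      abort("all architecture lengths must be positive",
            class = "doubletscan_spec_error")
    }
    if (insertion_purine_fraction < 0 || insertion_purine_fraction > 1) {
      abort("insertion_purine_fraction must lie in [0, 1]",
            class = "doubletscan_spec_error")
    }
    if (expanded) {
      if (g_run_max < 1) {
        abort(paste("unsatisfiable spec: g_run_max < 1 leaves no G runs,",
                    "so no window can exceed the G4Hunter threshold"),
              class = "doubletscan_spec_error")
      }
      if (g_run_max > 2) {
        abort(paste("unsatisfiable spec: g_run_max > 2 lets the canonical",
                    "G4 pattern match the pG4-like segment"),
              class = "doubletscan_spec_error")
      }
      if (insertion_len < separator_len + dup_block_len + 1L) {
        abort("insertion_len must exceed separator_len + dup_block_len",
              class = "doubletscan_spec_error")
      }
      if (first_exon_len < dup_block_len + 2L) {
        abort("first_exon_len must exceed dup_block_len + 2",
              class = "doubletscan_spec_error")
      }
      purine_len <- dup_block_len + insertion_len
      if (dup_mismatches < 0 || dup_mismatches > dup_block_len %/% 4L) {
        abort("dup_mismatches must be small relative to dup_block_len",
              class = "doubletscan_spec_error")
      }
      off <- if (is.null(pg4_offset)) max(0L, (purine_len - pg4_len) %/% 2L)
             else pg4_offset
      if (off < 0) abort("pg4_offset must be >= 0",
                         class = "doubletscan_spec_error")
    }
  })
  invisible(spec)
}

# Random uniform ACGT string.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Purine string rich in capped G-runs: token stream of G-run + A-spacer
# tokens, truncated to n; the last base is forced to A so concatenation
# never merges G-runs across segment boundaries.
rand_purine_segment <- function(n, g_run_max) {
  toks <- character(0)
  len <- 0L
  while (len < n) {
    k <- sample(seq_len(g_run_max), 1L,
                prob = seq_len(g_run_max)^2)   # favour the longest allowed run
    j <- sample(1:2, 1L, prob = c(0.8, 0.2))
    t <- paste0(strrep("G", k), strrep("A", j))
    toks <- c(toks, t)
    len <- len + nchar(t)
  }
  s <- substr(paste(toks, collapse = ""), 1L, n)
  ch <- seq_chars(s)
  ch[n] <- "A"
  ch
}

# Replace k interior purines by pyrimidines, breaking no structure.
plant_pyrimidines <- function(ch, k) {
  if (k <= 0L) return(ch)
  cand <- which(ch %in% c("A", "G"))
  cand <- cand[cand > 1L & cand < length(ch)]
  pick <- sort(sample(cand, k))
  ch[pick] <- sample(c("C", "T"), k, replace = TRUE)
  ch
}

assemble_doublet <- function(spec) {
  head_len <- max(1L, (spec$first_exon_len - spec$dup_block_len + 1L) %/% 2L)
  tail_len <- spec$first_exon_len - spec$dup_block_len - head_len
  head <- seq_chars(rand_dna(head_len))
  head[head_len] <- sample(c("C", "T"), 1L)     # break runs into block A
  tail <- seq_chars(rand_dna(max(tail_len, 0L)))

  if (!spec$expanded) {
    block_a <- rand_purine_segment(spec$dup_block_len, spec$g_run_max)
    exon1 <- c(head, block_a, tail)
    ann_extra <- NULL
  } else {
    pad_len <- spec$insertion_len - spec$separator_len - spec$dup_block_len
    # pyrimidine budget of the insertion, met exactly
    n_pyr <- spec$insertion_len -
      round(spec$insertion_purine_fraction * spec$insertion_len)
    block_a <- rand_purine_segment(spec$dup_block_len, spec$g_run_max)
    # pyrimidines shared by both copies live in block A (and its copy)
    n_pyr_pad <- min(1L, n_pyr)                 # the lone mid-pG4 cytosine
    block_a <- plant_pyrimidines(block_a, n_pyr - n_pyr_pad)
    # copy with planted purine<->purine mismatches (G->A preferred: never
    # lengthens a G-run)
    block_b <- block_a
    g_pos <- which(block_b == "G")
    g_pos <- g_pos[g_pos > 1L & g_pos < length(block_b)]
    if (length(g_pos) < spec$dup_mismatches) {
      abort("cannot place planted mismatches", class = "doubletscan_spec_error")
    }
    mm <- sample(g_pos, spec$dup_mismatches)
    block_b[mm] <- "A"
    sep <- rand_purine_segment(spec$separator_len, spec$g_run_max)
    sep[1L] <- "A"                              # boundary base, see below
    pad <- rand_purine_segment(pad_len, spec$g_run_max)
    pad[1L] <- "G"                              # must mismatch sep[1]
    if (n_pyr_pad > 0L && pad_len >= 3L) {
      pad[pad_len %/% 2L + 1L] <- "C"           # single cytosine mid-pG4
    }
    exon1 <- c(head, block_a, sep, block_b, pad, tail)
    a_start <- head_len                         # exon1-relative, 0-based
    ann_extra <- tibble::tibble(
      name = c("insertion", "dup_a", "dup_b", "separator", "purine_region"),
      start = c(a_start + spec$dup_block_len,
                a_start,
                a_start + spec$dup_block_len + spec$separator_len,
                a_start + spec$dup_block_len,
                a_start),
      end = c(a_start + spec$dup_block_len + spec$insertion_len,
              a_start + spec$dup_block_len,
              a_start + 2L * spec$dup_block_len + spec$separator_len,
              a_start + spec$dup_block_len + spec$separator_len,
              a_start + spec$dup_block_len + spec$insertion_len)
    )
    purine_len <- spec$dup_block_len + spec$insertion_len
    off <- if (is.null(spec$pg4_offset)) {
      max(0L, (purine_len - spec$pg4_len) %/% 2L)
    } else {
      spec$pg4_offset
    }
    ann_extra <- dplyr::bind_rows(
      ann_extra,
      tibble::tibble(name = "pg4", start = a_start + off,
                     end = a_start + off + spec$pg4_len)
    )
  }

  flank5 <- tolower(rand_dna(spec$flank_len))
  intron <- tolower(rand_dna(spec$intron_len))
  exon2 <- rand_dna(spec$second_exon_len)
  flank3 <- tolower(rand_dna(spec$flank_len))
  exon1_str <- paste(exon1, collapse = "")

  offs <- cumsum(c(0L, spec$flank_len, length(exon1), spec$intron_len,
                   spec$second_exon_len))
  ann <- tibble::tibble(
    name = c("flank5", "exon1", "intron", "exon2", "flank3"),
    start = c(offs[1], offs[2], offs[3], offs[4], offs[5]),
    end = c(offs[2], offs[3], offs[4], offs[5], offs[5] + spec$flank_len)
  )
  if (!is.null(ann_extra)) {
    ann_extra$start <- ann_extra$start + spec$flank_len
    ann_extra$end <- ann_extra$end + spec$flank_len
    ann <- dplyr::bind_rows(ann, ann_extra)
  }
  list(sequence = paste0(flank5, exon1_str, intron, exon2, flank3),
       annotations = ann)
}

# Invariant checks run at generation time; returns NULL or a reason string.
check_gene_model <- function(model, spec) {
  if (!spec$expanded) return(NULL)
  ann <- model$annotations
  iv <- function(nm) unlist(ann[ann$name == nm, c("start", "end")])
  seq <- model$sequence
  if (max(ann$end) > nchar(seq)) return("annotation out of bounds")
  ins <- iv("insertion")
  n_pur_target <- round(spec$insertion_purine_fraction *
                          spec$insertion_len) / spec$insertion_len
  if (abs(purine_fraction(seq, ins[1], ins[2]) - n_pur_target) > 1e-9) {
    return("insertion purine composition not exact")
  }
  a <- iv("dup_a"); b <- iv("dup_b")
  sa <- seq_chars(substr(toupper(seq), a[1] + 1L, a[2]))
  sb <- seq_chars(substr(toupper(seq), b[1] + 1L, b[2]))
  if (sum(sa != sb) != spec$dup_mismatches) return("planted mismatch count off")
  # exact duplication recovery at a budget equal to the planted distance
  dups <- find_intraexon_duplications(
    seq, min_len = min(20L, spec$dup_block_len),
    max_mismatch = spec$dup_mismatches
  )
  if (nrow(dups) == 0 ||
      dups$a_start[1] != a[1] || dups$a_end[1] != a[2] ||
      dups$b_start[1] != b[1] || dups$b_end[1] != b[2]) {
    return("planted duplication not recovered exactly")
  }
  pg4 <- iv("pg4")
  pg4_seq <- substr(toupper(seq), pg4[1] + 1L, min(pg4[2], nchar(seq)))
  if (is.null(spec$pg4_offset)) {
    if (nrow(canonical_g4_scan(pg4_seq)) != 0) {
      return("canonical G4 inside pG4-like segment")
    }
    scan <- g4_scan(seq)
    hit <- scan$start < pg4[2] & scan$end > pg4[1] & scan$g4h_call
    if (!any(hit)) return("no G4Hunter call over pG4-like segment")
  }
  NULL
}

#' Generate a synthetic exon-doublet gene model
#'
#' Deterministic for a given spec (including its seed); the global RNG
#' state is left untouched. Generation self-checks the model invariants
#' and regenerates from a derived attempt seed on violation (bounded
#' retries, then a hard error).
#'
#' @param spec A [doublet_spec()].
#' @param max_attempts Bound on regeneration attempts.
#' @return A list of class `gene_model`: `sequence` (exon uppercase, intron
#'   lowercase), `annotations` (tibble of named 0-based half-open
#'   intervals), `spec`, `seed`, `attempt`.
#' @examples
#' gene <- generate_doublet_gene(doublet_spec(seed = 7))
#' gene$annotations
#' @export
generate_doublet_gene <- function(spec, max_attempts = 50L) {
  stopifnot(inherits(spec, "doublet_spec"))
  validate_doublet_spec(spec)
  for (attempt in seq_len(max_attempts)) {
    model <- withr::with_seed(derive_seed(spec$seed, attempt),
                              assemble_doublet(spec))
    reason <- check_gene_model(model, spec)
    if (is.null(reason)) {
      out <- list(sequence = model$sequence, annotations = model$annotations,
                  spec = spec, seed = spec$seed, attempt = attempt)
      class(out) <- "gene_model"
      return(out)
    }
  }
  abort(sprintf("could not satisfy gene-model invariants in %d attempts (%s)",
                max_attempts, reason),
        class = "doubletscan_spec_error")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %d nt, %s first exon, seed %d\n",
              nchar(x$sequence),
              if (x$spec$expanded) "expanded" else "unexpanded", x$seed))
  print(x$annotations)
  invisible(x)
}

#' Interval of a named gene-model annotation
#'
#' @param gene A `gene_model`.
#' @param name Annotation name (e.g. `"exon1"`, `"insertion"`, `"pg4"`).
#' @return A length-2 integer vector `c(start, end)` (0-based half-open).
#' @export
gene_annotation <- function(gene, name) {
  row <- gene$annotations[gene$annotations$name == name, ]
  if (nrow(row) == 0) {
    abort(sprintf("no annotation named '%s'", name),
          class = "doubletscan_spec_error")
  }
  c(start = row$start[1], end = row$end[1])
}

#' Subsequence of a gene model by annotation name
#'
#' @inheritParams gene_annotation
#' @return The annotated subsequence (case preserved).
#' @export
gene_region_seq <- function(gene, name) {
  iv <- gene_annotation(gene, name)
  substr(gene$sequence, iv[1] + 1L, min(iv[2], nchar(gene$sequence)))
}

#' Default planted hexamer scores
#'
#' The strongest splicing hexamer AGAAGA at its reference value 1.034, and
#' every purine-only hexamer (the vocabulary of the generator's insertion
#' and separator) at a high enhancer-like score.
#'
#' @param purine_score Score for the \{A,G\}^6 hexamers (default 0.5).
#' @return A named numeric vector of planted scores.
#' @export
default_planted_scores <- function(purine_score = 0.5) {
  g <- expand.grid(rep(list(c("A", "G")), 6), stringsAsFactors = FALSE)
  pur <- do.call(paste0, g)
  planted <- stats::setNames(rep(purine_score, length(pur)), pur)
  planted["AGAAGA"] <- 1.034
  planted
}

#' Generate a synthetic hexamer score table
#'
#' Background scores are i.i.d. normal(0, `background_sd`) truncated to
#' \[-1, 1\]; planted hexamers override the background exactly. Planted
#' scores must stay within \[-1.05, 1.05\], the scale of real ESE/ESSseq
#' tables (whose printed maximum is 1.034).
#'
#' @param seed Integer seed.
#' @param planted Named numeric vector hexamer -> score
#'   (default [default_planted_scores()]).
#' @param background_sd Standard deviation of the background (default
#'   0.05).
#' @return A [hexamer_score_table()].
#' @export
generate_score_table <- function(seed, planted = default_planted_scores(),
                                 background_sd = 0.05) {
  if (length(planted) > 0) {
    if (is.null(names(planted)) || !all(grepl("^[ACGTU]{6}$", names(planted)))) {
      abort("planted names must be valid hexamers",
            class = "doubletscan_table_error")
    }
    if (any(abs(planted) > 1.05)) {
      abort("planted score outside [-1.05, 1.05]",
            class = "doubletscan_table_error")
    }
  }
  hex <- all_hexamers()
  scores <- withr::with_seed(derive_seed(seed, 0L), {
    s <- stats::rnorm(length(hex), 0, background_sd)
    pmin(pmax(s, -1), 1)
  })
  if (background_sd == 0) scores <- rep(0, length(hex))
  names(scores) <- hex
  if (length(planted) > 0) {
    keys <- chartr("U", "T", toupper(names(planted)))
    scores[keys] <- planted
  }
  hexamer_score_table(names(scores), unname(scores),
                      source_label = sprintf("synthetic (seed %d)", seed))
}

#' Generate a cohort of gene models
#'
#' Odd indices are expanded, even indices unexpanded, so the cohort is
#' half/half. Per-gene seeds derive from the master seed by a fixed
#' splitmix-style map, so any subset is independently reproducible.
#'
#' @param n_genes Even integer >= 2.
#' @param spec_template A [doublet_spec()] whose `expanded` and `seed`
#'   fields are overridden per gene.
#' @param seed Master seed.
#' @return A list of `gene_model` objects of length `n_genes`.
#' @export
generate_cohort <- function(n_genes, spec_template = doublet_spec(),
                            seed = 1L) {
  if (n_genes < 2L || n_genes %% 2L != 0L) {
    abort("n_genes must be even and >= 2", class = "doubletscan_spec_error")
  }
  purrr::map(seq_len(n_genes), function(i) {
    spec <- spec_template
    spec$expanded <- (i %% 2L == 1L)
    spec$seed <- derive_seed(seed, i)
    generate_doublet_gene(spec)
  })
}
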