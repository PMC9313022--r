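test_that("unexpanded and expanded first exons have the reference lengths", {
  u <- generate_doublet_gene(doublet_spec(expanded = FALSE, seed = 7))
  e1 <- gene_annotation(u, "exon1")
  expect_equal(unname(e1[2] - e1[1]), 52)
  expect_false("insertion" %in% u$annotations$name)

  x <- generate_doublet_gene(doublet_spec(expanded = TRUE, seed = 7))
  e1x <- gene_annotation(x, "exon1")
  expect_equal(unname(e1x[2] - e1x[1]), 109)
  a <- gene_annotation(x, "dup_a")
  b <- gene_annotation(x, "dup_b")
  expect_equal(unname(a[2] - a[1]), 33)
  expect_equal(unname(b[2] - b[1]), 33)
  ins <- gene_annotation(x, "insertion")
  expect_equal(unname(ins[2] - ins[1]), 57)
  pg4 <- gene_annotation(x, "pg4")
  expect_equal(unname(pg4[2] - pg4[1]), 68)
})

test_that("generation is deterministic and leaves the global RNG untouched", {
  rng_before <- withr::with_seed(1, runif(1))
  set.seed(1)
  g1 <- generate_doublet_gene(doublet_spec(seed = 7))
  after <- runif(1)
  expect_equal(after, rng_before)          # global stream unaffected

  g2 <- generate_doublet_gene(doublet_spec(seed = 7))
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$annotations, g2$annotations)

  g3 <- generate_doublet_gene(doublet_spec(seed = 8))
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("gene-model invariants hold: composition, mismatches, motif structure", {
  spec <- doublet_spec(seed = 13)
  gene <- generate_doublet_gene(spec)
  seqs <- gene$sequence
  ins <- gene_annotation(gene, "insertion")

  target <- round(spec$insertion_purine_fraction * spec$insertion_len) /
    spec$insertion_len
  expect_equal(purine_fraction(seqs, ins[1], ins[2]), target)
  expect_lte(abs(purine_fraction(seqs, ins[1], ins[2]) -
                   spec$insertion_purine_fraction), 1 / spec$insertion_len)

  a <- gene_annotation(gene, "dup_a"); b <- gene_annotation(gene, "dup_b")
  sa <- strsplit(toupper(substr(seqs, a[1] + 1, a[2])), "")[[1]]
  sb <- strsplit(toupper(substr(seqs, b[1] + 1, b[2])), "")[[1]]
  expect_equal(sum(sa != sb), spec$dup_mismatches)

  pg4_seq <- gene_region_seq(gene, "pg4")
  expect_equal(nrow(canonical_g4_scan(pg4_seq)), 0)
  expect_equal(max(rle(strsplit(toupper(pg4_seq), "")[[1]] == "G")$lengths[
    rle(strsplit(toupper(pg4_seq), "")[[1]] == "G")$values]),
    spec$g_run_max)

  pg4 <- gene_annotation(gene, "pg4")
  sc <- g4_scan(seqs)
  over <- sc$start < pg4[2] & sc$end > pg4[1]
  expect_true(any(sc$g4h_call[over]))
  expect_true(any(sc$cgcc_call[over]))

  # exon uppercase, intron lowercase
  expect_true(grepl("^[acgt]+$", gene_region_seq(gene, "intron")))
  expect_true(grepl("^[ACGT]+$", gene_region_seq(gene, "exon1")))
  expect_true(all(gene$annotations$end <= nchar(seqs)))
})

test_that("the pG4 segment can straddle the exon 3' boundary", {
  gene <- generate_doublet_gene(doublet_spec(seed = 3, pg4_offset = 60))
  pg4 <- gene_annotation(gene, "pg4")
  e1 <- gene_annotation(gene, "exon1")
  expect_lt(pg4[1], e1[2])
  expect_gt(pg4[2], e1[2])                 # extends into the intron
  expect_lte(pg4[2], nchar(gene$sequence))
})

test_that("unsatisfiable specs fail fast", {
  expect_error(doublet_spec(g_run_max = 0), "unsatisfiable",
               class = "doubletscan_spec_error")
  expect_error(doublet_spec(g_run_max = 5), class = "doubletscan_spec_error")
  expect_error(doublet_spec(insertion_len = 30), class = "doubletscan_spec_error")
  expect_error(doublet_spec(first_exon_len = 30), class = "doubletscan_spec_error")
  expect_error(doublet_spec(intron_len = 0), class = "doubletscan_spec_error")
  expect_error(doublet_spec(insertion_purine_fraction = 1.2),
               class = "doubletscan_spec_error")
})

test_that("synthetic score tables plant scores exactly and are reproducible", {
  tab <- generate_score_table(seed = 4, planted = c(AGAAGA = 1.034))
  expect_equal(score_of(tab, "AGAAGA"), 1.034)
  expect_equal(score_extremes(tab, "max")$hexamer, "AGAAGA")

  tab2 <- generate_score_table(seed = 4, planted = c(AGAAGA = 1.034))
  expect_identical(tab$score, tab2$score)

  flat <- generate_score_table(seed = 4, planted = numeric(0),
                               background_sd = 0)
  expect_true(all(flat$score == 0))

  expect_error(generate_score_table(seed = 1, planted = c(AGAAGA = 1.2)),
               class = "doubletscan_table_error")
  expect_error(generate_score_table(seed = 1, planted = c(BADHEX = 0.5)),
               class = "doubletscan_table_error")

  # default planting: the purine vocabulary scores high, background near 0
  def <- generate_score_table(seed = 4)
  expect_equal(score_of(def, "GGAGGA"), 0.5)
  expect_lt(abs(score_of(def, "ACGTAC")), 1)
})

test_that("cohorts alternate variants and are reproducible by subsets", {
  co <- generate_cohort(6, seed = 2)
  expect_length(co, 6)
  expect_equal(vapply(co, function(g) g$spec$expanded, TRUE),
               rep(c(TRUE, FALSE), 3))
  co2 <- generate_cohort(6, seed = 2)
  expect_identical(vapply(co, function(g) g$sequence, ""),
                   vapply(co2, function(g) g$sequence, ""))
  # regenerating gene 3 alone reproduces it
  spec3 <- co[[3]]$spec
  expect_identical(generate_doublet_gene(spec3)$sequence, co[[3]]$sequence)

  expect_error(generate_cohort(3), class = "doubletscan_spec_error")
  expect_error(generate_cohort(0), class = "doubletscan_spec_error")
})

test_that("expanded cohort genes carry higher insertion-region scores on average", {
  tab <- generate_score_table(seed = 3)
  co <- generate_cohort(6, seed = 3)
  expanded <- co[vapply(co, function(g) g$spec$expanded, TRUE)]
  ins_means <- vapply(expanded, function(g) {
    p <- per_nucleotide_profile(g$sequence, tab)
    ins <- gene_annotation(g, "insertion")
    region_mean(p, ins[1], ins[2])$mean
  }, 0)
  whole_means <- vapply(expanded, function(g) {
    p <- per_nucleotide_profile(g$sequence, tab)
    region_mean(p, 0, nchar(g$sequence))$mean
  }, 0)
  expect_gt(mean(ins_means), mean(whole_means))
})

test_that("gene models round-trip through FASTA + BED + manifest", {
  dir <- withr::local_tempdir()
  gene <- generate_doublet_gene(doublet_spec(seed = 12))
  paths <- write_gene_model(gene, dir, prefix = "toy")
  expect_true(all(file.exists(paths)))

  fa <- read_fasta(paths["fasta"])
  expect_identical(unname(fa[1]), gene$sequence)    # case preserved

  bed <- read_bed(paths["bed"])
  expect_equal(bed$start, gene$annotations$start)
  expect_equal(bed$end, gene$annotations$end)
  expect_equal(bed$name, gene$annotations$name)

  man <- readLines(paths["manifest"])
  expect_true(any(grepl("^seed=12$", man)))
  expect_true(any(grepl("^first_exon_len=52$", man)))
})
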