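test_that("G4Hunter run scoring follows the per-base rule", {
  expect_equal(g4hunter_score("GGGG"), 4)
  expect_equal(g4hunter_score("GGGGCCCC"), 0)
  expect_equal(g4hunter_score("GGAT"), 1)
  expect_equal(g4hunter_score("G"), 1)
  expect_equal(g4hunter_score("GGGGG"), 4)          # cap at 4
  expect_equal(g4hunter_score("NGGN"), 1)           # N scores 0, breaks runs
  expect_equal(g4hunter_score("ggat"), 1)           # case-insensitive
  expect_error(g4hunter_score(""), class = "doubletscan_g4_error")
})

test_that("G4Hunter is antisymmetric under reverse complement", {
  withr::with_seed(101, {
    for (i in 1:100) {
      s <- random_dna(sample(10:80, 1))
      expect_equal(g4hunter_score(reverse_complement(s)),
                   -g4hunter_score(s))
    }
  })
})

test_that("extending a G-run never decreases the G4Hunter score", {
  withr::with_seed(55, {
    for (i in 1:50) {
      s <- random_dna(40)
      g_pos <- gregexpr("G", s, fixed = TRUE)[[1]]
      if (g_pos[1] == -1) next
      j <- sample(length(g_pos), 1)
      extended <- paste0(substr(s, 1, g_pos[j]), "G",
                         substr(s, g_pos[j] + 1, nchar(s)))
      expect_gte(g4hunter_score(extended), g4hunter_score(s))
    }
  })
})

test_that("cGcC accumulates run-length weights and uses the pseudocount", {
  expect_equal(cgcc_score("AAAAAAAA"), 0)
  # C-free: denominator pseudocount, score equals cG exactly
  expect_equal(cgcc_score("GGG"), 90)               # one run of 3: 3 * 30
  expect_equal(cgcc_score("GAGGA"), 10 + 40)        # runs of 1 and 2
  withr::with_seed(77, {
    for (i in 1:50) {
      s <- gsub("C", "A", random_dna(40))
      r <- rle(strsplit(s, "")[[1]] == "G")
      cg <- sum((10 * r$lengths[r$values]) * r$lengths[r$values])
      expect_equal(cgcc_score(s), cg)
    }
  })
  # hand-enumerated fixture for a fixed 60-nt sequence:
  # G-runs: 3,2,3,1,2 -> cG = 90+40+90+10+40 = 270
  # C-runs: 2,1,1     -> cC = 40+10+10 = 60 -> ratio 4.5
  fx <- paste0("GGGTAAGGTAAGGGTAAGTAAGGTCCTACTACT",
               "AATTAATTAATTAATTAATTAATTAAT")
  expect_equal(nchar(fx), 60)
  expect_equal(cgcc_score(fx), 270 / 60)
  expect_error(cgcc_score(""), class = "doubletscan_g4_error")
})

test_that("cGcC run-weight table is swappable data", {
  w <- cgcc_run_weights(4)
  expect_equal(w$weight_per_base, c(10, 20, 30, 40))
  flat <- tibble::tibble(run_len = 1:4, weight_per_base = rep(1, 4))
  # flat per-base weights make cG the plain G count
  expect_equal(cgcc_score("GGGAG", weights = flat), 4)
  # runs beyond the table extend by the last tabulated per-base slope
  expect_equal(cgcc_score(strrep("G", 6), weights = cgcc_run_weights(4)),
               10 * 36)
})

test_that("canonical G4 matching finds four capped-loop G-runs", {
  m <- canonical_g4_scan("GGGAGGGAGGGAGGG")
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 15))

  expect_equal(nrow(canonical_g4_scan("GGAGGAGGAGG")), 0)
  expect_equal(nrow(canonical_g4_scan("GGGAGGGAGGGAAAAAAAAGGG")), 0) # loop > 7

  # N counts as an arbitrary loop nucleotide
  expect_equal(nrow(canonical_g4_scan("GGGNGGGNGGGNGGG")), 1)

  # two well-separated motifs are both reported, non-overlapping
  two <- canonical_g4_scan(paste0("GGGAGGGAGGGAGGG", strrep("T", 20),
                                  "GGGTGGGTGGGTGGG"))
  expect_equal(nrow(two), 2)
  expect_true(two$start[2] >= two$end[1])
})

test_that("a perfect G-run window always contains a canonical match", {
  withr::with_seed(31, {
    for (i in 1:20) {
      runs <- replicate(4, strrep("G", sample(3:5, 1)))
      loops <- replicate(3, random_dna(sample(1:7, 1)))
      s <- paste0(runs[1], loops[1], runs[2], loops[2], runs[3], loops[3],
                  runs[4])
      expect_gte(nrow(canonical_g4_scan(s)), 1)
    }
  })
})

test_that("windows tile the sequence with a truncation-free tail rule", {
  cfg <- g4_scan_config()
  s100 <- withr::with_seed(4, random_dna(100))
  sc <- g4_scan(s100, cfg)
  expect_equal(sc$start, c(0, 10, 20, 30, 40))
  expect_equal(sc$end, c(60, 70, 80, 90, 100))

  # flush at 60: exactly one window
  sc60 <- g4_scan(withr::with_seed(5, random_dna(60)), cfg)
  expect_equal(nrow(sc60), 1)
  expect_equal(c(sc60$start, sc60$end), c(0, 60))

  # non-flush tail: one extra full-length window anchored at L - W
  sc95 <- g4_scan(withr::with_seed(6, random_dna(95)), cfg)
  expect_equal(sc95$start, c(0, 10, 20, 30, 35))
  expect_equal(sc95$end, c(60, 70, 80, 90, 95))

  # shorter than the window: single whole-sequence window
  sc30 <- g4_scan(withr::with_seed(7, random_dna(30)), cfg)
  expect_equal(nrow(sc30), 1)
  expect_equal(c(sc30$start, sc30$end), c(0, 30))
})

test_that("scan calls are strict threshold exceedances", {
  sA <- strrep("A", 200)
  sc <- g4_scan(sA)
  expect_true(all(sc$g4h == 0))
  expect_true(all(sc$cgcc == 0))
  expect_false(any(sc$g4h_call))
  expect_false(any(sc$cgcc_call))

  # exactly at threshold: not a call (strict inequality)
  cfg <- g4_scan_config(window_length = 10, window_step = 10,
                        g4h_threshold = 1.0)
  sc2 <- g4_scan("GGAAAAAATT", cfg)        # score (2+2)/10 = 0.4
  expect_false(sc2$g4h_call[1])
  cfg2 <- g4_scan_config(window_length = 4, window_step = 4,
                         g4h_threshold = 4.0)
  expect_false(g4_scan("GGGG", cfg2)$g4h_call[1])  # 4.0 > 4.0 is FALSE
})

test_that("both-strand scans append minus-strand windows", {
  s <- withr::with_seed(8, random_dna(100))
  one <- g4_scan(s)
  both <- g4_scan(s, both_strands = TRUE)
  expect_equal(nrow(both), 2 * nrow(one))
  minus <- both[both$strand == "-", ]
  expect_equal(minus$g4h[1], g4hunter_score(substr(reverse_complement(s), 1, 60)))
})

test_that("purine fraction counts A and G over the interval", {
  expect_equal(purine_fraction("AGAGAG"), 1)
  expect_equal(purine_fraction("ACGT"), 0.5)
  expect_equal(purine_fraction("ACGTAC", 0, 2), 0.5)
  expect_error(purine_fraction("ACGT", 2, 2),
               class = "doubletscan_interval_error")
})

test_that("invalid scan configurations are rejected", {
  expect_error(g4_scan_config(window_step = 0), class = "doubletscan_g4_error")
  expect_error(g4_scan_config(window_length = 10, window_step = 20),
               class = "doubletscan_g4_error")
})
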