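# Independent brute-force oracles. These deliberately share no code with
# the package implementation: they enumerate definitions directly.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Overlap-average oracle: enumerate every hexamer start j, add its score to
# positions j..j+5, divide by per-position counts. Unscorable hexamers
# (non-ACGT) contribute nothing.
oracle_profile <- function(seq, table) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  lut <- setNames(table$score, table$hexamer)
  num <- numeric(n)
  cnt <- integer(n)
  for (j in seq_len(n - 5L)) {
    h <- substr(s, j, j + 5L)
    if (!grepl("^[ACGT]{6}$", h)) next
    v <- unname(lut[h])
    idx <- j:(j + 5L)
    num[idx] <- num[idx] + v
    cnt[idx] <- cnt[idx] + 1L
  }
  list(score = ifelse(cnt > 0, num / pmax(cnt, 1), NA_real_), coverage = cnt)
}

# Duplication-pair oracle: test every (a_start, offset, length) triplet
# against the maximality definition directly.
oracle_dup_pairs <- function(seq, min_len, max_mismatch) {
  s <- toupper(seq)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  mm <- function(a, d, len) sum(ch[a:(a + len - 1L)] != ch[(a + d):(a + d + len - 1L)])
  valid <- function(a, d, len) {
    a >= 1L && len >= 1L && len <= d && (a + d + len - 1L) <= n &&
      mm(a, d, len) <= max_mismatch
  }
  rows <- list()
  for (d in seq_len(n - 1L)) {
    for (a in seq_len(n - d)) {
      len_max <- min(d, n - d - a + 1L)
      if (len_max < min_len) next
      for (len in min_len:len_max) {
        if (!valid(a, d, len)) next
        # maximal: neither one-base extension is valid
        if (valid(a - 1L, d, len + 1L)) next
        if (valid(a, d, len + 1L)) next
        rows[[length(rows) + 1L]] <-
          data.frame(a_start = a - 1L, a_end = a + len - 1L,
                     b_start = a + d - 1L, b_end = a + d + len - 1L,
                     length = len, mismatches = mm(a, d, len))
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      length = integer(), mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  # containment suppression within the same offset
  off <- out$b_start - out$a_start
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(off == off[i] & out$a_start <= out$a_start[i] &
           out$a_end >= out$a_end[i] & out$length > out$length[i])
  }, TRUE)
  out <- unique(out[keep, ])
  out[order(-out$length, out$a_start, out$b_start), , drop = FALSE]
}

# Two-sided p-value of the t statistic by numerical integration of the t
# density written from the gamma-function formula.
oracle_t_p <- function(t, df) {
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * integrate(dens, abs(t), Inf, rel.tol = 1e-10)$value
}

# A small deterministic synthetic score table shared across tests.
test_table <- function(seed = 11) generate_score_table(seed = seed)
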