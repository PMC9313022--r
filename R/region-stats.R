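# Region-versus-background two-sample statistics on profile scores.
#
# The per-nucleotide scores of a region are compared with a background set
# by an unpaired t-test. The test treats positions as independent
# observations, which overlapping hexamers make optimistic; a block
# permutation test (block = hexamer span, 6 nt) is provided as the
# conservative alternative.

#' Unpaired two-sample t-test
#'
#' Pooled-variance Student (default) or Welch variant. The two-sided
#' p-value is computed through the regularized incomplete beta function:
#' `p = I_{df/(df + t^2)}(df/2, 1/2)`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return An object of class `ese_ttest`: a list with `mean_x`, `mean_y`,
#'   `n_x`, `n_y`, `t`, `df`, `p`, `variant`. `t > 0` means `mean(x) >
#'   mean(y)`.
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
unpaired_t_test <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- as.double(x); y <- as.double(y)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) {
    abort("both samples need at least 2 observations",
          class = "doubletscan_stats_error")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    abort("degenerate samples: both variances are zero",
          class = "doubletscan_stats_error")
  }
  mx <- mean(x); my <- mean(y)
  if (variant == "pooled") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  p <- stats::pbeta(df / (df + t^2), df / 2, 1 / 2)
  structure(list(mean_x = mx, mean_y = my, n_x = nx, n_y = ny,
                 t = t, df = df, p = p, variant = variant),
            class = "ese_ttest")
}

#' @export
print.ese_ttest <- function(x, ...) {
  cat(sprintf("Unpaired t-test (%s)\n", x$variant))
  cat(sprintf("  means: %.2f vs. %.2f  (n = %d, %d)\n",
              x$mean_x, x$mean_y, x$n_x, x$n_y))
  cat(sprintf("  t = %.4g, df = %.4g, two-sided p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an unpaired t-test result
#'
#' @param x An `ese_ttest` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate` (difference of means),
#'   `mean_x`, `mean_y`, `statistic`, `df`, `p.value`, `method`.
#' @export
tidy.ese_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_x - x$mean_y,
    mean_x = x$mean_x, mean_y = x$mean_y,
    n_x = x$n_x, n_y = x$n_y,
    statistic = x$t, df = x$df, p.value = x$p,
    method = paste0("unpaired t-test (", x$variant, ")")
  )
}

#' @rdname tidy.ese_ttest
#' @export
glance.ese_ttest <- function(x, ...) tidy(x, ...)

# Collect non-missing scores at the union of 0-based half-open intervals.
region_scores <- function(profile, intervals) {
  pos <- profile$position
  sel <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    sel <- sel | (pos >= intervals$start[i] & pos < intervals$end[i])
  }
  s <- profile$score[sel]
  s[!is.na(s)]
}

#' Compare a region's profile scores against a background
#'
#' Scores at the region positions are tested against either every position
#' of the profile (`background = "whole"`, the transcript-average reading)
#' or every position outside the region (`"complement"`).
#'
#' @param profile A `nucleotide_profile`.
#' @param region A data frame of 0-based half-open intervals with columns
#'   `start`, `end` (one or more rows; their union is the region).
#' @param background `"whole"` or `"complement"`.
#' @inheritParams unpaired_t_test
#' @return An `ese_ttest` whose `mean_x`/`mean_y` are the region and
#'   background means.
#' @export
compare_region_to_background <- function(profile, region,
                                         background = c("whole", "complement"),
                                         variant = c("pooled", "welch")) {
  background <- match.arg(background)
  if (is.numeric(region) && length(region) == 2) {
    region <- tibble::tibble(start = region[1], end = region[2])
  }
  x <- region_scores(profile, region)
  y <- if (background == "whole") {
    profile$score[!is.na(profile$score)]
  } else {
    pos <- profile$position
    inside <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(region))) {
      inside <- inside | (pos >= region$start[i] & pos < region$end[i])
    }
    s <- profile$score[!inside]
    s[!is.na(s)]
  }
  if (length(x) == 0 || length(y) == 0) {
    abort("region or background holds no covered positions",
          class = "doubletscan_stats_error")
  }
  unpaired_t_test(x, y, variant = variant)
}

#' Block permutation test for a region mean
#'
#' Conservative alternative to the t-test: the profile score vector is cut
#' into consecutive blocks (default 6 nt, the hexamer span, so the
#' within-block autocorrelation induced by overlapping hexamers is kept
#' intact), the blocks are permuted, and the region mean is recomputed.
#' The two-sided p-value is the fraction of permutations whose region mean
#' deviates from the overall mean at least as much as the observed one
#' (with the +1 correction).
#'
#' @inheritParams compare_region_to_background
#' @param block Block length in nt (default 6).
#' @param n_perm Number of permutations (default 2000).
#' @return A one-row tibble: `mean_region`, `mean_overall`, `p`, `n_perm`,
#'   `block`.
#' @export
block_permutation_test <- function(profile, region, block = 6L,
                                   n_perm = 2000L) {
  if (is.numeric(region) && length(region) == 2) {
    region <- tibble::tibble(start = region[1], end = region[2])
  }
  scores <- profile$score
  pos <- profile$position
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(region))) {
    inside <- inside | (pos >= region$start[i] & pos < region$end[i])
  }
  obs <- mean(scores[inside], na.rm = TRUE)
  overall <- mean(scores, na.rm = TRUE)
  blocks <- split(seq_along(scores), (seq_along(scores) - 1L) %/% block)
  n_region <- sum(inside)
  stat <- abs(obs - overall)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
    perm_mean <- mean(scores[perm][seq_len(n_region)], na.rm = TRUE)
    if (abs(perm_mean - overall) >= stat) exceed <- exceed + 1L
  }
  tibble::tibble(mean_region = obs, mean_overall = overall,
                 p = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, block = block)
}
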