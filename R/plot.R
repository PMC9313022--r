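# ggplot2 displays of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-nucleotide profile
#'
#' The score track with an optional baseline and called peaks.
#'
#' @param object A `nucleotide_profile`.
#' @param baseline Optional baseline to draw (and to call peaks against
#'   when `peaks = TRUE`).
#' @param peaks Mark peaks called at `baseline`?
#' @param smooth_window Passed to [find_peaks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nucleotide_profile <- function(object, baseline = NULL,
                                        peaks = FALSE, smooth_window = 7L,
                                        ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "position (nt)", y = "ESE/ESSseq score") +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline, linetype = "dashed")
    if (peaks) {
      pk <- find_peaks(object, baseline, smooth_window = smooth_window)
      if (nrow(pk) > 0) {
        p <- p + ggplot2::geom_point(
          data = pk,
          ggplot2::aes(x = .data$peak_position, y = .data$value),
          colour = "red", inherit.aes = FALSE
        )
      }
    }
  }
  p
}

#' Plot a G4 scan
#'
#' Window scores for both scorers with their thresholds; canonical motif
#' matches as rug marks.
#'
#' @param object A `g4_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.g4_scan <- function(object, ...) {
  cfg <- attr(object, "config")
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2) |>
    tidyr::pivot_longer(c("g4h", "cgcc"), names_to = "scorer",
                        values_to = "value")
  thr <- tibble::tibble(scorer = c("g4h", "cgcc"),
                        threshold = c(cfg$g4h_threshold, cfg$cgcc_threshold))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~scorer, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "window midpoint (nt)", y = "score") +
    ggplot2::theme_minimal()
  canon <- canonical_matches(object)
  if (!is.null(canon) && nrow(canon) > 0) {
    p <- p + ggplot2::geom_rug(
      data = dplyr::mutate(canon, mid = (.data$start + .data$end) / 2),
      ggplot2::aes(x = .data$mid), inherit.aes = FALSE, sides = "b"
    )
  }
  p
}

#' Plot a gene model's architecture
#'
#' Annotation intervals as stacked segments.
#'
#' @param object A `gene_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_model <- function(object, ...) {
  ann <- dplyr::mutate(object$annotations,
                       name = factor(.data$name, levels = rev(.data$name)))
  ggplot2::ggplot(ann, ggplot2::aes(y = .data$name)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$name),
                          linewidth = 3) +
    ggplot2::labs(x = "position (nt)", y = NULL) +
    ggplot2::theme_minimal()
}
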