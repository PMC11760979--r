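# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an average signal pileup
#'
#' @param object A `pileup_profile`.
#' @param ... Unused.
#' @return A ggplot: mean normalized coverage against distance from the
#'   locus center.
#' @export
autoplot.pileup_profile <- function(object, ...) {
  bin_size <- attr(object, "bin_size")
  df <- dplyr::mutate(tibble::as_tibble(object),
    mid = .data$offset + bin_size / 2
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "distance from locus center (bp)",
      y = "mean normalized coverage",
      title = sprintf("Pileup over %d loci", attr(object, "n_loci"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the moving-average co-binding profile
#'
#' @param object An `ma_profile`.
#' @param ... Unused.
#' @return A ggplot of smoothed co-binding density along the expression
#'   ranking (upregulated genes on the left).
#' @export
autoplot.ma_profile <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$rank, y = .data$smoothed)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "genes ranked by log2 fold change (up -> down)",
      y = sprintf(
        "co-binding density (window %d genes)", attr(object, "window_genes")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot dynamics class counts
#'
#' @param object A `dynamics` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of class counts, per condition when a
#'   condition column is present.
#' @export
autoplot.dynamics <- function(object, ...) {
  counts <- summarize_dynamics(object)
  p <- ggplot2::ggplot(counts, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "dynamics class", y = "loci") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(counts)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  }
  p
}

#' Plot a per-class condition comparison
#'
#' @param object A `class_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot showing, for each class, the loci unique to each
#'   condition and shared between them.
#' @export
autoplot.class_comparison <- function(object, ...) {
  long <- tibble::as_tibble(object) %>%
    dplyr::select("label", "unique_a", "shared", "unique_b") %>%
    tidyr::pivot_longer(-"label", names_to = "set", values_to = "n") %>%
    dplyr::mutate(set = factor(.data$set, c("unique_a", "shared", "unique_b")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$n, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "dynamics class", y = "loci", fill = NULL) +
    ggplot2::theme_minimal()
}
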