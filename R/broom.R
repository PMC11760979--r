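# broom-style verbs for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname overlap_binding
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble::as_tibble(x$shared)
}

#' @rdname overlap_binding
#' @export
glance.overlap_result <- function(x, ...) {
  tibble::tibble(
    n_a = x$n_a, n_b = x$n_b, n_overlap = x$n_overlap,
    fraction = x$fraction, min_overlap = x$min_overlap
  )
}

#' One-row summary of an open/closed call matrix
#'
#' @param x An `open_matrix` from [call_open()].
#' @param ... Unused.
#' @return Tibble with the locus and library counts, the threshold, and
#'   the overall open fraction.
#' @export
glance.open_matrix <- function(x, ...) {
  tibble::tibble(
    n_loci = dplyr::n_distinct(x$locus_id),
    n_libraries = dplyr::n_distinct(x$library_id),
    theta = attr(x, "theta"),
    open_fraction = mean(x$open)
  )
}

#' One-row summary of a dynamics classification
#'
#' @param x A `dynamics` tibble from [classify_dynamics()].
#' @param ... Unused.
#' @export
glance.dynamics <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_conditions = if ("condition" %in% names(x)) {
      dplyr::n_distinct(x$condition)
    } else 1L,
    fc_threshold = attr(x, "fc_threshold"),
    n_complex = sum(x$label == "COMPLEX"),
    n_persistently_closed = sum(x$label == "PC")
  )
}

#' @rdname summarize_dynamics
#' @param x A `dynamics` tibble.
#' @param ... Unused.
#' @export
tidy.dynamics <- function(x, ...) {
  summarize_dynamics(x)
}
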