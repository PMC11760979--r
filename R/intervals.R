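# Column order used for interval tibbles throughout the package.
.interval_cols <- c("chrom", "start", "end")

#' Validate a tibble of genomic intervals
#'
#' Intervals are BED-convention half-open spans: `start` is 0-based
#' inclusive, `end` is 0-based exclusive, so an interval covers bases
#' `start .. end - 1`. Strand is never carried on intervals; chromatin
#' accessibility and binding loci are unstranded.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param arg Name used in error messages.
#' @return `x` as a tibble, invisibly unchanged apart from class.
#' @keywords internal
validate_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", arg))
  }
  missing_cols <- setdiff(.interval_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` lacks interval column(s): %s", arg,
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(x)
  if (!is.character(x$chrom) || anyNA(x$chrom) || any(x$chrom == "")) {
    abort(sprintf("`%s`: `chrom` must be non-empty strings", arg))
  }
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    abort(sprintf("`%s`: `start`/`end` must be numeric", arg))
  }
  if (anyNA(x$start) || anyNA(x$end)) {
    abort(sprintf("`%s`: coordinates contain NA", arg))
  }
  if (any(x$start != floor(x$start)) || any(x$end != floor(x$end))) {
    abort(sprintf("`%s`: coordinates must be whole numbers", arg))
  }
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s`: invalid interval at row %d (start %s, end %s); need start >= 0 and end > start",
      arg, bad[1], format(x$start[bad[1]], scientific = FALSE),
      format(x$end[bad[1]], scientific = FALSE)
    ))
  }
  x
}

# BED half-open 0-based -> IRanges 1-based closed.
intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

gr_to_intervals <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Sort intervals by (chrom, start, end)
#' @keywords internal
sort_intervals <- function(x) {
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

#' Merge an interval set into disjoint loci
#'
#' Overlapping and book-ended (touching) intervals are collapsed into a
#' single span, so each merged locus is one contiguous region.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`).
#' @return Tibble of sorted, disjoint intervals.
#' @export
#' @examples
#' merge_intervals(tibble::tibble(
#'   chrom = "chr1", start = c(100, 150, 250), end = c(200, 250, 300)
#' ))
merge_intervals <- function(x) {
  x <- validate_intervals(x)
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  gr <- GenomicRanges::reduce(intervals_to_gr(x), min.gapwidth = 1L)
  sort_intervals(gr_to_intervals(gr))
}
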