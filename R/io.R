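# Readers and writers for the plain-text genomic formats the pipeline
# touches: BED3/BED5 (peaks, binding sites, loci), bedGraph (coverage),
# and headered TSVs (library statistics, gene tables). All coordinates
# are 0-based half-open. Parsers reject malformed records with the
# offending line number; they never silently repair them.

# Returns data lines with original line numbers; skips comments,
# track/browser lines and blank lines.
read_data_lines <- function(path) {
  if (!file.exists(path)) {
    usage_error(sprintf("input file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) &
    !grepl("^#", lines) &
    !grepl("^(track|browser)\\b", lines)
  tibble::tibble(line_no = seq_along(lines), text = lines)[keep, ]
}

parse_coord <- function(x, path, line_no, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad)) {
    i <- which(bad)[1]
    data_error(sprintf(
      "%s, line %d: %s '%s' is not an integer", path, line_no[i], what, x[i]
    ))
  }
  v
}

#' Read a BED file of genomic intervals
#'
#' Reads BED3 to BED5. Columns beyond the fifth are ignored; `track`,
#' `browser`, comment (`#`) and blank lines are skipped. Coordinates are
#' returned unchanged in the BED convention (0-based half-open).
#'
#' @param path Path to a tab- (or whitespace-) delimited BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, and `name` and
#'   `score` when a fourth/fifth column is present (`NA` on lines where
#'   the column is absent). Rows keep file order.
#' @export
read_bed <- function(path) {
  dat <- read_data_lines(path)
  if (nrow(dat) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(dat$text, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    data_error(sprintf(
      "%s, line %d: expected >= 3 fields, found %d", path, dat$line_no[i], nf[i]
    ))
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = parse_coord(vapply(fields, `[[`, "", 2), path, dat$line_no, "start"),
    end = parse_coord(vapply(fields, `[[`, "", 3), path, dat$line_no, "end")
  )
  bad <- which(out$start < 0 | out$end <= out$start)
  if (length(bad) > 0) {
    data_error(sprintf(
      "%s, line %d: invalid interval [%s, %s)", path, dat$line_no[bad[1]],
      format(out$start[bad[1]], scientific = FALSE),
      format(out$end[bad[1]], scientific = FALSE)
    ))
  }
  if (any(nf >= 4)) {
    out$name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA_character_)
  }
  if (any(nf >= 5)) {
    raw <- ifelse(nf >= 5, vapply(fields, function(f) f[min(5, length(f))], ""), NA_character_)
    score <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(score))
    if (length(bad) > 0) {
      data_error(sprintf(
        "%s, line %d: score '%s' is not numeric", path, dat$line_no[bad[1]], raw[bad[1]]
      ))
    }
    out$score <- score
  }
  out
}

#' Write intervals as BED
#'
#' Writes BED3, BED4 or BED5 depending on which of `name`/`score` are
#' present and non-missing. Field formatting is deterministic, so
#' writing and re-reading a valid interval table is lossless.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  has_name <- "name" %in% names(x) && nrow(x) > 0 && !all(is.na(x$name))
  has_score <- "score" %in% names(x) && nrow(x) > 0 && !all(is.na(x$score))
  cols <- list(
    x$chrom,
    format_coord(x$start),
    format_coord(x$end)
  )
  if (has_name || has_score) {
    nm <- if ("name" %in% names(x)) x$name else rep(NA_character_, nrow(x))
    cols <- c(cols, list(ifelse(is.na(nm), ".", nm)))
  }
  if (has_score) {
    cols <- c(cols, list(ifelse(is.na(x$score), ".", format_value(x$score))))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

format_value <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == floor(v) && abs(v) < 1e15) {
      format(v, scientific = FALSE, trim = TRUE)
    } else {
      formatC(v, format = "g", digits = 15)
    }
  }, "")
}

#' Read a bedGraph coverage track
#'
#' A track is a tibble of per-interval coverage values; bases not
#' covered by any interval have implicit value 0. Input intervals may be
#' unsorted, but overlapping intervals within a contig are rejected (a
#' track must define one value per base) and negative values are
#' rejected.
#'
#' @param path Path to a 4-column bedGraph file.
#' @return Tibble with `chrom`, `start`, `end`, `value`, sorted by
#'   (chrom, start).
#' @export
read_bedgraph <- function(path) {
  dat <- read_data_lines(path)
  if (nrow(dat) == 0) {
    return(empty_track())
  }
  fields <- strsplit(dat$text, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4)) {
    i <- which(nf < 4)[1]
    data_error(sprintf(
      "%s, line %d: bedGraph needs 4 fields, found %d", path, dat$line_no[i], nf[i]
    ))
  }
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4)))
  if (anyNA(value)) {
    i <- which(is.na(value))[1]
    data_error(sprintf("%s, line %d: non-numeric value", path, dat$line_no[i]))
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = parse_coord(vapply(fields, `[[`, "", 2), path, dat$line_no, "start"),
    end = parse_coord(vapply(fields, `[[`, "", 3), path, dat$line_no, "end"),
    value = value
  )
  bad <- which(out$start < 0 | out$end <= out$start)
  if (length(bad) > 0) {
    data_error(sprintf(
      "%s, line %d: invalid interval [%s, %s)", path, dat$line_no[bad[1]],
      format(out$start[bad[1]], scientific = FALSE),
      format(out$end[bad[1]], scientific = FALSE)
    ))
  }
  if (any(out$value < 0)) {
    i <- which(out$value < 0)[1]
    data_error(sprintf("%s, line %d: negative coverage value", path, dat$line_no[i]))
  }
  validate_track(sort_intervals(out), path)
}

# Checks sortedness/disjointness of a track already sorted by (chrom, start).
validate_track <- function(x, what = "track") {
  ov <- x %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::filter(dplyr::row_number() > 1 & .data$start < dplyr::lag(.data$end)) %>%
    dplyr::ungroup()
  if (nrow(ov) > 0) {
    data_error(sprintf(
      "%s: overlapping intervals on %s near position %s",
      what, ov$chrom[1], format_coord(ov$start[1])
    ))
  }
  x
}

empty_track <- function() {
  tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(), value = numeric()
  )
}

#' Write a coverage track as bedGraph
#'
#' @param x Track tibble (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  x <- validate_intervals(x)
  if (!"value" %in% names(x)) abort("track lacks a `value` column")
  writeLines(
    paste(x$chrom, format_coord(x$start), format_coord(x$end),
      format_value(x$value),
      sep = "\t"
    ),
    path
  )
  invisible(path)
}

#' Read per-library sequencing statistics
#'
#' The library table drives normalization (total unique read counts) and
#' the experimental design (timepoint and condition per library).
#'
#' @param path TSV with header columns `library_id`,
#'   `total_unique_reads`, `timepoint`, `condition` (extra columns kept).
#' @param timepoints Optional ordered character vector of valid
#'   timepoint labels; when given, unknown labels are an error and the
#'   `timepoint` column is returned as an ordered factor.
#' @return Tibble, one row per library.
#' @export
read_library_stats <- function(path, timepoints = NULL) {
  if (!file.exists(path)) usage_error(sprintf("input file not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  required <- c("library_id", "total_unique_reads", "timepoint", "condition")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    data_error(sprintf(
      "%s: missing column(s): %s", path, paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(x$library_id)) {
    dup <- x$library_id[duplicated(x$library_id)][1]
    data_error(sprintf("%s: duplicate library_id '%s'", path, dup))
  }
  if (anyNA(x$total_unique_reads) || any(x$total_unique_reads <= 0) ||
      any(x$total_unique_reads != floor(x$total_unique_reads))) {
    data_error(sprintf("%s: total_unique_reads must be positive integers", path))
  }
  if (!is.null(timepoints)) {
    unknown <- setdiff(unique(x$timepoint), timepoints)
    if (length(unknown) > 0) {
      data_error(sprintf(
        "%s: unknown timepoint label(s): %s (declared order: %s)",
        path, paste(unknown, collapse = ", "), paste(timepoints, collapse = " < ")
      ))
    }
    x$timepoint <- factor(x$timepoint, levels = timepoints, ordered = TRUE)
  }
  tibble::as_tibble(x)
}

#' Read a gene table with TSS coordinates and expression fold changes
#'
#' One row per gene: TSS position (0-based), strand, and the log2 fold
#' change of the gene's expression relative to the declared reference
#' condition. Fold changes are required for every gene because the
#' ranked moving-average profile sorts on them.
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `tss`,
#'   `strand`, `log2fc`.
#' @return Tibble, one row per gene.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("input file not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  required <- c("gene_id", "chrom", "tss", "strand", "log2fc")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    data_error(sprintf(
      "%s: missing column(s): %s", path, paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(x$gene_id)) {
    dup <- x$gene_id[duplicated(x$gene_id)][1]
    data_error(sprintf("%s: duplicate gene_id '%s'", path, dup))
  }
  if (anyNA(x$tss) || any(x$tss < 0) || any(x$tss != floor(x$tss))) {
    data_error(sprintf("%s: tss must be non-negative integers", path))
  }
  if (!all(x$strand %in% c("+", "-"))) {
    data_error(sprintf("%s: strand must be '+' or '-'", path))
  }
  if (anyNA(x$log2fc)) {
    data_error(sprintf("%s: log2fc contains NA; fold change is required", path))
  }
  tibble::as_tibble(x)
}
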