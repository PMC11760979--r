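# Peak re-calling: build the cross-library superset of peaks, quantify
# normalized tag density per locus per library, and call loci open or
# closed against a fixed threshold.
#
# The motivation is that conservative peak callers miss weak peaks, so a
# locus absent from one library's calls may still carry signal there.
# Re-calling scores every locus of the union in every library, so a
# "closed" call always means low density, never a missed caller.

#' Default open/closed density threshold
#'
#' Minimum mean per-base normalized tag density for a locus to be called
#' open. Loci at or above the threshold are open; strictly below,
#' closed.
#' @export
DEFAULT_THETA <- 0.2734

#' Per-library normalization scale factors
#'
#' Coverage is normalized to tags-per-ten-million: each library's track
#' is multiplied by `1e7 / total_unique_reads`, putting all libraries on
#' a common depth so one density threshold applies to all of them.
#'
#' @param stats Library table with `library_id` and `total_unique_reads`
#'   (see [read_library_stats()]).
#' @return Tibble with `library_id` and `scale_factor`.
#' @export
#' @examples
#' compute_scale_factor(tibble::tibble(
#'   library_id = c("a", "b"),
#'   total_unique_reads = c(1e7, 2e7)
#' ))
compute_scale_factor <- function(stats) {
  if (!all(c("library_id", "total_unique_reads") %in% names(stats))) {
    abort("`stats` needs columns library_id and total_unique_reads")
  }
  if (anyNA(stats$total_unique_reads) || any(stats$total_unique_reads <= 0)) {
    data_error("total_unique_reads must be positive")
  }
  tibble::tibble(
    library_id = stats$library_id,
    scale_factor = 1e7 / stats$total_unique_reads
  )
}

#' Scale a coverage track by a constant factor
#'
#' Multiplies every value by `factor`; interval geometry is unchanged.
#'
#' @param track Track tibble (`chrom`, `start`, `end`, `value`).
#' @param factor Positive scalar multiplier.
#' @return The scaled track.
#' @export
scale_track <- function(track, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) || factor <= 0) {
    abort("`factor` must be a single positive number")
  }
  dplyr::mutate(track, value = .data$value * factor)
}

#' Average several coverage tracks
#'
#' Used to merge biological replicates: replicate tracks are scaled to
#' common depth first, then averaged per base. Bases covered by no
#' interval in a track contribute that track's implicit 0.
#'
#' @param tracks List of track tibbles.
#' @return A single track tibble; adjacent equal-value runs are merged.
#' @export
average_tracks <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  if (length(tracks) == 1) return(tracks[[1]])
  n <- length(tracks)
  combined <- dplyr::bind_rows(tracks, .id = ".track")
  if (nrow(combined) == 0) return(empty_track())
  pieces <- GenomicRanges::disjoin(intervals_to_gr(combined))
  hits <- GenomicRanges::findOverlaps(pieces, intervals_to_gr(combined))
  val <- rep(0, length(pieces))
  agg <- tapply(
    combined$value[S4Vectors::subjectHits(hits)],
    S4Vectors::queryHits(hits), sum
  )
  val[as.integer(names(agg))] <- as.numeric(agg)
  out <- gr_to_intervals(pieces)
  out$value <- val / n
  out <- sort_intervals(out)
  collapse_track_runs(dplyr::filter(out, .data$value != 0))
}

# Merge adjacent intervals with identical values (cosmetic compaction).
collapse_track_runs <- function(track) {
  if (nrow(track) < 2) return(track)
  track %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(.run = cumsum(
      dplyr::row_number() == 1 |
        .data$start != dplyr::lag(.data$end, default = -1) |
        .data$value != dplyr::lag(.data$value, default = NA)
    )) %>%
    dplyr::group_by(.data$chrom, .data$.run) %>%
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      value = .data$value[1], .groups = "drop"
    ) %>%
    dplyr::select("chrom", "start", "end", "value") %>%
    sort_intervals()
}

#' Build the universal peak superset across libraries
#'
#' Takes each library's peak calls and forms the union of all intervals,
#' merging overlapping and book-ended peaks into single loci. Every
#' locus of the superset is subsequently quantified in every library,
#' whether or not that library's caller reported a peak there.
#'
#' @param peak_sets A named list of interval tibbles (one per library),
#'   or a single interval tibble (treated as one library).
#' @return Tibble of sorted, disjoint loci with a stable `locus_id`.
#' @export
build_superset <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  if (!is.list(peak_sets) || length(peak_sets) == 0) {
    usage_error("`peak_sets` must be a non-empty list of interval tables")
  }
  peak_sets <- purrr::imap(peak_sets, function(x, nm) {
    validate_intervals(x, arg = paste0("peak_sets[", nm, "]"))
  })
  loci <- merge_intervals(dplyr::bind_rows(
    purrr::map(peak_sets, ~ dplyr::select(.x, "chrom", "start", "end"))
  ))
  loci$locus_id <- sprintf("L%06d", seq_len(nrow(loci)))
  loci
}

# Warns (once per track) about loci on contigs the track never covers.
check_contigs <- function(loci, track, library_id) {
  absent <- setdiff(unique(loci$chrom), unique(track$chrom))
  if (length(absent) > 0 && nrow(track) > 0) {
    warn(sprintf(
      "library %s: no coverage on contig(s) %s; densities there are 0",
      library_id, paste(absent, collapse = ", ")
    ))
  }
}

#' Quantify normalized tag density per locus per library
#'
#' Tag density of a locus in a library is the mean per-base scaled
#' coverage over the locus: the summed (value x overlap width) of the
#' library's track within the locus, divided by the locus length. The
#' definition is length-independent, so short and long loci are
#' thresholded on the same scale.
#'
#' @param loci Superset loci from [build_superset()] (disjoint, sorted,
#'   with `locus_id`).
#' @param tracks Named list of depth-scaled track tibbles; names are
#'   library (or replicate-group) identifiers.
#' @return A long tibble of class `superset_matrix`: one row per
#'   (locus, library) with columns `locus_id`, `chrom`, `start`, `end`,
#'   `library_id`, `density`. The library order is kept in the
#'   `library_order` attribute.
#' @export
quantify_density <- function(loci, tracks) {
  loci <- validate_intervals(loci, "loci")
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- sprintf("L%06d", seq_len(nrow(loci)))
  }
  if (!is.list(tracks) || is.data.frame(tracks)) {
    abort("`tracks` must be a named list of track tables")
  }
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    abort("`tracks` must be named by library_id")
  }
  gr_loci <- intervals_to_gr(loci)
  width <- loci$end - loci$start
  per_lib <- purrr::imap(tracks, function(track, lib) {
    check_contigs(loci, track, lib)
    dens <- rep(0, nrow(loci))
    if (nrow(track) > 0) {
      gr_track <- intervals_to_gr(track)
      hits <- GenomicRanges::findOverlaps(gr_loci, gr_track)
      if (length(hits) > 0) {
        qh <- S4Vectors::queryHits(hits)
        sh <- S4Vectors::subjectHits(hits)
        ov <- pmin(loci$end[qh], track$end[sh]) -
          pmax(loci$start[qh], track$start[sh])
        mass <- tapply(track$value[sh] * ov, qh, sum)
        dens[as.integer(names(mass))] <- as.numeric(mass)
      }
    }
    dplyr::mutate(loci, library_id = lib, density = dens / width)
  })
  out <- dplyr::bind_rows(per_lib) %>%
    dplyr::select("locus_id", "chrom", "start", "end", "library_id", "density")
  structure(out,
    class = c("superset_matrix", class(out)),
    library_order = names(tracks)
  )
}

#' Call loci open or closed against a density threshold
#'
#' A locus is open in a library when its normalized tag density is at or
#' above `theta`, closed when strictly below. Density exactly equal to
#' `theta` is open: the threshold is read as the minimum density of a
#' genuine peak.
#'
#' @param matrix A `superset_matrix` from [quantify_density()] (any
#'   tibble with a `density` column works).
#' @param theta Open/closed threshold in normalized density units;
#'   default [DEFAULT_THETA].
#' @return The input with a logical `open` column added; class
#'   `open_matrix`, with `theta` stored as an attribute.
#' @export
call_open <- function(matrix, theta = DEFAULT_THETA) {
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta < 0) {
    abort("`theta` must be a single non-negative number")
  }
  if (!"density" %in% names(matrix)) abort("`matrix` lacks a `density` column")
  out <- dplyr::mutate(matrix, open = .data$density >= theta)
  structure(out,
    class = unique(c("open_matrix", class(out))),
    library_order = attr(matrix, "library_order"),
    theta = theta
  )
}
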