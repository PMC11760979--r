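# End-to-end orchestration: scale tracks to common depth, merge
# replicates, build the peak superset, quantify, threshold, classify.

#' Run the re-call and dynamics pipeline
#'
#' Convenience wrapper chaining [compute_scale_factor()],
#' [scale_track()], replicate merging with [average_tracks()],
#' [build_superset()], [quantify_density()], [call_open()] and
#' [classify_dynamics()].
#'
#' @param peaks Named list of per-library peak tibbles (names =
#'   `library_id`).
#' @param tracks Named list of per-library raw coverage tracks.
#' @param stats Library table (`library_id`, `total_unique_reads`,
#'   `timepoint`, `condition`).
#' @param timepoints Ordered timepoint labels.
#' @param theta Open/closed density threshold (default [DEFAULT_THETA]).
#' @param fc_threshold,pseudocount Passed to [classify_dynamics()].
#' @param merge_replicates Average depth-scaled replicate tracks within
#'   each (condition, timepoint) before quantification (default TRUE).
#' @return List of class `atacdyn_pipeline`: `superset` (loci tibble),
#'   `matrix` (open/closed calls per locus per (condition, timepoint)
#'   group), `labels` (per-condition `dynamics` tibble) and `params`.
#' @export
run_pipeline <- function(peaks, tracks, stats, timepoints = c("D0", "D1", "D3"),
                         theta = DEFAULT_THETA, fc_threshold = 1,
                         pseudocount = 0.01, merge_replicates = TRUE) {
  if (!setequal(names(tracks), stats$library_id)) {
    usage_error("track names must match stats$library_id")
  }
  sf <- compute_scale_factor(stats)
  scaled <- purrr::imap(
    tracks,
    function(tr, id) scale_track(tr, sf$scale_factor[sf$library_id == id])
  )
  if (merge_replicates) {
    groups <- stats %>%
      dplyr::mutate(group_id = paste(.data$condition, .data$timepoint, sep = "_")) %>%
      dplyr::select("library_id", "group_id", "condition", "timepoint")
    grouped <- groups %>%
      dplyr::group_by(.data$group_id) %>%
      dplyr::summarise(members = list(.data$library_id), .groups = "drop")
    use_tracks <- setNames(
      purrr::map(grouped$members, ~ average_tracks(scaled[.x])),
      grouped$group_id
    )
    design <- dplyr::distinct(
      groups, library_id = .data$group_id, .data$condition, .data$timepoint
    )
  } else {
    use_tracks <- scaled
    design <- dplyr::select(stats, "library_id", "condition", "timepoint")
  }
  superset <- build_superset(peaks)
  om <- call_open(quantify_density(superset, use_tracks), theta = theta)
  om <- dplyr::left_join(om, design, by = "library_id")
  labels <- classify_dynamics(
    dplyr::select(om, "locus_id", "condition", "timepoint", "open", "density"),
    timepoints = timepoints, fc_threshold = fc_threshold,
    pseudocount = pseudocount
  )
  structure(
    list(
      superset = superset, matrix = om, labels = labels,
      params = list(
        theta = theta, fc_threshold = fc_threshold,
        pseudocount = pseudocount, timepoints = timepoints,
        merge_replicates = merge_replicates
      )
    ),
    class = "atacdyn_pipeline"
  )
}

#' Score planted-label recovery against simulation truth
#'
#' Matches superset loci to planted loci by exact coordinates and
#' reports the fraction of planted (locus, condition) labels the
#' pipeline reproduced. Planted loci missing from the superset count as
#' unrecovered.
#'
#' @param pipeline An `atacdyn_pipeline` result.
#' @param truth_loci The simulator's `truth_loci` table.
#' @return List with `recovery` (overall fraction), `n_truth`,
#'   `n_matched`, and `by_condition` (a tibble).
#' @export
score_label_recovery <- function(pipeline, truth_loci) {
  matched <- truth_loci %>%
    dplyr::left_join(
      dplyr::select(pipeline$superset, "chrom", "start", "end",
        superset_id = "locus_id"
      ),
      by = c("chrom", "start", "end")
    ) %>%
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(pipeline$labels), "condition",
        superset_id = "locus_id", called = "label"
      ),
      by = c("condition", "superset_id")
    ) %>%
    dplyr::mutate(hit = !is.na(.data$called) &
      as.character(.data$called) == .data$label)
  by_condition <- matched %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(
      n = dplyr::n(), recovered = sum(.data$hit),
      recovery = mean(.data$hit), .groups = "drop"
    )
  list(
    recovery = mean(matched$hit),
    n_truth = nrow(matched),
    n_matched = sum(!is.na(matched$superset_id)),
    by_condition = by_condition
  )
}

#' @export
print.atacdyn_pipeline <- function(x, ...) {
  cat(sprintf(
    "atacdyn pipeline: %d superset loci, %d groups, theta = %g\n",
    nrow(x$superset),
    length(unique(x$matrix$library_id)),
    x$params$theta
  ))
  print(summarize_dynamics(x$labels))
  invisible(x)
}
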