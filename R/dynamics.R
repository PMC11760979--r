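# Temporal dynamics classification: each superset locus is labeled from
# its open/closed trajectory over an ordered time course, per condition.
#
# Classes for a 3-timepoint course (D0 < D1 < D3):
#   CO1 closed -> open at the first transition, stays open (c,o,o)
#   CO2 opens only at the final timepoint                  (c,c,o)
#   OC1 closes at the first transition                     (o,c,c)
#   OC2 closes only at the final timepoint                 (o,o,c)
#   PO  persistently open, subdivided by the log2 density change
#       between the last and first timepoints into PO_UP / PO_DOWN / PO
#   PC  persistently closed
#   COMPLEX non-monotone trajectories (open-closed-open etc.)
#
# For k > 3 timepoints only monotone patterns are labeled: CO<j>/OC<j>
# where j is the number of timepoints before the transition.

#' Dynamics class labels
#' @export
DYNAMICS_CLASSES <- c(
  "CO1", "CO2", "OC1", "OC2", "PO", "PO_UP", "PO_DOWN", "PC", "COMPLEX"
)

# Label one open/closed pattern; calls is a logical vector in timepoint
# order, delta the log2 last/first density ratio.
label_pattern <- function(calls, delta, fc_threshold) {
  n <- length(calls)
  if (all(!calls)) return("PC")
  if (all(calls)) {
    # delta exactly 0 is always plain PO, so fc_threshold = 0 splits
    # every changed locus into up/down without swallowing the unchanged
    if (delta == 0) return("PO")
    if (delta >= fc_threshold) return("PO_UP")
    if (delta <= -fc_threshold) return("PO_DOWN")
    return("PO")
  }
  n_lead_closed <- match(TRUE, calls) - 1
  n_lead_open <- match(FALSE, calls) - 1
  if (n_lead_closed > 0 && all(calls[(n_lead_closed + 1):n])) {
    return(paste0("CO", n_lead_closed))
  }
  if (n_lead_open > 0 && all(!calls[(n_lead_open + 1):n])) {
    return(paste0("OC", n_lead_open))
  }
  "COMPLEX"
}

#' Classify loci into temporal dynamics classes
#'
#' Consumes the long open-call table for one time course (optionally
#' several conditions at once) and assigns every locus exactly one
#' dynamics label per condition. Labels depend only on the open/closed
#' pattern across timepoints and, for persistently open loci, on
#' `delta_log2 = log2((d_last + pseudocount) / (d_first + pseudocount))`,
#' the depth-normalized density change from the first to the last
#' timepoint.
#'
#' @param x Long tibble with columns `locus_id`, `timepoint`, `open`
#'   (logical), `density`, and optionally `condition`; one row per
#'   (locus, timepoint) within each condition.
#' @param timepoints Ordered character vector of timepoint labels, e.g.
#'   `c("D0", "D1", "D3")`. Every (locus, condition) must have exactly
#'   one row per timepoint.
#' @param fc_threshold Minimum `|delta_log2|` for a persistently open
#'   locus to be called `PO_UP`/`PO_DOWN`; default 1 (2-fold).
#' @param pseudocount Small positive density added before the log ratio;
#'   default 0.01 normalized units.
#' @return Tibble of class `dynamics` with one row per locus (per
#'   condition): `locus_id`, (`condition`,) `pattern` (e.g. `"coo"`),
#'   `delta_log2`, `label` (factor over [DYNAMICS_CLASSES]).
#' @export
classify_dynamics <- function(x, timepoints, fc_threshold = 1,
                              pseudocount = 0.01) {
  stopifnot(is.character(timepoints), length(timepoints) >= 2)
  if (fc_threshold < 0) abort("`fc_threshold` must be >= 0")
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be > 0")
  }
  needed <- c("locus_id", "timepoint", "open", "density")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("`x` lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(unique(as.character(x$timepoint)), timepoints)
  if (length(unknown) > 0) {
    usage_error(sprintf(
      "timepoint(s) %s not in declared order %s",
      paste(unknown, collapse = ", "), paste(timepoints, collapse = " < ")
    ))
  }
  group_cols <- intersect("condition", names(x))
  x <- x %>%
    dplyr::mutate(timepoint = factor(as.character(.data$timepoint),
      levels = timepoints
    )) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(c(group_cols, "locus_id"))),
      .data$timepoint
    )
  counts <- x %>%
    dplyr::count(dplyr::across(dplyr::all_of(c(group_cols, "locus_id"))))
  if (nrow(counts) > 0 && any(counts$n != length(timepoints))) {
    usage_error(sprintf(
      "each locus needs exactly %d timepoints; found a locus with %d",
      length(timepoints), counts$n[counts$n != length(timepoints)][1]
    ))
  }
  k <- length(timepoints)
  out <- x %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "locus_id")))) %>%
    dplyr::summarise(
      pattern = paste(ifelse(.data$open, "o", "c"), collapse = ""),
      delta_log2 = log2((.data$density[k] + pseudocount) /
        (.data$density[1] + pseudocount)),
      .groups = "drop"
    )
  levels <- c(
    paste0("CO", seq_len(k - 1)), paste0("OC", seq_len(k - 1)),
    "PO", "PO_UP", "PO_DOWN", "PC", "COMPLEX"
  )
  if (k == 3) levels <- DYNAMICS_CLASSES
  out$label <- factor(
    mapply(
      function(p, d) {
        label_pattern(strsplit(p, "")[[1]] == "o", d, fc_threshold)
      },
      out$pattern, out$delta_log2,
      USE.NAMES = FALSE
    ),
    levels = levels
  )
  structure(out,
    class = unique(c("dynamics", class(out))),
    timepoints = timepoints, fc_threshold = fc_threshold,
    pseudocount = pseudocount
  )
}

#' Tally dynamics classes
#'
#' @param labels A `dynamics` tibble (or any tibble with a `label`
#'   column, plus optionally `condition`).
#' @return Tibble with one row per class (per condition), zero-filled so
#'   every class of [DYNAMICS_CLASSES] appears; counts sum to the number
#'   of loci.
#' @export
summarize_dynamics <- function(labels) {
  if (!"label" %in% names(labels)) abort("`labels` lacks a `label` column")
  group_cols <- intersect("condition", names(labels))
  lv <- factor(as.character(labels$label), levels = DYNAMICS_CLASSES)
  df <- dplyr::mutate(tibble::as_tibble(labels), label = lv)
  if (length(group_cols) == 0) {
    out <- df %>% dplyr::count(.data$label, .drop = FALSE, name = "n")
  } else {
    out <- df %>%
      dplyr::count(.data$condition, .data$label, .drop = FALSE, name = "n")
  }
  out
}

#' Compare dynamics classes between two conditions
#'
#' For each class, counts the loci labeled with that class in both
#' conditions (shared) and in exactly one (unique), by locus identity on
#' the shared superset — the per-class Venn breakdown.
#'
#' @param labels_a,labels_b `dynamics` tibbles for condition A and B,
#'   indexed by the same superset `locus_id`s.
#' @return Tibble of class `class_comparison`: one row per class with
#'   `n_a`, `n_b`, `shared`, `unique_a`, `unique_b`.
#' @export
compare_conditions <- function(labels_a, labels_b) {
  for (nm in c("labels_a", "labels_b")) {
    l <- get(nm)
    if (!all(c("locus_id", "label") %in% names(l))) {
      abort(sprintf("`%s` needs columns locus_id and label", nm))
    }
  }
  if (!setequal(labels_a$locus_id, labels_b$locus_id) ||
      anyDuplicated(labels_a$locus_id) || anyDuplicated(labels_b$locus_id)) {
    usage_error("label tables must index the same superset loci exactly once each")
  }
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(labels_a), "locus_id", label_a = "label"),
    dplyr::select(tibble::as_tibble(labels_b), "locus_id", label_b = "label"),
    by = "locus_id"
  )
  out <- purrr::map_dfr(DYNAMICS_CLASSES, function(cl) {
    in_a <- joined$label_a == cl
    in_b <- joined$label_b == cl
    tibble::tibble(
      label = cl,
      n_a = sum(in_a), n_b = sum(in_b),
      shared = sum(in_a & in_b),
      unique_a = sum(in_a & !in_b),
      unique_b = sum(in_b & !in_a)
    )
  })
  out$label <- factor(out$label, levels = DYNAMICS_CLASSES)
  structure(out, class = unique(c("class_comparison", class(out))))
}
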