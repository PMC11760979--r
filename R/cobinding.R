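# Transcription-factor co-binding integration: overlap two binding-site
# sets, assign loci to genes by TSS distance windows, average signal
# pileups centered on locus sets, and smooth binary co-binding presence
# along genes ranked by expression fold change.

#' Overlap two binding-site sets
#'
#' Each set is merged internally first, then every A locus is tested for
#' at least `min_overlap` shared base pairs with any B locus. The result
#' is A-centric (the fraction is over A loci); swap the arguments for
#' the B-centric counts.
#'
#' @param a,b Interval tibbles of binding loci.
#' @param min_overlap Minimum shared base pairs to count as overlapping
#'   (default 1).
#' @return An object of class `overlap_result`: a list with `n_a`,
#'   `n_b`, `n_overlap`, `fraction`, and `shared` (the merged A loci
#'   that overlap B). Use [tidy()] for the shared loci, [glance()] for
#'   the one-row summary.
#' @export
overlap_binding <- function(a, b, min_overlap = 1) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  if (nrow(a) == 0) {
    usage_error("set A is empty: overlap fraction is undefined")
  }
  hit <- rep(FALSE, nrow(a))
  if (nrow(b) > 0) {
    # sets on entirely different contigs are a valid (empty) overlap,
    # not worth a seqlevel warning
    hit <- suppressWarnings(GenomicRanges::countOverlaps(
      intervals_to_gr(a), intervals_to_gr(b),
      minoverlap = min_overlap
    )) > 0
  }
  structure(
    list(
      n_a = nrow(a), n_b = nrow(b),
      n_overlap = sum(hit),
      fraction = sum(hit) / nrow(a),
      shared = a[hit, ],
      min_overlap = min_overlap
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result: %d / %d A loci (%.1f%%) overlap %d B loci (>= %d bp)\n",
    x$n_overlap, x$n_a, 100 * x$fraction, x$n_b, x$min_overlap
  ))
  invisible(x)
}

# Distance (bp) from a TSS point to a half-open interval: 0 when the
# TSS base lies inside, otherwise the number of bases separating them.
tss_locus_distance <- function(tss, start, end) {
  pmax(0, pmax(start - tss, tss - (end - 1)))
}

#' Assign loci to genes by TSS distance windows
#'
#' A gene is linked to a locus when its transcription start site lies
#' within `window` bp of the locus (distance 0 when the locus spans the
#' TSS). The mapping is many-to-many; strand is deliberately ignored —
#' the window is symmetric around the TSS.
#'
#' @param loci Interval tibble; a `locus_id` column is added when absent.
#' @param genes Gene tibble from [read_gene_table()] (`gene_id`,
#'   `chrom`, `tss` required).
#' @param window Maximum TSS-to-locus distance in bp (default 10000).
#' @return Tibble with one row per (gene, locus) assignment: `gene_id`,
#'   `locus_id`, `distance`.
#' @export
assign_loci_to_genes <- function(loci, genes, window = 10000) {
  if (!is.numeric(window) || length(window) != 1 || window < 0) {
    abort("`window` must be a single non-negative number")
  }
  loci <- validate_intervals(loci, "loci")
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- sprintf("L%06d", seq_len(nrow(loci)))
  }
  if (!all(c("gene_id", "chrom", "tss") %in% names(genes))) {
    abort("`genes` needs columns gene_id, chrom, tss")
  }
  if (nrow(loci) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(
      gene_id = character(), locus_id = character(), distance = numeric()
    ))
  }
  gr_tss <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$tss + 1, genes$tss + 1)
  )
  # maxgap counts the bases strictly between the ranges, so a TSS at
  # distance d from a locus edge has gap d - 1; maxgap = window - 1
  # admits distance <= window, and window = 0 keeps containment only
  hits <- GenomicRanges::findOverlaps(
    gr_tss, intervals_to_gr(loci),
    maxgap = window - 1
  )
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  tibble::tibble(
    gene_id = genes$gene_id[qh],
    locus_id = loci$locus_id[sh],
    distance = tss_locus_distance(genes$tss[qh], loci$start[sh], loci$end[sh])
  ) %>%
    dplyr::arrange(.data$gene_id, .data$distance, .data$locus_id)
}

#' Mark per-gene co-binding presence
#'
#' Flags each gene 1 when at least one shared (co-bound) locus lies
#' within `window` bp of its TSS, else 0.
#'
#' @param genes Gene tibble.
#' @param shared_loci Shared loci, e.g. `overlap_binding(a, b)$shared`.
#' @param window Distance window in bp (default 5000).
#' @return `genes` with an integer `cobound` column appended.
#' @export
mark_cobinding_presence <- function(genes, shared_loci, window = 5000) {
  shared_loci <- validate_intervals(shared_loci, "shared_loci")
  if (nrow(shared_loci) == 0) {
    return(dplyr::mutate(tibble::as_tibble(genes), cobound = 0L))
  }
  assigned <- assign_loci_to_genes(shared_loci, genes, window = window)
  dplyr::mutate(tibble::as_tibble(genes),
    cobound = as.integer(.data$gene_id %in% assigned$gene_id)
  )
}

#' Moving-average co-binding density along expression-ranked genes
#'
#' Genes are ranked from up- to downregulated (log2 fold change
#' descending, ties broken by `gene_id` for determinism) and the binary
#' co-binding indicator is smoothed with a centered moving average of
#' `window_genes` genes, truncated (not padded) at the edges. The
#' smoothed curve visualizes how co-binding density tracks expression
#' change.
#'
#' @param genes Gene tibble carrying `log2fc` and a 0/1 `cobound`
#'   indicator (see [mark_cobinding_presence()]).
#' @param window_genes Odd positive window size in genes (default 101).
#' @return Tibble of class `ma_profile`: `rank`, `gene_id`, `log2fc`,
#'   `cobound`, `smoothed` (in `[0, 1]`), ordered by rank.
#' @export
moving_average_profile <- function(genes, window_genes = 101) {
  if (!all(c("gene_id", "log2fc", "cobound") %in% names(genes))) {
    abort("`genes` needs columns gene_id, log2fc, cobound")
  }
  if (!is.numeric(window_genes) || length(window_genes) != 1 ||
      is.na(window_genes) || window_genes < 1 ||
      window_genes != floor(window_genes) || window_genes %% 2 == 0) {
    usage_error("`window_genes` must be an odd positive integer")
  }
  ranked <- tibble::as_tibble(genes) %>%
    dplyr::arrange(dplyr::desc(.data$log2fc), .data$gene_id) %>%
    dplyr::mutate(rank = dplyr::row_number())
  n <- nrow(ranked)
  h <- (window_genes - 1) / 2
  cs <- c(0, cumsum(ranked$cobound))
  lo <- pmax(0, seq_len(n) - 1 - h)
  hi <- pmin(n, seq_len(n) + h)
  smoothed <- (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
  out <- dplyr::select(
    dplyr::mutate(ranked, smoothed = smoothed),
    "rank", "gene_id", "log2fc", "cobound", "smoothed"
  )
  structure(out,
    class = unique(c("ma_profile", class(out))),
    window_genes = window_genes
  )
}

#' Average signal pileup centered on a locus set
#'
#' For each locus the window `[center - flank, center + flank)` around
#' its midpoint is cut into fixed-width bins and the mean per-base
#' coverage of the track is computed per bin; the profile is the mean of
#' these per-locus profiles. Windows truncated by a contig edge
#' contribute zeros for the out-of-range bases, matching the implicit
#' zero coverage there.
#'
#' @param loci Interval tibble the windows are centered on (non-empty).
#' @param track Depth-scaled track tibble.
#' @param flank Bases on each side of the locus center (default 2000);
#'   must be a multiple of `bin_size`.
#' @param bin_size Bin width in bp (default 50).
#' @return Tibble of class `pileup_profile`: one row per bin with `bin`,
#'   `offset` (bin start relative to center) and `value` (mean
#'   normalized coverage); attributes `flank`, `bin_size`, `n_loci`.
#' @export
pileup_profile <- function(loci, track, flank = 2000, bin_size = 50) {
  loci <- validate_intervals(loci, "loci")
  if (nrow(loci) == 0) usage_error("`loci` is empty: nothing to center on")
  if (bin_size <= 0 || flank <= 0 || flank %% bin_size != 0) {
    abort("`flank` must be a positive multiple of `bin_size`")
  }
  n_bins <- as.integer(2 * flank / bin_size)
  center <- floor((loci$start + loci$end) / 2)
  grid <- tidyr::expand_grid(
    locus = seq_len(nrow(loci)),
    bin = seq_len(n_bins)
  ) %>%
    dplyr::mutate(
      offset = -flank + (.data$bin - 1) * bin_size,
      win_start = center[.data$locus] + .data$offset,
      win_end = .data$win_start + bin_size,
      chrom = loci$chrom[.data$locus]
    ) %>%
    # clip windows at the contig start; clipped bases count as zeros
    dplyr::mutate(win_start = pmax(.data$win_start, 0)) %>%
    dplyr::filter(.data$win_end > .data$win_start)
  mass <- rep(0, nrow(grid))
  if (nrow(track) > 0) {
    gr_bins <- GenomicRanges::GRanges(
      grid$chrom, IRanges::IRanges(grid$win_start + 1, grid$win_end)
    )
    gr_track <- intervals_to_gr(track)
    hits <- GenomicRanges::findOverlaps(gr_bins, gr_track)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov <- pmin(grid$win_end[qh], track$end[sh]) -
        pmax(grid$win_start[qh], track$start[sh])
      agg <- tapply(track$value[sh] * ov, qh, sum)
      mass[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  # mean per-base coverage per bin: divide by full bin width, then
  # average over all loci (a clipped bin still divides by bin_size)
  per_bin <- grid %>%
    dplyr::mutate(cov = mass / bin_size) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(value = sum(.data$cov) / nrow(loci), .groups = "drop")
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    offset = -flank + (seq_len(n_bins) - 1) * bin_size
  ) %>%
    dplyr::left_join(per_bin, by = "bin") %>%
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0))
  structure(out,
    class = unique(c("pileup_profile", class(out))),
    flank = flank, bin_size = bin_size, n_loci = nrow(loci)
  )
}
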