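# Brute-force oracles and random fixture generators. Everything here is
# deliberately naive (per-base arrays, all-pairs scans, exhaustive
# enumeration) and independent of the package's interval machinery.

# logical per-base cover array for one contig; base i (0-based) is
# array index i + 1
cover_array <- function(intervals, contig, contig_len) {
  a <- rep(FALSE, contig_len)
  sub <- intervals[intervals$chrom == contig, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    if (sub$start[i] < contig_len) {
      a[(sub$start[i] + 1):min(sub$end[i], contig_len)] <- TRUE
    }
  }
  a
}

# per-base value array for a track on one contig
value_array <- function(track, contig, contig_len) {
  a <- rep(0, contig_len)
  sub <- track[track$chrom == contig, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    if (sub$start[i] < contig_len) {
      a[(sub$start[i] + 1):min(sub$end[i], contig_len)] <- sub$value[i]
    }
  }
  a
}

# mean per-base value of a track over a half-open locus
bruteforce_density <- function(track, chrom, start, end, contig_len = end) {
  a <- value_array(track, chrom, max(contig_len, end))
  mean(a[(start + 1):end])
}

rand_intervals <- function(n, contig = "chr1", contig_len = 10000,
                           max_len = 300, bed5 = FALSE) {
  start <- sample.int(contig_len - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  out <- tibble::tibble(chrom = contig, start = start, end = start + len)
  if (bed5) {
    out$name <- sprintf("iv%03d", seq_len(n))
    out$score <- round(stats::runif(n, 0, 1000), 2)
  }
  out
}

# random sorted non-overlapping track with gaps
rand_track <- function(n, contig = "chr1", contig_len = 10000,
                       max_len = 200, max_value = 5) {
  bounds <- sort(sample.int(contig_len, 2 * n))
  start <- bounds[seq(1, 2 * n, by = 2)] - 1
  end <- bounds[seq(2, 2 * n, by = 2)]
  keep <- end > start
  tibble::tibble(
    chrom = contig, start = start[keep], end = end[keep],
    value = round(stats::runif(sum(keep), 0, max_value), 3)
  )
}

# Exhaustive truth table for 3-timepoint dynamics labels, enumerated
# directly from the class definitions (independent of label_pattern):
# each row lists the open/closed pattern and the label for a given
# delta regime (down: delta <= -thr, flat: |delta| < thr, up: >= thr).
dynamics_truth_table <- function() {
  tibble::tribble(
    ~pattern, ~down, ~flat, ~up,
    "ccc", "PC", "PC", "PC",
    "cco", "CO2", "CO2", "CO2",
    "coc", "COMPLEX", "COMPLEX", "COMPLEX",
    "coo", "CO1", "CO1", "CO1",
    "occ", "OC1", "OC1", "OC1",
    "oco", "COMPLEX", "COMPLEX", "COMPLEX",
    "ooc", "OC2", "OC2", "OC2",
    "ooo", "PO_DOWN", "PO", "PO_UP"
  )
}

# all-pairs overlap oracle: which rows of a overlap any row of b by at
# least min_overlap shared bases
bruteforce_overlap <- function(a, b, min_overlap = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= min_overlap
    }, logical(1)))
  }, logical(1))
}

# distance from a TSS point to a half-open interval, by scanning bases
bruteforce_tss_distance <- function(tss, start, end) {
  if (tss >= start && tss < end) return(0)
  min(abs(tss - start), abs(tss - (end - 1)))
}

# truncated centered moving average, the direct definition
bruteforce_moving_average <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# small simulation config for fast unit tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    contigs = c(t1 = 4e5, t2 = 4e5),
    n_per_class = 15,
    n_genes = 120,
    n_extra_sites = 40,
    n_replicates = 1,
    ...
  )
}
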