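# Synthetic multi-timepoint, two-condition ATAC-like datasets with
# planted ground truth: coverage tracks, per-library peak calls, two TF
# binding-site sets with a controlled co-binding fraction near
# upregulated genes, and gene tables whose fold changes couple to
# co-binding. Every pipeline stage is testable without any download.

SIM_CLASSES <- c("CO1", "CO2", "OC1", "OC2", "PO", "PO_UP", "PO_DOWN")

# open/closed pattern per planted class over 3 timepoints
SIM_PATTERNS <- list(
  CO1 = c(FALSE, TRUE, TRUE),
  CO2 = c(FALSE, FALSE, TRUE),
  OC1 = c(TRUE, FALSE, FALSE),
  OC2 = c(TRUE, TRUE, FALSE),
  PO = c(TRUE, TRUE, TRUE),
  PO_UP = c(TRUE, TRUE, TRUE),
  PO_DOWN = c(TRUE, TRUE, TRUE)
)

#' Simulation configuration
#'
#' Defines the study design the generator emulates: a 3-timepoint
#' (D0/D1/D3), 2-condition (WT/KO) chromatin time course with planted
#' dynamics classes, plus two TF binding-site sets whose co-binding near
#' a gene's TSS is coupled to that gene's expression fold change.
#'
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   output bundles.
#' @param contigs Named numeric vector of contig lengths in bp.
#' @param timepoints Ordered timepoint labels (exactly 3).
#' @param conditions Two condition labels; the first is the reference.
#' @param n_per_class Loci planted per dynamics class per condition
#'   (default 500).
#' @param locus_length Planted locus width in bp (default 400).
#' @param open_density_mean,closed_density_mean Mean normalized density
#'   of open / closed states (defaults 1.0 and 0.05, straddling the
#'   default open/closed threshold of 0.2734).
#' @param background_density Constant low coverage outside planted loci
#'   (default 0.01) so thresholding is non-degenerate.
#' @param noise_sd Standard deviation of multiplicative log-normal noise
#'   on per-locus densities (default 0.2; 0 disables noise).
#' @param po_change_log2 Planted |log2 change| of PO_UP/PO_DOWN loci
#'   between first and last timepoint (default 2).
#' @param condition_shuffle Fraction of loci whose planted class is
#'   permuted in the second condition (default 0.5); per-condition class
#'   counts are preserved exactly.
#' @param n_replicates Replicate libraries per (condition, timepoint)
#'   (default 2).
#' @param reads_per_library Nominal total unique reads per library
#'   (default 1e7); actual totals vary uniformly within +/-20%.
#' @param n_genes Number of genes (default 2000).
#' @param cobind_fraction_up,cobind_fraction_down Probability that a
#'   gene in the top / bottom expression tercile has a co-bound locus
#'   planted within 5 kb of its TSS (defaults 0.6 and 0.1; the middle
#'   tercile uses their mean).
#' @param n_extra_sites Binding sites per factor placed independently of
#'   genes (default 500 each), so the two sets overlap only partially.
#' @param theta Open/closed threshold the per-library peak "caller"
#'   applies to its own sampled densities (default [DEFAULT_THETA]);
#'   this is how weak peaks go missing from single-library peak lists.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       contigs = c(sim1 = 12e6, sim2 = 12e6, sim3 = 12e6),
                       timepoints = c("D0", "D1", "D3"),
                       conditions = c("WT", "KO"),
                       n_per_class = 500,
                       locus_length = 400,
                       open_density_mean = 1.0,
                       closed_density_mean = 0.05,
                       background_density = 0.01,
                       noise_sd = 0.2,
                       po_change_log2 = 2.0,
                       condition_shuffle = 0.5,
                       n_replicates = 2,
                       reads_per_library = 1e7,
                       n_genes = 2000,
                       cobind_fraction_up = 0.6,
                       cobind_fraction_down = 0.1,
                       n_extra_sites = 500,
                       theta = DEFAULT_THETA) {
  cfg <- as.list(environment())
  if (length(timepoints) != 3) abort("the generator plants 3-timepoint courses")
  if (length(conditions) != 2) abort("exactly two conditions are required")
  rates <- c(cobind_fraction_up, cobind_fraction_down, condition_shuffle)
  if (any(rates < 0 | rates > 1)) abort("fractions must lie in [0, 1]")
  if (!(open_density_mean > theta && theta > closed_density_mean)) {
    abort("need open_density_mean > theta > closed_density_mean")
  }
  if (is.null(names(contigs)) || any(names(contigs) == "")) {
    abort("`contigs` must be a named vector of lengths")
  }
  if (n_per_class < 1 || locus_length < 1 || n_genes < 1 || n_replicates < 1) {
    abort("counts must be positive")
  }
  structure(cfg, class = "sim_config")
}

# Non-overlapping placement by rejection: oversample starts, keep those
# at least `len + gap` apart, retry until enough survive.
place_intervals <- function(contigs, n, len, gap = 10, max_rounds = 40) {
  total_len <- sum(contigs)
  if (n * (len + gap) > 0.5 * total_len) {
    data_error("contigs too small for the requested number of loci")
  }
  per_contig <- diff(round(c(0, cumsum(contigs / total_len)) * n))
  out <- purrr::map2_dfr(names(contigs), per_contig, function(nm, k) {
    if (k == 0) {
      return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
    }
    clen <- contigs[[nm]]
    kept <- numeric(0)
    for (round in seq_len(max_rounds)) {
      cand <- sort(unique(c(kept, floor(runif(2 * k, 0, clen - len)))))
      # greedy thinning: keep a start only when far enough from the last kept
      sel <- cand[1]
      last <- cand[1]
      for (s in cand[-1]) {
        if (s - last >= len + gap) {
          sel <- c(sel, s)
          last <- s
        }
      }
      kept <- sel
      if (length(kept) >= k) break
    }
    if (length(kept) < k) data_error("could not place loci without overlap")
    if (length(kept) > k) kept <- sort(sample(kept, k))
    tibble::tibble(chrom = nm, start = kept, end = kept + len)
  })
  sort_intervals(out)
}

# Planted mean density for one class across the 3 timepoints.
class_mean_profile <- function(class, cfg) {
  open <- cfg$open_density_mean
  closed <- cfg$closed_density_mean
  h <- cfg$po_change_log2 / 2
  if (class == "PO_UP") return(open * 2^c(-h, 0, h))
  if (class == "PO_DOWN") return(open * 2^c(h, 0, -h))
  ifelse(SIM_PATTERNS[[class]], open, closed)
}

#' Generate a synthetic chromatin-dynamics dataset with planted truth
#'
#' Emits, per (condition, timepoint, replicate) library: a raw coverage
#' track (bedGraph geometry) whose per-locus mean density after depth
#' scaling follows the planted class profile under multiplicative
#' log-normal noise, and a per-library peak list containing only the
#' loci whose sampled density clears the threshold in that library —
#' reproducing the "weak peak missed by the caller" phenomenon the
#' re-call procedure addresses. Also emits two TF binding-site sets
#' whose co-binding near TSSs is coupled to gene expression fold change,
#' the gene table, per-library read totals, and the full ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_bundle` with elements `config`, `loci`,
#'   `truth_loci`, `truth_genes`, `stats`, `tracks` (named list of raw
#'   track tibbles), `peaks` (named list of interval tibbles),
#'   `binding_a`, `binding_b`, `genes`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  cfg <- config

  n_loci <- length(SIM_CLASSES) * cfg$n_per_class
  loci <- place_intervals(cfg$contigs, n_loci, cfg$locus_length)
  loci$locus_id <- sprintf("P%06d", seq_len(nrow(loci)))

  # planted labels: exact class counts in both conditions
  labels_wt <- sample(rep(SIM_CLASSES, each = cfg$n_per_class))
  labels_ko <- labels_wt
  n_shuffle <- round(cfg$condition_shuffle * n_loci)
  if (n_shuffle > 1) {
    idx <- sample(n_loci, n_shuffle)
    labels_ko[idx] <- labels_wt[idx][sample(n_shuffle)]
  }
  planted <- setNames(list(labels_wt, labels_ko), cfg$conditions)

  truth_loci <- purrr::map_dfr(cfg$conditions, function(cond) {
    dplyr::mutate(loci, condition = cond, label = planted[[cond]])
  })

  # per-library design and read depths
  design <- tidyr::expand_grid(
    condition = cfg$conditions,
    timepoint = cfg$timepoints,
    replicate = seq_len(cfg$n_replicates)
  ) %>%
    dplyr::mutate(
      library_id = sprintf("%s_%s_r%d", .data$condition, .data$timepoint,
                           .data$replicate),
      total_unique_reads = round(cfg$reads_per_library * runif(dplyr::n(), 0.8, 1.2))
    )
  stats <- dplyr::select(
    design, "library_id", "total_unique_reads", "timepoint", "condition",
    "replicate"
  )

  # planted mean density per (condition, locus, timepoint)
  mean_profiles <- purrr::map(SIM_CLASSES, class_mean_profile, cfg = cfg)
  names(mean_profiles) <- SIM_CLASSES

  tracks <- list()
  peaks <- list()
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]
    tp_idx <- match(design$timepoint[i], cfg$timepoints)
    mu <- vapply(planted[[cond]], function(cl) mean_profiles[[cl]][tp_idx], 0)
    noise <- if (cfg$noise_sd > 0) exp(rnorm(n_loci, 0, cfg$noise_sd)) else 1
    sampled <- mu * noise
    raw_scale <- design$total_unique_reads[i] / 1e7
    tracks[[design$library_id[i]]] <-
      densities_to_track(loci, sampled * raw_scale,
        cfg$contigs, cfg$background_density * raw_scale
      )
    peaks[[design$library_id[i]]] <-
      dplyr::select(loci[sampled >= cfg$theta, ], "chrom", "start", "end")
  }

  genes_bundle <- simulate_genes(cfg, loci)

  structure(
    list(
      config = cfg, loci = loci, truth_loci = truth_loci,
      truth_genes = genes_bundle$truth_genes, stats = stats,
      tracks = tracks, peaks = peaks,
      binding_a = genes_bundle$binding_a, binding_b = genes_bundle$binding_b,
      genes = genes_bundle$genes
    ),
    class = "sim_bundle"
  )
}

# Constant-value locus coverage plus constant background elsewhere.
densities_to_track <- function(loci, values, contigs, background) {
  loci <- sort_intervals(dplyr::mutate(loci, value = unname(values)))
  purrr::map_dfr(names(contigs), function(nm) {
    clen <- contigs[[nm]]
    sub <- loci[loci$chrom == nm, ]
    if (nrow(sub) == 0) {
      return(tibble::tibble(chrom = nm, start = 0, end = clen, value = background))
    }
    gap_start <- c(0, sub$end)
    gap_end <- c(sub$start, clen)
    gaps <- tibble::tibble(
      chrom = nm, start = gap_start, end = gap_end, value = background
    )[gap_end > gap_start, ]
    sort_intervals(dplyr::bind_rows(
      gaps, dplyr::select(sub, "chrom", "start", "end", "value")
    ))
  })
}

# Genes, fold changes, and the two binding-site sets with co-binding
# coupled to expression terciles.
simulate_genes <- function(cfg, loci) {
  margin <- 6000
  gene_chrom <- sample(names(cfg$contigs), cfg$n_genes,
    replace = TRUE, prob = cfg$contigs / sum(cfg$contigs)
  )
  tss <- floor(runif(
    cfg$n_genes, margin, cfg$contigs[gene_chrom] - margin
  ))
  genes <- tibble::tibble(
    gene_id = sprintf("G%05d", seq_len(cfg$n_genes)),
    chrom = gene_chrom,
    tss = tss,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    log2fc = rnorm(cfg$n_genes)
  )
  tercile <- dplyr::ntile(dplyr::desc(genes$log2fc), 3)
  p_cobind <- c(
    cfg$cobind_fraction_up,
    mean(c(cfg$cobind_fraction_up, cfg$cobind_fraction_down)),
    cfg$cobind_fraction_down
  )[tercile]
  cobound <- as.integer(runif(cfg$n_genes) < p_cobind)

  # co-bound genes get an overlapping A/B site pair near the TSS; the
  # shared (intersection) region lies within 5 kb of the TSS
  site_len <- 200
  offset <- floor(runif(cfg$n_genes, -4500, 4500))
  center <- pmax(genes$tss + offset, site_len)
  a_pair <- tibble::tibble(
    chrom = genes$chrom, start = center - 150, end = center + 50
  )[cobound == 1, ]
  b_pair <- tibble::tibble(
    chrom = genes$chrom, start = center - 50, end = center + 150
  )[cobound == 1, ]

  extra_a <- place_intervals(cfg$contigs, cfg$n_extra_sites, site_len, gap = 200)
  extra_b <- place_intervals(cfg$contigs, cfg$n_extra_sites, site_len, gap = 200)

  list(
    genes = genes,
    truth_genes = dplyr::mutate(
      dplyr::select(genes, "gene_id", "log2fc"), cobound = cobound
    ),
    binding_a = sort_intervals(dplyr::bind_rows(a_pair, extra_a)),
    binding_b = sort_intervals(dplyr::bind_rows(b_pair, extra_b))
  )
}

#' Write a simulated bundle to disk
#'
#' Emits the bundle as the plain-text files the pipeline reads: one
#' bedGraph and one peak BED per library, the library-statistics and
#' gene TSVs, the two binding-site BEDs, the planted-truth TSVs, and an
#' echo of the resolved configuration.
#'
#' @param bundle A `sim_bundle` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  for (d in file.path(dir, c("", "tracks", "peaks"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  for (lib in names(bundle$tracks)) {
    write_bedgraph(bundle$tracks[[lib]],
      file.path(dir, "tracks", paste0(lib, ".bedgraph"))
    )
    write_bed(bundle$peaks[[lib]], file.path(dir, "peaks", paste0(lib, ".bed")))
  }
  readr::write_tsv(bundle$stats, file.path(dir, "stats.tsv"))
  readr::write_tsv(bundle$genes, file.path(dir, "genes.tsv"))
  write_bed(bundle$binding_a, file.path(dir, "binding_a.bed"))
  write_bed(bundle$binding_b, file.path(dir, "binding_b.bed"))
  readr::write_tsv(bundle$truth_loci, file.path(dir, "truth_loci.tsv"))
  readr::write_tsv(bundle$truth_genes, file.path(dir, "truth_genes.tsv"))
  cfg <- bundle$config
  echo <- tibble::tibble(
    key = names(cfg),
    value = vapply(cfg, function(v) {
      if (!is.null(names(v))) {
        paste(sprintf("%s:%s", names(v), format(v, scientific = FALSE, trim = TRUE)),
          collapse = ";"
        )
      } else {
        paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
      }
    }, "")
  )
  readr::write_tsv(echo, file.path(dir, "config.tsv"))
  invisible(dir)
}

#' Read a simulated bundle back from disk
#'
#' @param dir Directory written by [write_sim_bundle()].
#' @return A list with `stats`, `tracks`, `peaks`, `genes`, `binding_a`,
#'   `binding_b`, `truth_loci`, `truth_genes` (no `config`).
#' @export
read_sim_bundle <- function(dir) {
  track_files <- sort(list.files(file.path(dir, "tracks"), full.names = TRUE))
  peak_files <- sort(list.files(file.path(dir, "peaks"), full.names = TRUE))
  name_of <- function(p) sub("\\.(bedgraph|bed)$", "", basename(p))
  list(
    stats = read_library_stats(file.path(dir, "stats.tsv")),
    tracks = setNames(purrr::map(track_files, read_bedgraph), name_of(track_files)),
    peaks = setNames(purrr::map(peak_files, read_bed), name_of(peak_files)),
    genes = read_gene_table(file.path(dir, "genes.tsv")),
    binding_a = read_bed(file.path(dir, "binding_a.bed")),
    binding_b = read_bed(file.path(dir, "binding_b.bed")),
    truth_loci = readr::read_tsv(file.path(dir, "truth_loci.tsv"),
      show_col_types = FALSE, progress = FALSE
    ),
    truth_genes = readr::read_tsv(file.path(dir, "truth_genes.tsv"),
      show_col_types = FALSE, progress = FALSE
    )
  )
}

#' A tiny fixed worked example
#'
#' A deterministic, hand-sized bundle (one 100 kb contig, 7 loci — one
#' per dynamics class — 5 genes, 1 condition, no noise) whose every
#' value is printable. Used in the documentation and unit tests.
#'
#' The planted loci start at 1000, 3000, ..., 13000 (width 400) with
#' classes CO1, CO2, OC1, OC2, PO, PO_UP, PO_DOWN in that order; open
#' densities are 1.0 (with the PO_UP ramp 0.5/1/2 and PO_DOWN 2/1/0.5),
#' closed densities 0.05, background 0.01. Genes G1..G5 sit at TSS
#' 20000, 30000, ..., 60000 with log2 fold changes 2, 1, 0, -1, -2; G1
#' and G3 carry an overlapping A/B binding-site pair at their TSS.
#'
#' @return A list shaped like [simulate_dataset()]'s bundle.
#' @export
simulate_worked_example <- function() {
  contigs <- c(toy = 100000)
  timepoints <- c("D0", "D1", "D3")
  classes <- SIM_CLASSES
  loci <- tibble::tibble(
    chrom = "toy",
    start = seq(1000, by = 2000, length.out = 7),
    end = seq(1000, by = 2000, length.out = 7) + 400,
    locus_id = sprintf("P%06d", 1:7)
  )
  cfg <- sim_config(
    seed = 0, contigs = contigs, conditions = c("WT", "KO"),
    n_per_class = 1, noise_sd = 0, n_replicates = 1, n_genes = 5
  )
  profiles <- purrr::map(classes, class_mean_profile, cfg = cfg)
  names(profiles) <- classes

  stats <- tibble::tibble(
    library_id = paste0("WT_", timepoints, "_r1"),
    total_unique_reads = 1e7,
    timepoint = timepoints,
    condition = "WT",
    replicate = 1L
  )
  tracks <- list()
  peaks <- list()
  for (i in seq_along(timepoints)) {
    dens <- vapply(classes, function(cl) profiles[[cl]][i], 0)
    tracks[[stats$library_id[i]]] <-
      densities_to_track(loci, dens, contigs, cfg$background_density)
    peaks[[stats$library_id[i]]] <-
      dplyr::select(loci[dens >= cfg$theta, ], "chrom", "start", "end")
  }
  genes <- tibble::tibble(
    gene_id = paste0("G", 1:5),
    chrom = "toy",
    tss = seq(20000, 60000, by = 10000),
    strand = c("+", "-", "+", "-", "+"),
    log2fc = c(2, 1, 0, -1, -2)
  )
  cobound <- c(1L, 0L, 1L, 0L, 0L)
  at <- genes$tss[cobound == 1]
  binding_a <- tibble::tibble(chrom = "toy", start = at - 150, end = at + 50)
  binding_b <- tibble::tibble(chrom = "toy", start = at - 50, end = at + 150)
  # one factor-specific site each, far from any TSS
  binding_a <- dplyr::bind_rows(
    binding_a, tibble::tibble(chrom = "toy", start = 80000, end = 80200)
  )
  binding_b <- dplyr::bind_rows(
    binding_b, tibble::tibble(chrom = "toy", start = 90000, end = 90200)
  )
  truth_loci <- dplyr::mutate(loci, condition = "WT", label = classes)
  structure(
    list(
      config = cfg, loci = loci, truth_loci = truth_loci,
      truth_genes = dplyr::mutate(
        dplyr::select(genes, "gene_id", "log2fc"), cobound = cobound
      ),
      stats = stats, tracks = tracks, peaks = peaks,
      binding_a = sort_intervals(binding_a),
      binding_b = sort_intervals(binding_b),
      genes = genes
    ),
    class = "sim_bundle"
  )
}
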