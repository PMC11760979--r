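# Binding-site overlap, gene-window assignment, moving-average and
# pileup profiles.

test_that("overlap fraction is 1 against itself and 0 for disjoint sets", {
  withr::local_seed(31)
  a <- merge_intervals(rand_intervals(20))
  self <- overlap_binding(a, a)
  expect_equal(self$fraction, 1)
  expect_equal(self$n_overlap, self$n_a)

  b <- dplyr::mutate(a, chrom = "other")
  none <- overlap_binding(a, b)
  expect_equal(none$fraction, 0)
  expect_equal(nrow(none$shared), 0)

  expect_error(overlap_binding(a[0, ], b), "empty")
})

test_that("overlap counts match the all-pairs oracle on random set pairs", {
  withr::local_seed(32)
  for (i in 1:60) {
    a <- merge_intervals(rand_intervals(sample(1:25, 1)))
    b <- merge_intervals(rand_intervals(sample(1:25, 1)))
    ov <- overlap_binding(a, b)
    hit <- bruteforce_overlap(a, b)
    expect_equal(ov$n_overlap, sum(hit))
    expect_equal(ov$shared[, 1:3], a[hit, 1:3])
    expect_equal(ov$fraction, mean(hit))
  }
})

test_that("overlap fraction is invariant under joint translation", {
  withr::local_seed(33)
  a <- merge_intervals(rand_intervals(15))
  b <- merge_intervals(rand_intervals(15))
  f0 <- overlap_binding(a, b)$fraction
  shift <- 12345
  f1 <- overlap_binding(
    dplyr::mutate(a, start = start + shift, end = end + shift),
    dplyr::mutate(b, start = start + shift, end = end + shift)
  )$fraction
  expect_equal(f0, f1)
})

test_that("gene assignment uses TSS distance with containment at distance 0", {
  loci <- tibble::tibble(chrom = "c", start = 1000, end = 1400, locus_id = "L1")
  spanning <- tibble::tibble(gene_id = "g", chrom = "c", tss = 1200)
  expect_equal(assign_loci_to_genes(loci, spanning, window = 0)$distance, 0)

  # boundary: the window is inclusive at exactly `window` bases
  at_limit <- tibble::tibble(gene_id = "g", chrom = "c", tss = 1399 + 10000)
  expect_equal(nrow(assign_loci_to_genes(loci, at_limit, window = 10000)), 1)
  past_limit <- tibble::tibble(gene_id = "g", chrom = "c", tss = 1399 + 10001)
  expect_equal(nrow(assign_loci_to_genes(loci, past_limit, window = 10000)), 0)
})

test_that("gene assignment matches the brute-force distance oracle on a 1 Mb contig", {
  withr::local_seed(34)
  loci <- merge_intervals(rand_intervals(60, contig_len = 1e6, max_len = 500))
  loci$locus_id <- sprintf("L%03d", seq_len(nrow(loci)))
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:50), chrom = "chr1",
    tss = sample.int(1e6, 50) - 1
  )
  for (window in c(0, 1000, 10000)) {
    got <- assign_loci_to_genes(loci, genes, window = window)
    want <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      purrr::map_dfr(seq_len(nrow(loci)), function(j) {
        d <- bruteforce_tss_distance(genes$tss[i], loci$start[j], loci$end[j])
        if (d <= window) {
          tibble::tibble(gene_id = genes$gene_id[i], locus_id = loci$locus_id[j],
            distance = d
          )
        }
      })
    })
    if (nrow(want) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$gene_id, want$distance, want$locus_id), ]
      expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
    }
  }
})

test_that("gene assignment is monotone in the window size", {
  withr::local_seed(35)
  loci <- merge_intervals(rand_intervals(40, contig_len = 1e6, max_len = 400))
  loci$locus_id <- sprintf("L%03d", seq_len(nrow(loci)))
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:30), chrom = "chr1", tss = sample.int(1e6, 30) - 1
  )
  key <- function(x) paste(x$gene_id, x$locus_id)
  prev <- character()
  for (window in c(0, 500, 2000, 10000, 50000)) {
    cur <- key(assign_loci_to_genes(loci, genes, window = window))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("co-binding presence composes the 5 kb assignment", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "c", tss = c(1000, 50000),
    strand = c("+", "-"), log2fc = c(1, -1)
  )
  none <- mark_cobinding_presence(genes, tibble::tibble(
    chrom = character(), start = numeric(), end = numeric()
  ))
  expect_equal(none$cobound, c(0L, 0L))

  at_each <- tibble::tibble(chrom = "c", start = c(900, 49900), end = c(1100, 50100))
  expect_equal(mark_cobinding_presence(genes, at_each)$cobound, c(1L, 1L))

  withr::local_seed(36)
  shared <- merge_intervals(rand_intervals(30, contig_len = 100000, max_len = 300))
  many <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40), chrom = "chr1",
    tss = sample.int(100000, 40) - 1, strand = "+", log2fc = rnorm(40)
  )
  got <- mark_cobinding_presence(many, shared, window = 5000)
  want <- vapply(many$tss, function(t) {
    any(vapply(seq_len(nrow(shared)), function(j) {
      bruteforce_tss_distance(t, shared$start[j], shared$end[j]) <= 5000
    }, logical(1)))
  }, logical(1))
  expect_equal(got$cobound, as.integer(want))
})

test_that("the moving average reproduces hand-computed truncated means", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5), log2fc = 5:1, cobound = c(1L, 0L, 1L, 0L, 1L)
  )
  ma <- moving_average_profile(genes, window_genes = 3)
  expect_equal(ma$smoothed, c(0.5, 2 / 3, 1 / 3, 2 / 3, 0.5))

  all1 <- dplyr::mutate(genes, cobound = 1L)
  expect_equal(moving_average_profile(all1, 3)$smoothed, rep(1, 5))
  all0 <- dplyr::mutate(genes, cobound = 0L)
  expect_equal(moving_average_profile(all0, 3)$smoothed, rep(0, 5))

  expect_error(moving_average_profile(genes, 4), "odd")
  expect_error(moving_average_profile(genes, 0), "odd")
})

test_that("the moving average matches the direct definition and is edge-symmetric", {
  withr::local_seed(37)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    w <- sample(c(1, 3, 5, 7, 11), 1)
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:n),
      log2fc = seq(n, 1), # strictly decreasing: ranking is the identity
      cobound = sample(0:1, n, replace = TRUE)
    )
    ma <- moving_average_profile(genes, w)
    expect_equal(ma$smoothed, bruteforce_moving_average(genes$cobound, w))
    # reversing the indicator reverses the profile
    rev_genes <- dplyr::mutate(genes, cobound = rev(cobound))
    expect_equal(
      moving_average_profile(rev_genes, w)$smoothed,
      rev(ma$smoothed)
    )
  }
})

test_that("ties in log2fc rank deterministically by gene_id", {
  genes <- tibble::tibble(
    gene_id = c("b", "a", "c"), log2fc = c(1, 1, 1), cobound = c(1L, 0L, 0L)
  )
  ma <- moving_average_profile(genes, 1)
  expect_equal(ma$gene_id, c("a", "b", "c"))
})

test_that("pileups are flat on uniform and zero tracks", {
  withr::local_seed(38)
  loci <- rand_intervals(10, contig_len = 100000, max_len = 400)
  uniform <- tibble::tibble(chrom = "chr1", start = 0, end = 100000, value = 2.5)
  # keep windows inside the covered region
  loci <- dplyr::filter(loci, start > 5000, end < 95000)
  p <- pileup_profile(loci, uniform, flank = 2000, bin_size = 50)
  expect_equal(nrow(p), 80)
  expect_equal(p$value, rep(2.5, 80))

  zero <- dplyr::mutate(uniform, value = 0)
  expect_equal(pileup_profile(loci, zero)$value, rep(0, 80))

  expect_error(pileup_profile(loci[0, ], uniform), "empty")
  expect_error(pileup_profile(loci, uniform, flank = 2000, bin_size = 33),
    "multiple"
  )
})

test_that("a triangular signal pileup equals per-base brute-force binning", {
  # triangle: coverage ramps 0..99 then back down, one locus at its peak
  ramp <- tibble::tibble(
    chrom = "c",
    start = seq(1000, by = 10, length.out = 200),
    end = seq(1010, by = 10, length.out = 200),
    value = c(seq_len(100), rev(seq_len(100)))
  )
  locus <- tibble::tibble(chrom = "c", start = 1950, end = 2050)
  p <- pileup_profile(locus, ramp, flank = 500, bin_size = 25)
  center <- floor((1950 + 2050) / 2)
  arr <- value_array(ramp, "c", 5000)
  want <- vapply(seq_len(40), function(k) {
    s <- center - 500 + (k - 1) * 25
    mean(arr[(s + 1):(s + 25)])
  }, numeric(1))
  expect_equal(p$value, want, tolerance = 1e-12)
})

test_that("pileup mass is conserved against the brute-force window total", {
  withr::local_seed(39)
  track <- rand_track(40, contig_len = 50000, max_len = 400)
  loci <- rand_intervals(8, contig_len = 50000, max_len = 300)
  loci <- dplyr::filter(loci, start > 3000, end < 47000)
  flank <- 1000
  bin <- 50
  p <- pileup_profile(loci, track, flank = flank, bin_size = bin)
  arr <- value_array(track, "chr1", 50000)
  mass_bf <- sum(vapply(seq_len(nrow(loci)), function(i) {
    ctr <- floor((loci$start[i] + loci$end[i]) / 2)
    sum(arr[(ctr - flank + 1):(ctr + flank)])
  }, numeric(1)))
  expect_equal(sum(p$value * bin * nrow(loci)), mass_bf, tolerance = 1e-9)
})
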