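# Superset construction, density quantification and open/closed calls.

test_that("scale factors invert total read counts", {
  sf <- compute_scale_factor(tibble::tibble(
    library_id = c("a", "b"), total_unique_reads = c(1e7, 2e7)
  ))
  expect_equal(sf$scale_factor, c(1, 0.5))
  expect_error(
    compute_scale_factor(tibble::tibble(library_id = "a", total_unique_reads = 0)),
    "positive"
  )
  withr::local_seed(5)
  totals <- sample.int(5e7, 50)
  sf <- compute_scale_factor(tibble::tibble(
    library_id = as.character(1:50), total_unique_reads = totals
  ))
  expect_equal(sf$scale_factor * totals, rep(1e7, 50), tolerance = 1e-15)
})

test_that("scale_track rescales mass exactly and keeps geometry", {
  withr::local_seed(6)
  tr <- rand_track(10)
  expect_equal(scale_track(tr, 1), tr)
  zero <- dplyr::mutate(tr, value = 0)
  expect_equal(scale_track(zero, 3.7)$value, rep(0, nrow(tr)))
  for (i in 1:30) {
    tr <- rand_track(sample(1:25, 1))
    f <- runif(1, 0.1, 5)
    scaled <- scale_track(tr, f)
    expect_equal(scaled[, 1:3], tr[, 1:3])
    mass <- function(t) sum(t$value * (t$end - t$start))
    expect_equal(mass(scaled), f * mass(tr), tolerance = 1e-12)
  }
})

test_that("the superset is the merged union of per-library peaks", {
  one <- tibble::tibble(chrom = "chr1", start = c(0, 50), end = c(60, 100))
  ss <- build_superset(list(lib = one))
  expect_equal(ss[, 1:3], tibble::tibble(chrom = "chr1", start = 0, end = 100))

  two <- list(
    a = tibble::tibble(chrom = "chr1", start = 100, end = 200),
    b = tibble::tibble(chrom = "chr1", start = 150, end = 250)
  )
  expect_equal(build_superset(two)$start, 100)
  expect_equal(build_superset(two)$end, 250)

  # book-ended peaks merge into one locus
  touching <- list(
    a = tibble::tibble(chrom = "chr1", start = 100, end = 200),
    b = tibble::tibble(chrom = "chr1", start = 200, end = 300)
  )
  expect_equal(nrow(build_superset(touching)), 1)

  expect_error(build_superset(list()), "non-empty")
})

test_that("superset covered bases equal the per-base union on random fixtures", {
  withr::local_seed(8)
  for (i in 1:40) {
    n_lib <- sample(1:4, 1)
    sets <- purrr::map(seq_len(n_lib), ~ rand_intervals(sample(1:50, 1)))
    names(sets) <- paste0("lib", seq_len(n_lib))
    ss <- build_superset(sets)
    expect_equal(
      cover_array(ss, "chr1", 10000),
      Reduce(`|`, purrr::map(sets, cover_array, contig = "chr1", contig_len = 10000))
    )
    # disjoint and sorted
    expect_true(all(diff(ss$start) > 0))
    expect_true(all(ss$start[-1] > ss$end[-nrow(ss)])) # merged book-ends too
  }
})

test_that("superset construction is idempotent and library-order invariant", {
  withr::local_seed(9)
  sets <- purrr::map(1:4, ~ rand_intervals(30))
  names(sets) <- paste0("lib", 1:4)
  ss <- build_superset(sets)
  expect_equal(build_superset(list(again = ss))[, 1:3], ss[, 1:3])
  expect_equal(build_superset(rev(sets))[, 1:3], ss[, 1:3])
})

test_that("density is mean per-base scaled coverage over the locus", {
  loci <- tibble::tibble(chrom = "c", start = 0, end = 10, locus_id = "L1")
  piecewise <- tibble::tibble(
    chrom = "c", start = c(0, 5), end = c(5, 10), value = c(2, 4)
  )
  sm <- quantify_density(loci, list(lib = piecewise))
  expect_equal(sm$density, 3.0)

  zero <- tibble::tibble(chrom = "c", start = 0, end = 10, value = 0)
  expect_equal(quantify_density(loci, list(lib = zero))$density, 0)

  # uniform coverage gives the constant regardless of locus length
  for (len in c(10, 100, 1000)) {
    l <- tibble::tibble(chrom = "c", start = 5, end = 5 + len, locus_id = "L1")
    u <- tibble::tibble(chrom = "c", start = 0, end = 5000, value = 1.7)
    expect_equal(quantify_density(l, list(lib = u))$density, 1.7)
  }
})

test_that("density matches the per-base mean oracle on random tracks", {
  withr::local_seed(10)
  for (i in 1:40) {
    loci <- rand_intervals(sample(1:10, 1)) |> merge_intervals()
    loci$locus_id <- sprintf("L%d", seq_len(nrow(loci)))
    track <- rand_track(sample(1:30, 1))
    sm <- quantify_density(loci, list(x = track))
    want <- purrr::map_dbl(
      seq_len(nrow(loci)),
      ~ bruteforce_density(track, "chr1", loci$start[.x], loci$end[.x], 10000)
    )
    expect_equal(sm$density, want, tolerance = 1e-12)
  }
})

test_that("density is invariant to splitting track intervals into finer pieces", {
  withr::local_seed(12)
  loci <- tibble::tibble(chrom = "c", start = 10, end = 200, locus_id = "L1")
  track <- tibble::tibble(chrom = "c", start = c(0, 100), end = c(100, 300),
    value = c(2, 5)
  )
  split_track <- tibble::tibble(
    chrom = "c",
    start = c(0, 40, 100, 150, 200),
    end = c(40, 100, 150, 200, 300),
    value = c(2, 2, 5, 5, 5)
  )
  expect_equal(
    quantify_density(loci, list(a = track))$density,
    quantify_density(loci, list(a = split_track))$density
  )
})

test_that("a locus on a contig absent from a track scores 0 with a warning", {
  loci <- tibble::tibble(
    chrom = c("c1", "c2"), start = c(0, 0), end = c(10, 10),
    locus_id = c("L1", "L2")
  )
  track <- tibble::tibble(chrom = "c1", start = 0, end = 10, value = 2)
  expect_warning(sm <- quantify_density(loci, list(x = track)), "c2")
  expect_equal(sm$density, c(2, 0))
})

test_that("open calls follow the threshold with equality counting as open", {
  sm <- tibble::tibble(
    locus_id = c("a", "b", "c"),
    density = c(0.20, 0.50, 0.2734),
    library_id = "x"
  )
  om <- call_open(sm, theta = 0.2734)
  expect_equal(om$open, c(FALSE, TRUE, TRUE))
})

test_that("open counts are monotone non-increasing in theta and hit both extremes", {
  withr::local_seed(13)
  sm <- tibble::tibble(
    locus_id = sprintf("L%d", 1:200),
    density = runif(200, 0, 2),
    library_id = "x"
  )
  grid <- seq(0, 2.5, length.out = 50)
  counts <- vapply(grid, function(th) sum(call_open(sm, th)$open), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 200) # theta = 0 with positive signal: all open
  expect_equal(sum(call_open(sm, 1e9)$open), 0)
})

test_that("averaging replicate tracks matches the per-base mean", {
  withr::local_seed(14)
  tracks <- purrr::map(1:3, ~ rand_track(15, contig_len = 2000))
  avg <- average_tracks(tracks)
  want <- Reduce(`+`, purrr::map(tracks, value_array, contig = "chr1",
    contig_len = 2000
  )) / 3
  expect_equal(value_array(avg, "chr1", 2000), want, tolerance = 1e-12)
})
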