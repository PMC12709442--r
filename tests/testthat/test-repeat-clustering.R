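test_that("element readers parse, filter and reject malformed rows", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tL1toy\t0\t+",
               "chr1\t900\t1200\tAluToy\t0\t-",
               "chr2\t50\t400\tL1toy\t0\t+",
               "chr2\t500\t400\tL1toy\t0\t+"), bed)   # last row start >= end
  expect_message(el <- read_elements(bed, "bed"), "rejected 1")
  expect_equal(nrow(el), 3)
  el2 <- read_elements(bed, "bed", subfamily_filter = "L1toy")
  expect_equal(nrow(el2), 2)
  expect_error(read_elements(bed, "bed", subfamily_filter = "nope"),
               "nope")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genoName\tgenoStart\tgenoEnd\trepName",
               "chr1\t100\t600\tL1toy",
               "chr1\t900\t1200\tAluToy",
               "chr2\t50\t400\tL1toy"), tsv)
  el3 <- read_elements(tsv, "rmsk_tsv")
  expect_equal(el3$start, el$start)
  expect_equal(el3$subfamily, el$subfamily)
  expect_equal(el3$center, floor((el3$start + el3$end) / 2))
})

test_that("pairwise distances enumerate within-chromosome pairs only", {
  el <- tibble::tibble(chrom = c("a", "a", "a"), start = c(0, 5, 12),
                       end = c(1, 6, 13), center = c(0, 5, 12))
  expect_setequal(pairwise_distances(el)$distance, c(5, 7, 12))
  el2 <- tibble::tibble(chrom = c("a", "a", "b"), center = c(0, 5, 3),
                        start = 0, end = 1)
  expect_equal(pairwise_distances(el2)$distance, 5)
  el3 <- tibble::tibble(chrom = c("a", "b"), center = c(1, 2),
                        start = 0, end = 1)
  expect_warning(out <- pairwise_distances(el3), "fewer than 2")
  expect_equal(nrow(out), 0)
})

test_that("uniform pairwise density is a proper density matching simulation", {
  L <- 1e6
  expect_equal(uniform_density(L, L), 0)
  expect_equal(uniform_density(0, L), 2 / L)
  expect_error(uniform_density(-1, L))
  expect_error(uniform_density(L + 1, L))
  igr <- integrate(uniform_density, 0, L, L = L, rel.tol = 1e-10)
  expect_equal(igr$value, 1, tolerance = 1e-9)
  # Monte-Carlo oracle: i.i.d. uniform pairs on [0, L]
  set.seed(7)
  d <- abs(runif(2e5, 0, L) - runif(2e5, 0, L))
  h <- log_binned_histogram(d, n_bins = 20)
  cdf <- function(x) (2 * L * x - x^2) / L^2
  p_exp <- cdf(pmin(h$bin_hi, L)) - cdf(h$bin_lo)
  keep <- p_exp * length(d) >= 5
  chi <- sum((h$count[keep] - length(d) * p_exp[keep])^2 /
               (length(d) * p_exp[keep]))
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("log-binned histograms are normalized probability densities", {
  h1 <- log_binned_histogram(c(42), n_bins = 5)
  expect_equal(sum(h1$density * (h1$bin_hi - h1$bin_lo)), 1, tolerance = 1e-12)
  set.seed(8)
  h <- log_binned_histogram(rexp(5000, 1e-4), n_bins = 30)
  expect_equal(sum(h$density * (h$bin_hi - h$bin_lo)), 1, tolerance = 1e-12)
  # zero distances go to the smallest bin
  hz <- log_binned_histogram(c(0, 1, 10, 100), n_bins = 3)
  expect_equal(sum(hz$count), 4)
  expect_error(log_binned_histogram(numeric(0)), "empty")
})

test_that("dbscan_1d matches hand enumeration and the brute-force closure", {
  lab <- dbscan_1d(c(0, 4000, 50000), eps = 10000, min_samples = 2)
  expect_equal(partition_signature(lab), c(1, 1, 0))
  expect_equal(mean(lab > 0), 2 / 3)
  expect_equal(dbscan_1d(c(0, 3e4, 6e4), eps = 1e4), c(0L, 0L, 0L))
  set.seed(9)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    x <- round(runif(n, 0, 2e5))
    eps <- sample(c(3000, 10000, 30000), 1)
    ms <- sample(2:4, 1)
    got <- dbscan_1d(x, eps, ms)
    want <- brute_dbscan(x, eps, ms)
    expect_true(dbscan_equivalent(x, eps, ms, got, want),
                info = paste("n =", n, "eps =", eps, "ms =", ms))
  }
})

test_that("in-cluster fraction of uniform placements matches direct simulation", {
  # oracle: direct simulation of the same placement process
  L <- 1e7; n <- 400; eps <- 1e4
  frac <- function(seed) {
    set.seed(seed)
    x <- sort(runif(n, 0, L))
    mean(c(diff(x) <= eps, FALSE) | c(FALSE, diff(x) <= eps))
  }
  oracle <- vapply(1:200, frac, 0)
  g <- synth_genome("chr1", L)
  got <- vapply(1:20, function(i) {
    el <- synth_uniform_annotations(g, n, 100, seed = 5000 + i)
    mean(cluster_elements(el, eps = eps)$in_cluster)
  }, 0)
  expect_lt(abs(mean(got) - mean(oracle)),
            3 * sqrt(var(oracle) / length(oracle) + var(got) / length(got)))
})

test_that("cluster statistics use element extremes for spans", {
  el <- tibble::tibble(chrom = "a",
                       start = c(1000, 3000, 50000),
                       end = c(1500, 3500, 50500),
                       subfamily = "t") |>
    transpoloop:::add_centers() |>
    cluster_elements(eps = 10000)
  st <- cluster_stats(el)
  expect_equal(st$summary$n_clusters, 1)
  expect_equal(st$clusters$span, 2500)
  expect_equal(st$summary$fraction_in_clusters, 2 / 3)
  # no clusters
  el2 <- tibble::tibble(chrom = "a", start = c(0, 5e5), end = c(100, 5e5 + 100),
                        subfamily = "t") |>
    transpoloop:::add_centers() |> cluster_elements(eps = 1000)
  st2 <- cluster_stats(el2)
  expect_equal(st2$summary$fraction_in_clusters, 0)
  expect_true(is.na(st2$summary$mean_span))
  # everything in one cluster
  el3 <- tibble::tibble(chrom = "a", start = c(0, 500, 1000),
                        end = c(100, 600, 1100), subfamily = "t") |>
    transpoloop:::add_centers() |> cluster_elements(eps = 1000)
  expect_equal(cluster_stats(el3)$summary$fraction_in_clusters, 1)
})

test_that("peak filtering keeps dual-assay or significant peaks", {
  pk <- tibble::tibble(chrom = "a", start = c(0, 100, 200), end = c(50, 150, 250),
                       flag_dnase = c(TRUE, FALSE, FALSE),
                       flag_faire = c(TRUE, FALSE, FALSE),
                       combined_p = c(0.5, 0.005, 0.02))
  kept <- filter_peaks(pk)
  expect_equal(kept$start, c(0, 100))
  expect_error(filter_peaks(tibble::tibble(chrom = "a", start = 1, end = 2)),
               "combined_p")
})

test_that("overlap fraction distinguishes interval and center modes", {
  open <- tibble::tibble(chrom = "a", start = 150, end = 300)
  el <- tibble::tibble(chrom = "a", start = 100, end = 200, subfamily = "t") |>
    transpoloop:::add_centers()
  expect_equal(overlap_fraction(el, open, "interval")$fraction, 1)
  expect_equal(overlap_fraction(el, open, "center")$fraction, 1)  # center 150
  open2 <- tibble::tibble(chrom = "a", start = 190, end = 300)
  expect_equal(overlap_fraction(el, open2, "interval")$fraction, 1)
  expect_equal(overlap_fraction(el, open2, "center")$fraction, 0)
})

test_that("group comparison agrees with a hand-computed U statistic", {
  expect_equal(compare_groups(rep(1, 5), rep(1, 5)), 1)
  expect_lt(compare_groups(1:20, 21:40), 1e-6)
  expect_error(compare_groups(1:2, 1:5), "at least 3")
  set.seed(10)
  for (i in 1:50) {
    a <- round(rnorm(sample(5:20, 1)), 1)
    b <- round(rnorm(sample(5:20, 1), mean = runif(1, -1, 1)), 1)
    expect_equal(compare_groups(a, b), manual_mwu_p(a, b), tolerance = 1e-6)
  }
})

test_that("chromosome exclusion and span helpers behave as configured", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tL1toy\t0\t+",
               "chrX\t900\t1200\tL1toy\t0\t-",
               "chr2\t50\t400\tL1toy\t0\t+"), bed)
  el <- read_elements(bed, "bed", exclude_chroms = "chrX")
  expect_setequal(unique(el$chrom), c("chr1", "chr2"))
  sp <- genomic_span(el)
  expect_equal(sp$span[sp$chrom == "chr1"], 500)
  expect_equal(genomic_span(el, pooled = TRUE), 500 + 350)
})
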