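test_that("radius of gyration matches the pairwise-sum identity", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 2)
  set.seed(50)
  x <- matrix(rnorm(300), 100, 3)
  rg2_pairs <- sum(as.matrix(stats::dist(x))^2) / (2 * 100^2)
  expect_equal(radius_of_gyration(x)^2, rg2_pairs, tolerance = 1e-10)
})

test_that("hill fits recover planted parameters", {
  n <- 0:100
  tr <- tibble::tibble(n_tr = n, rg = hill_curve(n, 3, 7, 8, 50))
  f <- fit_hill(tr, n_total = 100)
  expect_true(f$converged)
  expect_equal(f$r0, 3, tolerance = 0.01)
  expect_equal(f$r_inf, 7, tolerance = 0.01)
  expect_equal(f$n, 8, tolerance = 0.08)
  expect_equal(f$k, 50, tolerance = 0.5)
  # permutation invariance of the data order
  f2 <- fit_hill(tr[sample(nrow(tr)), ], n_total = 100)
  expect_equal(f2$n, f$n, tolerance = 1e-6)
  # noisy recovery: n within 15% on average over seeds
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- tr
    noisy$rg <- noisy$rg + rnorm(101, sd = 0.02 * 4)
    fit_hill(noisy, n_total = 100)$n
  }, 0)
  expect_lt(abs(mean(errs) - 8) / 8, 0.15)
  expect_gt(mean(abs(errs - 8) / 8 < 0.3), 0.9)
})

test_that("linear ramps yield small hill exponents rather than errors", {
  tr <- tibble::tibble(n_tr = 0:50, rg = 2 + 0.05 * (0:50))
  f <- fit_hill(tr, n_total = 50)
  expect_lt(f$n, 2)
  expect_error(fit_hill(tr[1:4, ]), "at least 6")
  td <- tidy(f); gl <- glance(f)
  expect_setequal(td$term, c("r0", "r_inf", "n", "k"))
  expect_equal(gl$n_obs, 51)
})

test_that("alpha_mle hits the boundary cases and the exhaustive grid", {
  # every post-first event adjacent -> estimate 1
  h_adj <- tibble::tibble(site = c(10L, 11L, 12L, 9L, 13L))
  expect_equal(alpha_mle(h_adj, n_total = 50), 1)
  # never adjacent -> estimate 0
  h_non <- tibble::tibble(site = c(10L, 30L, 20L, 40L, 45L))
  expect_equal(alpha_mle(h_non, n_total = 50), 0)
  # exhaustive-grid oracle on random histories
  set.seed(51)
  for (a in c(0.25, 0.5, 0.75)) {
    h <- synth_insertion_history(40, a, n_insertions = 25)
    est <- alpha_mle(h, n_total = 40)
    brute <- brute_alpha_grid(h$site, 40)
    expect_equal(est, brute, tolerance = 2e-4)
  }
  expect_error(alpha_mle(tibble::tibble(site = 1L), n_total = 10),
               "at least 2")
  expect_warning(out <- alpha_mle(c(5L, 2L), n_total = 50, n_first = 1),
                 "undefined")
  expect_true(is.na(out))
})

test_that("alpha_mle recovers the generating alpha across its range", {
  set.seed(52)
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    est <- vapply(1:40, function(i) {
      alpha_mle(synth_insertion_history(100, a, 50), n_total = 100)
    }, 0)
    expect_lt(abs(mean(est) - a), 0.1)
  }
})

test_that("insertion distance metric handles anchors and short histories", {
  h <- tibble::tibble(r_norm = rep(0, 10))
  expect_equal(as.numeric(insertion_distance_metric(h)), 0)
  set.seed(53)
  # insertions uniform on a sphere of radius Rg -> metric 1
  h2 <- tibble::tibble(r_norm = rep(1, 30))
  expect_equal(as.numeric(insertion_distance_metric(h2)), 1)
  h3 <- tibble::tibble(r_norm = runif(12))
  expect_message(out <- insertion_distance_metric(h3, n_first = 30), "12")
  expect_equal(attr(out, "n_used"), 12L)
})

test_that("radial distributions integrate to one per group", {
  d <- tibble::tibble(group = rep(c("native", "transposed"), c(200, 100)),
                      distance = c(abs(rnorm(200)), abs(rnorm(100, 2))))
  rd <- radial_distributions(d, n_bins = 20)
  for (g in unique(rd$group)) {
    sub <- rd[rd$group == g, ]
    expect_equal(sum(sub$density * (sub$bin_hi - sub$bin_lo)), 1,
                 tolerance = 1e-12)
  }
  # all mass at a point lands in a single bin
  d2 <- tibble::tibble(group = "native", distance = rep(1.3, 50))
  rd2 <- radial_distributions(d2, n_bins = 10, r_max = 2)
  expect_equal(sum(rd2$density > 0), 1)
})

test_that("core-shell classification uses 40% of the native bounding radius", {
  p <- tiny_params()
  st <- new_polymer(p)
  n <- p$n_monomers
  st$pos[] <- 0
  st$pos[seq_len(n), 1] <- c(seq(-1, 1, length.out = n - 2), 0, 0)
  st$kind[seq_len(n)] <- 0L
  st$kind[n - 1] <- 1L; st$kind[n] <- 1L
  st$pos[n - 1, ] <- 0            # at the native centroid -> inside
  st$pos[n, ] <- c(5, 0, 0)       # beyond the bounding radius -> outside
  cs <- core_shell_classify(st)
  expect_equal(cs$label[cs$monomer == n - 1], "inside")
  expect_equal(cs$label[cs$monomer == n], "outside")
  st$kind[seq_len(n)] <- 1L
  expect_warning(cs2 <- core_shell_classify(st), "no native")
  expect_true(all(cs2$label == "outside"))
})

test_that("loops carry transposons further from the native core than shells", {
  # alpha = 1 grows a loop reaching far beyond the native core; alpha = 0
  # coats the core in a shell. At equal Ntr the loop run's transposed
  # monomers sit further from the native centroid (relative to the native
  # bounding radius), and in both cases at least as many lie outside the
  # 40% core sphere under looping as under shell growth.
  profile <- function(alpha, seed) {
    set.seed(seed)
    p <- sim_params(n_monomers = 50, eps = 2.0)
    run <- suppressWarnings(
      run_prescribed(p, alpha = alpha, n_insertions = 20,
                     segment_steps = 2000, equil_steps = 25000))
    st <- run$state
    cs <- core_shell_classify(st)
    natives <- which(st$kind[seq_len(st$n_chain)] == 0L)
    ctr <- colMeans(st$pos[natives, , drop = FALSE])
    rb <- max(sqrt(rowSums(
      (st$pos[natives, , drop = FALSE] -
         matrix(ctr, length(natives), 3, byrow = TRUE))^2)))
    c(out = mean(cs$label == "outside"), reach = mean(cs$distance) / rb)
  }
  p1 <- vapply(1:3, function(s) profile(1, 60 + s), c(out = 0, reach = 0))
  p0 <- vapply(1:3, function(s) profile(0, 60 + s), c(out = 0, reach = 0))
  expect_gte(mean(p1["out", ]), mean(p0["out", ]))
  expect_gt(mean(p1["reach", ]), mean(p0["reach", ]))
})

test_that("scan aggregation is replicate-exact and permutation invariant", {
  runs <- tibble::tibble(
    k_t = rep(c(1, 1, 5, 5), each = 3), s_t = rep(c(0.3, 0.7), 6),
    replicate = rep(1:3, 4), seed = 1:12,
    alpha_mle = runif(12), hill_n = runif(12, 1, 10),
    hill_k = runif(12, 10, 40), mean_insert_dist = runif(12),
    n_events = 50L, completed = TRUE)
  agg <- aggregate_scan(runs)
  expect_equal(nrow(agg), 4)
  expect_equal(agg$n_replicates, rep(3L, 4))
  agg2 <- aggregate_scan(runs[sample(nrow(runs)), ])
  expect_equal(dplyr::arrange(as.data.frame(agg), k_t, s_t),
               dplyr::arrange(as.data.frame(agg2), k_t, s_t))
  one <- aggregate_scan(runs[runs$replicate == 1, ])
  expect_true(all(is.na(one$alpha_mle_sd)))
  expect_equal(one$alpha_mle_mean, runs$alpha_mle[runs$replicate == 1])
})

test_that("scenario labels partition the parameter quadrants", {
  cells <- tibble::tibble(k_t = c(0.5, 0.5, 5, 5), s_t = c(0.3, 0.7, 0.3, 0.7))
  lab <- scenario_label(cells)
  expect_equal(as.character(lab$scenario), c("I", "II", "III", "IV"))
  # degenerate thresholds collapse everything into one label
  lab2 <- scenario_label(cells, s_t_threshold = 10, k_t_threshold = 100)
  expect_true(all(lab2$scenario == "I"))
  expect_named(attr(lab, "thresholds"), c("s_t", "k_t"))
})
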