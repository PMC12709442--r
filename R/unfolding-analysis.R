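#' Fit a Hill curve to an unfolding trace
#'
#' Least-squares fit of
#' `Rg(N) = R0 + (Rinf - R0) * N^n / (K^n + N^n)`
#' to a radius-of-gyration trace over the number of transposed monomers.
#' The Hill exponent `n` measures the sharpness of unfolding (large `n`:
#' switch-like; small `n`: gradual) and the half-point `K` the transition
#' position. The fit uses bounded Levenberg-Marquardt
#' (\code{minpack.lm::nlsLM}) with `n` in (0, 50] and `K` in (0, Ntot],
#' multi-started from 5 initializations; the best-residual solution is
#' kept and non-convergence from all starts is reported honestly in the
#' `converged` flag rather than as an error.
#'
#' @param trace A tibble with columns `n_tr` and `rg`, or an
#'   `insertion_run`.
#' @param n_total Chain length bound for `K` (taken from the run if
#'   available, else `max(n_tr)`).
#' @return An object of class `hill_fit` with elements `r0`, `r_inf`,
#'   `n`, `k`, `resid_norm`, `converged`, `fit` (the underlying `nls`
#'   object or `NULL`) and `data`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' tr <- tibble::tibble(n_tr = 0:100,
#'                      rg = 3 + 4 * (0:100)^8 / (50^8 + (0:100)^8))
#' glance(fit_hill(tr))
#' @export
fit_hill <- function(trace, n_total = NULL) {
  if (inherits(trace, "insertion_run")) {
    if (is.null(n_total)) n_total <- trace$pars$n_total
    trace <- trace$trace
  }
  stopifnot(all(c("n_tr", "rg") %in% names(trace)))
  trace <- dplyr::arrange(trace[complete.cases(trace[, c("n_tr", "rg")]), ],
                          .data$n_tr)
  if (nrow(trace) < 6)
    stop("need at least 6 trace points spanning low and high n_tr")
  if (is.null(n_total)) n_total <- max(trace$n_tr)
  lo <- c(r0 = 0, r_inf = 0, n = 1e-3, k = 1e-3)
  hi <- c(r0 = Inf, r_inf = Inf, n = 50, k = n_total)
  r0_0 <- max(min(trace$rg), 1e-6)
  ri_0 <- max(trace$rg)
  k_mid <- max(min(median(trace$n_tr[trace$n_tr > 0]), n_total - 1e-6), 1)
  starts <- list(
    c(n = 1, k = k_mid), c(n = 2, k = k_mid), c(n = 5, k = k_mid),
    c(n = 10, k = k_mid), c(n = 20, k = max(1, 0.5 * k_mid))
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rg ~ r0 + (r_inf - r0) * ifelse(n_tr > 0, n_tr^n / (k^n + n_tr^n), 0),
        data = trace,
        start = list(r0 = r0_0, r_inf = ri_0, n = unname(s["n"]),
                     k = unname(s["k"])),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best)) {
    out <- list(r0 = NA_real_, r_inf = NA_real_, n = NA_real_, k = NA_real_,
                resid_norm = NA_real_, converged = FALSE, fit = NULL,
                data = trace)
  } else {
    cf <- coef(best)
    out <- list(r0 = cf[["r0"]], r_inf = cf[["r_inf"]], n = cf[["n"]],
                k = cf[["k"]], resid_norm = sqrt(deviance(best)),
                converged = isTRUE(best$convInfo$isConv), fit = best,
                data = trace)
  }
  structure(out, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> n =", signif(x$n, 4), " K =", signif(x$k, 4),
      " R0 =", signif(x$r0, 4), " Rinf =", signif(x$r_inf, 4),
      if (!x$converged) " [not converged]", "\n")
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("r0", "r_inf", "n", "k"),
                          estimate = NA_real_, std.error = NA_real_))
  }
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 std.error = unname(sm[, 2]))
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(r0 = x$r0, r_inf = x$r_inf, n = x$n, k = x$k,
                 resid_norm = x$resid_norm, converged = x$converged,
                 n_obs = nrow(x$data))
}

# Internal: per-event likelihood ingredients of the adjacency model,
# reconstructed from the ordered site sequence alone.
history_terms <- function(sites, n_total) {
  kind <- integer(n_total)
  out <- vector("list", length(sites))
  for (t in seq_along(sites)) {
    adj <- adjacent_candidates(kind)
    out[[t]] <- list(is_adj = sites[t] %in% adj, n_adj = length(adj),
                     n_native = sum(kind == 0L))
    kind[sites[t]] <- 1L
  }
  out
}

#' Maximum-likelihood placement adjacency
#'
#' Estimates the adjacency parameter `alpha` that best explains an
#' observed insertion history under the prescribed-adjacency choice rule:
#' each event contributes
#' `alpha * 1(site adjacent) / |A| + (1 - alpha) / |U|`,
#' where `A` is the set of chain-adjacent native candidates and `U` the
#' set of all native sites just before the event. Events with no adjacent
#' candidate (in particular the first insertion) are alpha-independent and
#' drop out. Only the first `n_first` insertions are used (default 50, the
#' window used when characterizing emergent runs). The likelihood is
#' maximized on a 1001-point grid refined by golden-section search.
#'
#' @param x An `insertion_run`, or a tibble/data frame with a `site`
#'   column, or a bare integer vector of sites in insertion order.
#' @param n_total Chain length (required unless `x` is an
#'   `insertion_run`).
#' @param n_first Number of leading insertions used.
#' @return The estimate in `[0, 1]`; `NA` (with a warning) when every
#'   event is alpha-independent.
#' @export
alpha_mle <- function(x, n_total = NULL, n_first = 50) {
  if (inherits(x, "insertion_run")) {
    if (is.null(n_total)) n_total <- x$pars$n_total
    sites <- x$history$site
  } else if (is.data.frame(x)) {
    sites <- x$site
  } else {
    sites <- as.integer(x)
  }
  if (is.null(n_total)) stop("n_total must be supplied")
  if (length(sites) < 2) stop("need at least 2 insertion events")
  sites <- head(sites, n_first)
  terms <- history_terms(sites, n_total)
  inf <- purrr::keep(terms, ~ .x$n_adj > 0L)
  if (length(inf) == 0L) {
    warning("all events are alpha-independent; estimate undefined")
    return(NA_real_)
  }
  a_part <- vapply(inf, function(t) if (t$is_adj) 1 / t$n_adj else 0, 0)
  u_part <- vapply(inf, function(t) 1 / t$n_native, 0)
  loglik <- function(a) sum(log(a * a_part + (1 - a) * u_part))
  grid <- seq(0, 1, length.out = 1001)
  ll <- vapply(grid, loglik, 0)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  if (lo == hi) return(grid[i])
  opt <- optimize(loglik, c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  cand <- c(grid[i], opt$maximum)
  cand[which.max(vapply(cand, loglik, 0))]
}

#' Mean normalized insertion distance
#'
#' Average, over the first `n_first` insertion events, of the distance of
#' the converted monomer from the chromatin center of mass divided by the
#' instantaneous radius of gyration, both evaluated at the insertion
#' frame. Values near 0 indicate insertion in the polymer core, values
#' near or above 1 insertion in the outer shell.
#'
#' @param x An `insertion_run` or a tibble with an `r_norm` column.
#' @param n_first Number of leading events used (default 30).
#' @return The mean normalized distance; attribute `n_used` records how
#'   many events entered (all of them, with a message, when fewer than
#'   `n_first` are available).
#' @export
insertion_distance_metric <- function(x, n_first = 30) {
  h <- if (inherits(x, "insertion_run")) x$history else x
  stopifnot("r_norm" %in% names(h))
  if (nrow(h) == 0L) return(structure(NA_real_, n_used = 0L))
  if (nrow(h) < n_first)
    message("only ", nrow(h), " events available (requested ", n_first, ")")
  r <- head(h$r_norm, n_first)
  structure(mean(r), n_used = length(r))
}

#' Distances of particles from the chromatin center
#'
#' @param state A `polymer_state`.
#' @return Tibble with `group` (`native`/`transposed`/`transposase`) and
#'   `distance` to the center of mass of all chromatin monomers.
#' @export
particle_distances <- function(state) {
  com <- colMeans(state$pos[seq_len(state$n_chain), , drop = FALSE])
  d <- sqrt(rowSums((state$pos - matrix(com, nrow(state$pos), 3,
                                        byrow = TRUE))^2))
  tibble::tibble(group = c("native", "transposed", "transposase")[state$kind + 1L],
                 distance = d)
}

#' Radial distance distributions by particle group
#'
#' Density-normalized histograms of center distances for each particle
#' group (and, if supplied alongside, insertion events). Each group's
#' densities integrate to 1.
#'
#' @param x A `polymer_state`, or a tibble with columns `group` and
#'   `distance` (e.g. [particle_distances()] rows pooled over frames,
#'   possibly augmented with insertion-event distances).
#' @param n_bins Number of equal-width bins (default 30).
#' @param r_max Upper edge of the histogram (default: max distance).
#' @return Tibble with `group`, `bin_lo`, `bin_hi`, `mid`, `density`.
#'   Groups present in the data but empty after filtering are dropped;
#'   the attribute `empty_groups` lists groups with no observations.
#' @export
radial_distributions <- function(x, n_bins = 30, r_max = NULL) {
  d <- if (inherits(x, "polymer_state")) particle_distances(x) else x
  stopifnot(all(c("group", "distance") %in% names(d)))
  groups <- unique(d$group)
  d <- d[is.finite(d$distance), ]
  if (is.null(r_max)) r_max <- max(d$distance)
  edges <- seq(0, max(r_max, .Machine$double.eps), length.out = n_bins + 1)
  w <- diff(edges)
  out <- purrr::map_dfr(unique(d$group), function(g) {
    v <- d$distance[d$group == g]
    v[v >= edges[n_bins + 1]] <- edges[n_bins + 1] - 1e-12
    cnt <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
    tibble::tibble(group = g, bin_lo = edges[-(n_bins + 1)],
                   bin_hi = edges[-1], mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                   density = cnt / (length(v) * w))
  })
  attr(out, "empty_groups") <- setdiff(groups, unique(out$group))
  out
}

#' Core-shell classification of transposed monomers
#'
#' The polymer core is the sphere centered on the centroid of the native
#' monomers with radius 40% of their bounding radius (the maximum native
#' distance from that centroid). Transposed monomers are labelled by
#' membership: a compact core coated by transposons (core-shell
#' configuration) keeps many transposed monomers inside; loops protruding
#' from the core put them outside.
#'
#' @param state A `polymer_state`.
#' @param core_fraction Core radius as a fraction of the native bounding
#'   radius (default 0.4).
#' @return Tibble with one row per transposed monomer: `monomer`,
#'   `distance` (from the native centroid) and `label`
#'   (`"inside"`/`"outside"`). With no native monomers left all are
#'   labelled outside and a warning is raised.
#' @export
core_shell_classify <- function(state, core_fraction = 0.4) {
  chain <- seq_len(state$n_chain)
  natives <- chain[state$kind[chain] == 0L]
  transposed <- chain[state$kind[chain] == 1L]
  if (length(natives) == 0L) {
    warning("no native monomers: core undefined, all labelled outside")
    d <- rep(NA_real_, length(transposed))
    return(tibble::tibble(monomer = transposed, distance = d,
                          label = rep("outside", length(transposed))))
  }
  ctr <- colMeans(state$pos[natives, , drop = FALSE])
  dist_to <- function(ix) sqrt(rowSums(
    (state$pos[ix, , drop = FALSE] - matrix(ctr, length(ix), 3, byrow = TRUE))^2))
  r_core <- core_fraction * max(dist_to(natives))
  d <- dist_to(transposed)
  tibble::tibble(monomer = transposed, distance = d,
                 label = ifelse(d <= r_core, "inside", "outside"))
}

#' Replicated (k_t, s_t) parameter scan of the emergent model
#'
#' Runs the emergent model for every grid cell and replicate, and reduces
#' each run to the summary metrics used throughout: the maximum-likelihood
#' adjacency of the first 50 insertions, the Hill exponent and half-point
#' of the unfolding trace, and the mean normalized distance of the first
#' 30 insertions.
#'
#' @param grid Tibble with columns `k_t` and `s_t`, one row per cell.
#' @param params_fn Function `(s_t) -> sim_params` building the cell's
#'   parameters (the transposase size must enter the physics).
#' @param replicates Replicates per cell (full scale: 25).
#' @param seed Base seed; replicate `r` of cell `i` uses
#'   `seed + 1000 * i + r`.
#' @param alpha_frac,dist_frac Estimator windows as fractions of the
#'   chain length: the adjacency MLE uses the first
#'   `ceiling(alpha_frac * n_total)` insertions and the distance metric
#'   the first `ceiling(dist_frac * n_total)`. The defaults (0.5, 0.3)
#'   reproduce the full-scale windows of 50 and 30 events at
#'   `n_total = 100` and stay meaningful for shorter chains.
#' @param ... Passed to [run_emergent()].
#' @return Tibble with one row per run: cell coordinates, `replicate`,
#'   `seed`, `alpha_mle`, `hill_n`, `hill_k`, `mean_insert_dist`,
#'   `n_events`, `completed`.
#' @export
run_scan <- function(grid, params_fn, replicates = 25, seed = 1,
                     alpha_frac = 0.5, dist_frac = 0.3, ...) {
  stopifnot(all(c("k_t", "s_t") %in% names(grid)))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      run_seed <- seed + 1000L * i + r
      set.seed(run_seed)
      pars <- params_fn(grid$s_t[i])
      run <- run_emergent(pars, k_t = grid$k_t[i], ...)
      hf <- tryCatch(fit_hill(run), error = function(e) NULL)
      n_alpha <- ceiling(alpha_frac * pars$n_monomers)
      n_dist <- ceiling(dist_frac * pars$n_monomers)
      am <- if (nrow(run$history) >= 2)
        suppressWarnings(alpha_mle(run, n_first = n_alpha)) else NA_real_
      tibble::tibble(
        k_t = grid$k_t[i], s_t = grid$s_t[i], replicate = r, seed = run_seed,
        alpha_mle = am,
        hill_n = if (is.null(hf)) NA_real_ else hf$n,
        hill_k = if (is.null(hf)) NA_real_ else hf$k,
        mean_insert_dist = as.numeric(insertion_distance_metric(run, n_first = n_dist)),
        n_events = nrow(run$history),
        completed = nrow(run$history) >= run$pars$n_total)
    })
  })
}

#' Aggregate scan replicates into a grid of cell statistics
#'
#' Per-(k_t, s_t) cell mean and standard deviation of the run metrics,
#' with exact replicate bookkeeping (cells keep the count of completed
#' runs that entered each statistic; single-replicate cells report `NA`
#' standard deviations).
#'
#' @param runs Output of [run_scan()].
#' @return A tibble of class `scan_grid`, one row per cell.
#' @export
aggregate_scan <- function(runs) {
  out <- runs |>
    dplyr::group_by(.data$k_t, .data$s_t) |>
    dplyr::summarise(
      dplyr::across(c("alpha_mle", "hill_n", "hill_k", "mean_insert_dist"),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         sd = ~ if (sum(is.finite(.x)) > 1)
                                  sd(.x, na.rm = TRUE) else NA_real_)),
      n_replicates = dplyr::n(),
      n_completed = sum(.data$completed),
      .groups = "drop")
  class(out) <- c("scan_grid", class(out))
  out
}

#' Scenario labels for scan cells
#'
#' Quadrant assignment of the four unfolding scenarios: transposases that
#' permeate chromatin (small `s_t`) with slow insertion give unclustered,
#' core-shell unfolding (I); size-excluded transposases with slow
#' insertion (II) or permeating transposases with fast insertion (III)
#' unfold via several small loops; size exclusion combined with fast
#' insertion typically yields one prominent loop (IV). Thresholds are
#' configurable and reported alongside the labels; by default they sit at
#' the grid midpoints. Alternatively the quadrants can be assigned on the
#' measured (`alpha_mle`, `hill_n`) plane.
#'
#' @param cells A `scan_grid` (or any tibble with the relevant columns).
#' @param on `"parameters"` (thresholds on `s_t`, `k_t`; default) or
#'   `"estimates"` (thresholds on `alpha_mle_mean` and `hill_n_mean`).
#' @param s_t_threshold,k_t_threshold Parameter-space thresholds
#'   (defaults: midpoints of the observed ranges).
#' @param alpha_threshold,n_threshold Estimate-space thresholds.
#' @return The input with a `scenario` factor column (`I`-`IV`);
#'   thresholds are attached as attribute `thresholds`. Cells with
#'   missing aggregates get `NA`.
#' @export
scenario_label <- function(cells, on = c("parameters", "estimates"),
                           s_t_threshold = NULL, k_t_threshold = NULL,
                           alpha_threshold = NULL, n_threshold = NULL) {
  on <- match.arg(on)
  if (on == "parameters") {
    if (is.null(s_t_threshold))
      s_t_threshold <- mean(range(cells$s_t))
    if (is.null(k_t_threshold))
      k_t_threshold <- mean(range(cells$k_t))
    big <- cells$s_t > s_t_threshold
    fast <- cells$k_t > k_t_threshold
    thr <- c(s_t = s_t_threshold, k_t = k_t_threshold)
  } else {
    a <- cells$alpha_mle_mean; n <- cells$hill_n_mean
    if (is.null(alpha_threshold)) alpha_threshold <- median(a, na.rm = TRUE)
    if (is.null(n_threshold)) n_threshold <- median(n, na.rm = TRUE)
    big <- a > alpha_threshold
    fast <- n <= n_threshold
    thr <- c(alpha = alpha_threshold, n = n_threshold)
  }
  lab <- dplyr::case_when(
    !big & !fast ~ "I", big & !fast ~ "II",
    !big & fast ~ "III", big & fast ~ "IV")
  cells$scenario <- factor(lab, levels = c("I", "II", "III", "IV"))
  attr(cells, "thresholds") <- thr
  cells
}
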