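# Shared fixtures and independent oracles used across the suite.

# Documented toy TRX table (10 complement classes); tests never depend on
# the shipped table's values.
toy_trx <- trx_table(c(AA = 10, AT = 20, AC = 5, AG = 8, CA = 12, CC = 4,
                       CG = 25, GA = 9, GC = 11, TA = 15))

# Brute-force DBSCAN oracle: full pairwise neighborhoods, BFS expansion
# from core points. Returns labels as a partition (noise = 0); cluster
# ids are arbitrary, compare with partition_signature().
brute_dbscan <- function(x, eps, min_samples) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d <- abs(outer(x, x, "-"))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neigh, length, 0L) >= min_samples
  lab <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (k in neigh[[j]]) {
        if (lab[k] == 0L) {
          lab[k] <- cur
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

# Border points (non-core points within eps of cores of several clusters)
# are assignment-ambiguous in DBSCAN; two labelings are equivalent when
# cores and noise agree and every border point joins a cluster with a
# core within eps.
dbscan_equivalent <- function(x, eps, min_samples, lab1, lab2) {
  d <- abs(outer(x, x, "-"))
  n_neigh <- rowSums(d <= eps)
  core <- n_neigh >= min_samples
  if (!identical(partition_signature(lab1[core]),
                 partition_signature(lab2[core]))) return(FALSE)
  for (lab in list(lab1, lab2)) {
    for (i in which(!core)) {
      if (lab[i] == 0L) {
        if (any(core & d[i, ] <= eps)) return(FALSE)  # should be border
      } else {
        ok <- any(core & lab == lab[i] & d[i, ] <= eps)
        if (!ok) return(FALSE)
      }
    }
  }
  TRUE
}

# Canonical form of a labelling: noise stays 0, clusters renumbered by
# first appearance, so two labelings are comparable.
partition_signature <- function(lab) {
  ids <- unique(lab[lab != 0L])
  match(lab, ids, nomatch = 0L)
}

# Hand-computed Mann-Whitney U two-sided p (midranks, normal
# approximation with tie correction and continuity correction) --
# independent of stats::wilcox.test.
manual_mwu_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
}

# Independent log-likelihood of an insertion history under the adjacency
# model, reconstructed step by step (used to cross-check alpha_mle by
# exhaustive grid maximization).
brute_alpha_loglik <- function(sites, n_total, alpha) {
  kind <- integer(n_total)
  ll <- 0
  for (s in sites) {
    nat <- which(kind == 0L)
    adj <- nat[vapply(nat, function(i) {
      (i > 1 && kind[i - 1] == 1L) || (i < n_total && kind[i + 1] == 1L)
    }, TRUE)]
    p <- if (length(adj) == 0L) 1 / length(nat)
         else alpha * (s %in% adj) / length(adj) + (1 - alpha) / length(nat)
    ll <- ll + log(p)
    kind[s] <- 1L
  }
  ll
}

brute_alpha_grid <- function(sites, n_total, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(a) brute_alpha_loglik(sites, n_total, a), 0)
  grid[which.max(ll)]
}

# Small, fast simulation parameter set for engine tests.
tiny_params <- function(...) sim_params(n_monomers = 20, r_bound = 10, ...)

# Evaluate the Hill curve (independent of fit_hill internals).
hill_curve <- function(n, r0, r_inf, hn, k) {
  ifelse(n > 0, r0 + (r_inf - r0) * n^hn / (k^hn + n^hn), r0)
}
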