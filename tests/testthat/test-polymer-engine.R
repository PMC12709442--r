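test_that("pair potentials match their closed forms at anchor points", {
  expect_equal(wca_energy(2^(1/6)), 0)
  expect_equal(wca_energy(1), 1)          # LJ zero + shift
  expect_equal(wca_energy(1.5), 0)        # beyond cutoff
  expect_error(wca_energy(0), "positive")
  expect_equal(attractive_lj_energy(2.5, eps = 1.5), 0)
  # minimum of the shifted attraction: -0.9837 eps at 2^(1/6) sigma
  rr <- seq(0.9, 2.5, by = 1e-4)
  u <- attractive_lj_energy(rr, eps = 1.5)
  expect_equal(min(u), -0.9837 * 1.5, tolerance = 1e-3)
  expect_equal(rr[which.min(u)], 2^(1/6), tolerance = 1e-3)
  expect_equal(bond_energy(1), 0)
  expect_equal(bend_energy(0), 0)
  expect_equal(bend_energy(pi / 2, kappa = 3), 3)
})

test_that("pair cutoffs implement size-based transposase exclusion", {
  expect_equal(pair_cutoff("monomer", "monomer"), 2^(1/6))
  expect_equal(pair_cutoff("monomer", "transposase", s_t = 0.5),
               2^(1/6) * 0.5)
  expect_lt(pair_cutoff("monomer", "transposase", s_t = 0.5),
            pair_cutoff("monomer", "monomer"))
  expect_equal(pair_cutoff("transposase", "transposase", s_t = 1),
               pair_cutoff("monomer", "monomer"))
  s <- c(0.3, 0.6, 0.9)
  expect_true(all(diff(pair_cutoff("monomer", "transposase", s_t = s)) > 0))
  expect_error(pair_cutoff("monomer", "widget"), "types")
})

test_that("engine forces are exact negative gradients of the energy", {
  set.seed(20)
  p <- tiny_params(n_transposase = 3, s_t = 0.6)
  st <- new_polymer(p, include_transposases = TRUE)
  # spread out hard overlaps: near-coincident beads make the energy so
  # large that finite differences lose precision to cancellation
  st <- soft_pushoff(st, p)
  for (soft_amp in c(0, 25)) {
    ep <- transpoloop:::engine_par(p, soft = soft_amp > 0)
    f <- transpoloop:::cpp_forces(st$pos, st$kind, ep, soft_amp)
    h <- 1e-6
    for (i in sample(nrow(st$pos), 5)) for (d in 1:3) {
      xp <- st$pos; xp[i, d] <- xp[i, d] + h
      xm <- st$pos; xm[i, d] <- xm[i, d] - h
      fd <- -(transpoloop:::cpp_energy(xp, st$kind, ep, soft_amp) -
                transpoloop:::cpp_energy(xm, st$kind, ep, soft_amp)) / (2 * h)
      expect_equal(f[i, d], fd, tolerance = 1e-5)
    }
  }
})

test_that("integrator limits: ballistic motion and symplectic energy behavior", {
  p <- tiny_params(gamma = 0, temperature = 0)
  st <- new_polymer(p)
  st$vel[] <- 0.3
  before <- st$pos
  st2 <- run_dynamics(st, p, 50, pairs_on = FALSE, bond_on = FALSE,
                      bend_on = FALSE, confine = FALSE, thermostat = FALSE)
  expect_equal(st2$pos, before + 50 * p$dt * 0.3, tolerance = 1e-12)

  # two-bead harmonic oscillator without thermostat: velocity Verlet is
  # symplectic, so the energy oscillates within a bounded band of order
  # (omega dt)^2 but shows no secular drift
  p2 <- sim_params(n_monomers = 2, gamma = 0, temperature = 0, r_bound = 10)
  st <- new_polymer(p2)
  st$pos <- matrix(c(0, 0, 0, 1.05, 0, 0), 2, 3, byrow = TRUE)
  st$vel <- matrix(0, 2, 3)
  st <- run_dynamics(st, p2, 10000, sample_every = 10, pairs_on = FALSE,
                     bend_on = FALSE, confine = FALSE, thermostat = FALSE)
  s <- attr(st, "samples")
  etot <- s$e_pot + 1.5 * 2 * s$t_kin  # KE = (3N/2) T_kin
  m <- length(etot)
  drift <- abs(mean(tail(etot, m %/% 10)) - mean(head(etot, m %/% 10)))
  expect_lt(drift / abs(mean(etot)), 1e-4)
  expect_lt(max(abs(etot - mean(etot))) / abs(mean(etot)), 0.02)
})

test_that("thermostatted dynamics equilibrate to the target temperature", {
  set.seed(21)
  p <- sim_params(n_monomers = 100, r_bound = 30)
  st <- new_polymer(p)
  st$pos <- matrix(rnorm(300) * 5, 100, 3)
  st <- run_dynamics(st, p, 30000, sample_every = 30, pairs_on = FALSE,
                     bond_on = FALSE, bend_on = FALSE, confine = FALSE)
  expect_equal(mean(attr(st, "samples")$t_kin), 1, tolerance = 0.05)
})

test_that("bond lengths satisfy equipartition in a bonds-only chain", {
  set.seed(22)
  p <- tiny_params(k_bond = 200)
  st <- new_polymer(p)
  st <- run_dynamics(st, p, 5000, pairs_on = FALSE, bend_on = FALSE)
  st <- run_dynamics(st, p, 40000, sample_every = 100, collect_frames = TRUE,
                     pairs_on = FALSE, bend_on = FALSE)
  frames <- attr(st, "samples")$frames
  bl <- unlist(lapply(frames, function(f) {
    sqrt(rowSums(diff(f[seq_len(p$n_monomers), ])^2))
  }))
  expect_equal(var(bl), 1 / p$k_bond, tolerance = 0.2)
})

test_that("soft push-off separates coincident beads", {
  set.seed(23)
  p <- tiny_params()
  st <- new_polymer(p)
  st$pos[2, ] <- st$pos[1, ]  # coincident pair
  st <- soft_pushoff(st, p)
  ratio <- transpoloop:::cpp_min_sep_ratio(st$pos, st$kind,
                                           transpoloop:::engine_par(p))
  expect_gte(ratio, 0.8)  # >= 0.9 sigma for monomer pairs
})

test_that("equilibration is seed-reproducible", {
  p <- tiny_params()
  set.seed(24); a <- suppressWarnings(prepare_polymer(p, equil_steps = 3000))
  set.seed(24); b <- suppressWarnings(prepare_polymer(p, equil_steps = 3000))
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
})

test_that("the reflecting sphere confines particles and preserves uniformity", {
  set.seed(25)
  p <- sim_params(n_monomers = 2, r_bound = 5, gamma = 0.5)
  st <- new_polymer(p)
  n <- 200
  st$pos <- matrix(rnorm(3 * n, sd = 1), n, 3)
  st$vel <- matrix(rnorm(3 * n), n, 3)
  st$kind <- rep(0L, n); st$mass <- rep(1, n); st$n_chain <- n
  st <- run_dynamics(st, p, 20000, sample_every = 100, collect_frames = TRUE,
                     pairs_on = FALSE, bond_on = FALSE, bend_on = FALSE)
  frames <- attr(st, "samples")$frames
  r <- unlist(lapply(frames, function(f) sqrt(rowSums(f^2))))
  expect_lte(max(r), 5)
  # ideal gas in a sphere: P(r <= q) = (q/R)^3; check the median radius
  tail_r <- r[seq(length(r) / 2, length(r))]
  expect_equal(mean(tail_r <= 5 * 0.5^(1/3)), 0.5,
               tolerance = 3 * 0.5 / sqrt(length(tail_r) / 200))
  # explicit reflection rule: outward radial velocity is reversed
  st2 <- st
  st2$pos[1, ] <- c(4.999, 0, 0); st2$vel[1, ] <- c(2, 0, 0)
  st2 <- run_dynamics(st2, p, 1, pairs_on = FALSE, bond_on = FALSE,
                      bend_on = FALSE, thermostat = FALSE)
  expect_lte(sqrt(sum(st2$pos[1, ]^2)), 5)
  expect_lt(st2$vel[1, 1], 0)
})

test_that("native attraction collapses the chain relative to the repulsive coil", {
  rg <- vapply(1:3, function(s) {
    set.seed(30 + s)
    st <- prepare_polymer(sim_params(n_monomers = 50), equil_steps = 25000,
                          check = FALSE)
    radius_of_gyration(st)
  }, 0)
  rg0 <- vapply(1:3, function(s) {
    set.seed(30 + s)
    st <- prepare_polymer(sim_params(n_monomers = 50, eps = 0),
                          equil_steps = 25000, check = FALSE)
    radius_of_gyration(st)
  }, 0)
  expect_lt(mean(rg), 0.7 * mean(rg0))
})

test_that("xyz and tsv trajectory exports round-trip their contents", {
  set.seed(26)
  p <- tiny_params(n_transposase = 2)
  st <- new_polymer(p, include_transposases = TRUE)
  st$kind[3] <- 1L
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(list(st, st), path)
  lines <- readLines(path)
  n <- nrow(st$pos)
  expect_length(lines, 2 * (n + 2))
  expect_equal(as.integer(lines[1]), n)
  expect_match(lines[2], "n_tr=1")
  first_atom <- strsplit(lines[3], " ")[[1]]
  expect_equal(first_atom[1], "N")
  expect_equal(as.numeric(first_atom[2:4]), st$pos[1, ], tolerance = 1e-5)
  expect_equal(substr(lines[3 + 2], 1, 1), "T")   # monomer 3 transposed
  expect_equal(substr(lines[n + 2], 1, 1), "P")  # last atom row of frame 1

  run <- structure(list(model = "prescribed",
                        trace = tibble::tibble(n_tr = 0:3, rg = 1:4),
                        history = tibble::tibble(event = 1L, site = 2L),
                        state = st, pars = list()),
                   class = "insertion_run")
  stem <- withr::local_tempfile()
  paths <- write_trace(run, stem)
  back <- utils::read.table(paths[1], header = TRUE, sep = "\t")
  expect_equal(back$rg, 1:4)
})
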