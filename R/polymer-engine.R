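#' Simulation parameters for the chromatin polymer model
#'
#' Assembles the full parameter set of the coarse-grained chromatin domain.
#' The chain has `n_monomers` beads of diameter `sigma` (the reduced length
#' unit), each representing `bp_per_monomer` basepairs of chromatin;
#' `sigma_nm` records the physical size of one bead so results can be
#' reported in nanometers. Native monomers attract each other with well
#' depth ~`eps` (shifted-truncated Lennard-Jones, cutoff 2.5 sigma);
#' transposed monomers and transposases are purely repulsive
#' (Weeks-Chandler-Andersen). Bending rigidity `kappa` (Kratky-Porod
#' potential) sets the persistence length, approximately `kappa` bonds for
#' stiff chains. Transposases have effective diameter `s_t * sigma`; the
#' monomer-transposase repulsion cutoff is `2^(1/6) * s_t * sigma`, smaller
#' than the mean pair diameter, so smaller transposases can approach
#' monomers more closely (size-based exclusion from dense chromatin).
#'
#' @param n_monomers Chain length `Ntot` (default 100, a 300-kb domain).
#' @param sigma_nm Physical monomer diameter in nanometers (default 30).
#' @param bp_per_monomer Basepairs of chromatin per bead (default 3000).
#' @param eps Native-native attraction strength in kBT (default 1.5).
#' @param kappa Kratky-Porod bending constant in kBT (default 3, giving a
#'   persistence length of ~3 bonds = 90 nm).
#' @param k_bond Harmonic bond constant in kBT/sigma^2 (default 200).
#' @param dt Integration timestep in reduced time units (default 0.01).
#' @param gamma Langevin damping rate in 1/tau (default 1).
#' @param temperature Thermostat temperature in kBT (default 1).
#' @param s_t Transposase size factor relative to a monomer (default 0.5).
#' @param n_transposase Number of explicit transposase particles (default 20).
#' @param r_bound Radius of the spherical reflecting boundary in sigma;
#'   `NULL` picks `max(15, n_monomers / (2*pi))` so the fully stretched
#'   chain fits inside.
#' @param seed Optional integer seed recorded with the parameters.
#' @return A list of class `sim_params`.
#' @examples
#' p <- sim_params(n_monomers = 50)
#' packing_density_bp_per_nm(p)
#' @export
sim_params <- function(n_monomers = 100, sigma_nm = 30, bp_per_monomer = 3000,
                       eps = 1.5, kappa = 3, k_bond = 200, dt = 0.01,
                       gamma = 1, temperature = 1, s_t = 0.5,
                       n_transposase = 20, r_bound = NULL, seed = NULL) {
  stopifnot(n_monomers >= 2, eps >= 0, kappa >= 0, s_t > 0, dt > 0,
            k_bond > 0, gamma >= 0, temperature >= 0, n_transposase >= 0)
  if (is.null(r_bound)) r_bound <- max(15, n_monomers / (2 * pi))
  if (r_bound < n_monomers / (2 * pi))
    stop("r_bound too small to contain the chain: need at least ",
         round(n_monomers / (2 * pi), 2), " sigma")
  structure(list(
    n_monomers = as.integer(n_monomers), sigma_nm = sigma_nm,
    bp_per_monomer = bp_per_monomer, eps = eps, kappa = kappa,
    k_bond = k_bond, dt = dt, gamma = gamma, temperature = temperature,
    s_t = s_t, n_transposase = as.integer(n_transposase),
    r_bound = r_bound, seed = seed
  ), class = "sim_params")
}

#' Implied chromatin packing density
#'
#' Linear packing density of the coarse-grained fiber: basepairs per bead
#' divided by the bead diameter in nanometers. With the defaults (3 kb per
#' 30-nm bead) this is 100 bp/nm, within the experimentally estimated
#' 90-130 bp/nm range for interphase chromatin.
#'
#' @param params A [sim_params()] object.
#' @return Packing density in basepairs per nanometer.
#' @export
packing_density_bp_per_nm <- function(params = sim_params()) {
  params$bp_per_monomer / params$sigma_nm
}

#' Pair potentials of the polymer model
#'
#' `wca_energy()` is the purely repulsive Weeks-Chandler-Andersen potential:
#' the Lennard-Jones potential shifted up by `eps_rep` and truncated at its
#' zero-crossing minimum `2^(1/6) * d_eff`. `attractive_lj_energy()` is the
#' shifted-truncated Lennard-Jones attraction applied to native-native
#' monomer pairs only, truncated at `2.5 * sigma` and shifted so the energy
#' is continuous (zero) at the cutoff; its minimum is about `-0.9837 * eps`
#' at `2^(1/6) * sigma`. `bond_energy()` and `bend_energy()` are the
#' harmonic spring between adjacent chain beads and the Kratky-Porod
#' bending energy `kappa * (1 - cos(theta))` between successive bonds.
#'
#' @param r Pair distance(s), reduced units; must be positive.
#' @param d_eff Effective pair diameter (repulsion length scale).
#' @param eps_rep Repulsion energy scale in kBT.
#' @param sigma Monomer diameter.
#' @param eps Attraction strength in kBT.
#' @param k_bond Bond spring constant; `r0` the rest length.
#' @param r0 Bond rest length.
#' @param theta Angle between successive bond vectors, radians.
#' @param kappa Bending constant in kBT.
#' @return Energy in kBT, vectorized over `r` (or `theta`).
#' @examples
#' wca_energy(2^(1/6))            # 0 at the cutoff
#' attractive_lj_energy(2^(1/6))  # close to -0.984 * 1.5
#' @export
wca_energy <- function(r, d_eff = 1, eps_rep = 1) {
  if (any(r <= 0)) stop("pair distance must be positive")
  rc <- 2^(1/6) * d_eff
  sr6 <- (d_eff / r)^6
  ifelse(r < rc, 4 * eps_rep * (sr6^2 - sr6) + eps_rep, 0)
}

#' @rdname wca_energy
#' @export
attractive_lj_energy <- function(r, sigma = 1, eps = 1.5) {
  if (any(r <= 0)) stop("pair distance must be positive")
  lj <- function(x) { s6 <- (sigma / x)^6; 4 * eps * (s6^2 - s6) }
  ifelse(r < 2.5 * sigma, lj(r) - lj(2.5 * sigma), 0)
}

#' @rdname wca_energy
#' @export
bond_energy <- function(r, k_bond = 200, r0 = 1) {
  if (any(r <= 0)) stop("bond length must be positive")
  0.5 * k_bond * (r - r0)^2
}

#' @rdname wca_energy
#' @export
bend_energy <- function(theta, kappa = 3) kappa * (1 - cos(theta))

#' Effective repulsion cutoff for a particle pair
#'
#' Monomer-monomer pairs repel with cutoff `2^(1/6) * sigma`. Any pair
#' involving a transposase (transposase-transposase or
#' monomer-transposase) uses `2^(1/6) * s_t * sigma`: for `s_t < 1` this is
#' smaller than the mean pair diameter, letting small transposases slip
#' closer to monomers than monomers can to each other.
#'
#' @param type_a,type_b `"monomer"` or `"transposase"` (vectorized).
#' @param sigma Monomer diameter.
#' @param s_t Transposase size factor.
#' @return Repulsion cutoff distance(s).
#' @export
pair_cutoff <- function(type_a, type_b, sigma = 1, s_t = 1) {
  ok <- c("monomer", "transposase")
  if (!all(type_a %in% ok) || !all(type_b %in% ok))
    stop("types must be 'monomer' or 'transposase'")
  both_mono <- type_a == "monomer" & type_b == "monomer"
  2^(1/6) * sigma * ifelse(both_mono, 1, s_t)
}

# Internal: parameter list handed to the C++ core. Overrides switch terms
# on/off for calibration runs (bonds-only, no attraction, soft phase, ...).
engine_par <- function(params, ...) {
  over <- list(...)
  base <- list(
    sigma = 1, eps_attr = params$eps, eps_rep = 1, kappa = params$kappa,
    kbond = params$k_bond, r0 = 1, dt = params$dt, gamma = params$gamma,
    temp = params$temperature, sT = params$s_t, rbound = params$r_bound,
    attract_on = TRUE, pairs_on = TRUE, bend_on = TRUE, bond_on = TRUE,
    thermostat = TRUE, confine = TRUE, soft = FALSE,
    soft_a0 = 0, soft_a1 = 0, nchain = params$n_monomers
  )
  base[names(over)] <- over
  base
}

transposase_mass <- function(s_t) max(s_t^3, 0.5)

#' Create a fresh polymer state
#'
#' Initializes the chain as a random walk with bond length sigma (overlaps
#' allowed; they are resolved by [soft_pushoff()]) and places
#' `n_transposase` transposase particles uniformly on the bounding sphere.
#' Velocities are drawn from the Maxwell-Boltzmann distribution at the
#' thermostat temperature.
#'
#' @param params A [sim_params()] object.
#' @param include_transposases Place explicit transposase particles
#'   (default `FALSE`; the prescribed-adjacency model needs none).
#' @return A list of class `polymer_state` with elements `pos`, `vel`
#'   (n x 3 matrices), `kind` (0 native, 1 transposed, 2 transposase),
#'   `n_chain`, `mass` and `steps` (elapsed timesteps).
#' @export
new_polymer <- function(params, include_transposases = FALSE) {
  n <- params$n_monomers
  nt <- if (include_transposases) params$n_transposase else 0L
  pos <- matrix(0, n + nt, 3)
  lim <- 0.8 * params$r_bound
  for (i in seq_len(n - 1)) {
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pos[i, ] + u
      if (sqrt(sum(cand^2)) < lim) break
    }
    pos[i + 1, ] <- cand
  }
  if (nt > 0) {
    u <- matrix(rnorm(3 * nt), nt, 3)
    u <- u / sqrt(rowSums(u^2))
    pos[n + seq_len(nt), ] <- u * params$r_bound * 0.999
  }
  kind <- c(rep(0L, n), rep(2L, nt))
  mass <- c(rep(1, n), rep(transposase_mass(params$s_t), nt))
  vel <- matrix(rnorm((n + nt) * 3, sd = sqrt(params$temperature / rep(mass, 3))),
                n + nt, 3)
  structure(list(pos = pos, vel = vel, kind = kind, n_chain = n,
                 mass = mass, steps = 0L),
            class = "polymer_state")
}

#' @export
print.polymer_state <- function(x, ...) {
  cat("<polymer_state> ", x$n_chain, " chain monomers (",
      sum(x$kind == 1L), " transposed), ",
      sum(x$kind == 2L), " transposases, ", x$steps, " steps elapsed\n",
      sep = "")
  invisible(x)
}

#' Tidy view of a polymer state
#'
#' @param x A `polymer_state`.
#' @param ... Unused.
#' @return A tibble with one row per particle: `particle`, `kind`
#'   (`native` / `transposed` / `transposase`), positions and velocities.
#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.polymer_state <- function(x, ...) {
  tibble::tibble(
    particle = seq_len(nrow(x$pos)),
    kind = c("native", "transposed", "transposase")[x$kind + 1L],
    x = x$pos[, 1], y = x$pos[, 2], z = x$pos[, 3],
    vx = x$vel[, 1], vy = x$vel[, 2], vz = x$vel[, 3]
  )
}

#' Advance the dynamics
#'
#' Runs `n_steps` of BAOAB Langevin velocity-Verlet integration. With the
#' thermostat off (`thermostat = FALSE` and `gamma = 0` in the parameters)
#' the scheme reduces to plain velocity Verlet and conserves energy.
#'
#' @param state A `polymer_state`.
#' @param params A [sim_params()] object.
#' @param n_steps Number of timesteps.
#' @param sample_every Record radius of gyration, kinetic temperature and
#'   potential energy every this many steps (0 = no sampling).
#' @param collect_frames Also keep position snapshots at each sample.
#' @param ... Engine overrides (e.g. `attract_on = FALSE`,
#'   `thermostat = FALSE`, `pairs_on = FALSE`, `confine = FALSE`).
#' @return The updated state; samples are attached as attribute
#'   `"samples"` (list with `rg`, `t_kin`, `e_pot`, `frames`).
#' @export
run_dynamics <- function(state, params, n_steps, sample_every = 0,
                         collect_frames = FALSE, ...) {
  ep <- engine_par(params, ...)
  out <- cpp_run(state$pos, state$vel, state$kind, state$mass, ep,
                 as.integer(n_steps), as.integer(sample_every),
                 collect_frames)
  state$pos <- out$pos
  state$vel <- out$vel
  state$steps <- state$steps + as.integer(n_steps)
  attr(state, "samples") <- list(rg = out$rg, t_kin = out$t_kin,
                                 e_pot = out$e_pot, frames = out$frames)
  state
}

#' Soft push-off phase
#'
#' Replaces all pair interactions by a bounded cosine soft-core potential
#' whose amplitude is ramped from 0 to `a_max`, gently separating the
#' overlapping beads of a freshly drawn random-walk chain, then settles
#' briefly on the full repulsive potential. Errors if hard overlaps
#' persist after the ramp.
#'
#' @param state,params State and parameters.
#' @param n_steps Ramp length in timesteps (default 3000).
#' @param a_max Final soft amplitude in kBT (default 60).
#' @param min_sep Required minimum pair separation after the phase, as a
#'   fraction of each pair's repulsion cutoff (default 0.8, i.e. about
#'   0.9 sigma for monomer pairs; separations below this sit several kBT
#'   up the repulsive wall and indicate unresolved overlaps rather than
#'   thermal fluctuation).
#' @return The pushed-off state.
#' @export
soft_pushoff <- function(state, params, n_steps = 3000, a_max = 60,
                         min_sep = 0.8) {
  state <- run_dynamics(state, params, n_steps, soft = TRUE,
                        soft_a0 = 0, soft_a1 = a_max, bend_on = FALSE)
  state <- run_dynamics(state, params, 500, attract_on = FALSE)
  ratio <- cpp_min_sep_ratio(state$pos, state$kind, engine_par(params))
  if (ratio < min_sep)
    stop("overlaps persist after soft push-off (min separation ",
         round(ratio, 3), " of cutoff); increase n_steps or a_max")
  state
}

#' Equilibration phase
#'
#' Runs the full potential until the chain has relaxed. When `check` is
#' `TRUE`, the radius of gyration sampled over the run is tested for a
#' residual trend (slope t-test on the last half); a significant trend at
#' the 95% level triggers a warning suggesting a longer equilibration.
#'
#' @param state,params State and parameters.
#' @param n_steps Equilibration length (default 20000).
#' @param sample_every Sampling stride for the stationarity check.
#' @param check Perform the stationarity check (default TRUE).
#' @param ... Engine overrides passed to [run_dynamics()].
#' @return The equilibrated state.
#' @export
equilibrate <- function(state, params, n_steps = 20000, sample_every = 100,
                        check = TRUE, ...) {
  state <- run_dynamics(state, params, n_steps, sample_every = sample_every, ...)
  if (check) {
    rg <- attr(state, "samples")$rg
    half <- rg[seq(floor(length(rg) / 2) + 1, length(rg))]
    if (length(half) >= 10 && sd(half) > 0) {
      fit <- lm(half ~ seq_along(half))
      p <- summary(fit)$coefficients[2, 4]
      if (p < 0.05)
        warning("radius of gyration still trending after equilibration ",
                "(slope p = ", signif(p, 3), "); consider more steps")
    }
  }
  state
}

#' Prepare an equilibrated polymer
#'
#' Convenience wrapper: fresh chain, soft push-off, then equilibration.
#'
#' @inheritParams new_polymer
#' @param equil_steps Equilibration length.
#' @param ... Passed to [equilibrate()].
#' @return An equilibrated `polymer_state`.
#' @export
prepare_polymer <- function(params, include_transposases = FALSE,
                            equil_steps = 20000, ...) {
  state <- new_polymer(params, include_transposases = include_transposases)
  state <- soft_pushoff(state, params)
  equilibrate(state, params, n_steps = equil_steps, ...)
}

#' Radius of gyration
#'
#' Root-mean-square distance of chain monomers from their centroid.
#' Equivalent (and tested against) the pair-sum identity
#' `Rg^2 = sum_ij |ri - rj|^2 / (2 N^2)`.
#'
#' @param x An n x 3 position matrix, or a `polymer_state` (in which case
#'   only chromatin monomers are used; transposases are excluded).
#' @return Radius of gyration (reduced units).
#' @export
radius_of_gyration <- function(x) {
  if (inherits(x, "polymer_state")) x <- x$pos[seq_len(x$n_chain), , drop = FALSE]
  x <- as.matrix(x)
  ctr <- colMeans(x)
  sqrt(mean(rowSums((x - matrix(ctr, nrow(x), 3, byrow = TRUE))^2)))
}

#' Persistence length from tangent correlations
#'
#' Equilibrates a chain with the native-native attraction disabled (purely
#' repulsive excluded volume plus bending rigidity), then measures the
#' bond tangent-tangent correlation `C(s) = <t_i . t_{i+s}>` over bond
#' separations `1..max_sep` and fits `log C(s) = -s / lp`. The persistence
#' length is reported in bonds and in nanometers (`lp * sigma_nm`).
#'
#' @param params A [sim_params()] object; the attraction is switched off
#'   internally regardless of `params$eps`.
#' @param seeds Integer seeds; one independent run per seed.
#' @param equil_steps,prod_steps Equilibration and production lengths.
#' @param sample_every Frame stride during production.
#' @param max_sep Largest bond separation used in the fit (default 5).
#' @return A tibble with one row per seed: `seed`, `lp_bonds`, `lp_nm`.
#' @export
persistence_length <- function(params = sim_params(), seeds = 1:5,
                               equil_steps = 20000, prod_steps = 40000,
                               sample_every = 200, max_sep = 5) {
  purrr::map_dfr(seeds, function(sd) {
    set.seed(sd)
    state <- new_polymer(params)
    state <- soft_pushoff(state, params)
    state <- run_dynamics(state, params, equil_steps, attract_on = FALSE)
    state <- run_dynamics(state, params, prod_steps, attract_on = FALSE,
                          sample_every = sample_every, collect_frames = TRUE)
    frames <- attr(state, "samples")$frames
    cs <- tangent_correlation(frames, params$n_monomers, max_sep)
    fit <- lm(log(cs) ~ 0 + seq_len(max_sep))
    lp <- -1 / coef(fit)[[1]]
    tibble::tibble(seed = sd, lp_bonds = lp, lp_nm = lp * params$sigma_nm)
  })
}

# Mean tangent-tangent correlation over frames for separations 1..max_sep.
tangent_correlation <- function(frames, n_chain, max_sep = 5) {
  acc <- numeric(max_sep)
  cnt <- numeric(max_sep)
  for (f in frames) {
    b <- diff(f[seq_len(n_chain), , drop = FALSE])
    b <- b / sqrt(rowSums(b^2))
    nb <- nrow(b)
    for (s in seq_len(max_sep)) {
      d <- rowSums(b[seq_len(nb - s), , drop = FALSE] *
                   b[seq_len(nb - s) + s, , drop = FALSE])
      acc[s] <- acc[s] + sum(d)
      cnt[s] <- cnt[s] + length(d)
    }
  }
  acc / cnt
}
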