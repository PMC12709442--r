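#' Chain-adjacent insertion candidates
#'
#' Native monomers with at least one transposed chain neighbour (positions
#' `i - 1` or `i + 1`; chain ends have a single neighbour). These are the
#' sites an adjacency-biased insertion can pick.
#'
#' @param kind Integer vector over the chain: 0 = native, 1 = transposed.
#' @return Integer vector of candidate monomer indices (1-based).
#' @export
adjacent_candidates <- function(kind) {
  n <- length(kind)
  if (n == 0L) return(integer(0))
  transposed <- kind == 1L
  left <- c(FALSE, transposed[-n])
  right <- c(transposed[-1], FALSE)
  which(kind == 0L & (left | right))
}

#' Choose the next insertion site under prescribed adjacency
#'
#' With probability `alpha` the site is drawn uniformly from the
#' chain-adjacent candidates (falling back to a uniform draw over all
#' native sites when no transposed monomer exists yet); otherwise it is
#' drawn uniformly over all native sites. The choice depends only on the
#' chain types, never on the spatial configuration.
#'
#' @param kind Integer type vector (0 native, 1 transposed).
#' @param alpha Placement adjacency probability in `[0, 1]`.
#' @return The chosen monomer index.
#' @export
choose_insertion_prescribed <- function(kind, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  native <- which(kind == 0L)
  if (length(native) == 0L) stop("no native monomer left: simulation complete")
  adj <- adjacent_candidates(kind)
  pool <- if (runif(1) < alpha && length(adj) > 0L) adj else native
  pool[sample.int(length(pool), 1L)]
}

#' Timesteps per simulation segment in the emergent model
#'
#' Insertion is attempted every `1000 / k_t` timesteps, so the insertion
#' rate `k_t` sets the segment length: `k_t = 10` gives 100-step segments,
#' `k_t = 0.1` gives 10,000-step segments.
#'
#' @param k_t Insertion rate (attempts per 1000 timesteps); must be > 0.
#' @return Integer number of timesteps.
#' @export
segment_length <- function(k_t) {
  if (any(k_t <= 0)) stop("k_t must be positive")
  as.integer(round(1000 / k_t))
}

#' Capture radius of the transposase insertion reaction
#'
#' The default `"contact"` rule uses the monomer-transposase contact
#' distance `(1 + s_t) * sigma / 2`; the alternative `"sum"` rule uses
#' `(1 + s_t) * sigma`.
#'
#' @param s_t Transposase size factor.
#' @param rule `"contact"` (default) or `"sum"`.
#' @param sigma Monomer diameter.
#' @return Capture radius.
#' @export
capture_radius <- function(s_t, rule = c("contact", "sum"), sigma = 1) {
  rule <- match.arg(rule)
  if (rule == "contact") (1 + s_t) * sigma / 2 else (1 + s_t) * sigma
}

#' Detect transposase captures
#'
#' Finds native monomer / transposase pairs closer than the capture
#' radius and resolves them into a one-to-one matching: pairs are accepted
#' greedily by increasing distance, ties broken by lower monomer index,
#' so each transposase converts at most one monomer and each monomer is
#' converted by at most one transposase. Distinct transposases may convert
#' distinct monomers in the same insertion phase.
#'
#' @param state A `polymer_state` containing transposases.
#' @param params A [sim_params()] object.
#' @param rule Capture-radius rule, see [capture_radius()].
#' @return A tibble with columns `monomer`, `transposase` (indices into
#'   the state's particle list) and `distance`; zero rows if nothing is
#'   captured.
#' @export
detect_captures <- function(state, params, rule = c("contact", "sum")) {
  radius <- capture_radius(params$s_t, rule)
  natives <- which(state$kind == 0L)
  tps <- which(state$kind == 2L)
  empty <- tibble::tibble(monomer = integer(0), transposase = integer(0),
                          distance = numeric(0))
  if (length(natives) == 0L || length(tps) == 0L) return(empty)
  pn <- state$pos[natives, , drop = FALSE]
  pt <- state$pos[tps, , drop = FALSE]
  d2 <- outer(rowSums(pn^2), rowSums(pt^2), "+") - 2 * pn %*% t(pt)
  d2[d2 < 0] <- 0
  hits <- which(d2 < radius^2, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty)
  cand <- tibble::tibble(
    monomer = natives[hits[, 1]],
    transposase = tps[hits[, 2]],
    distance = sqrt(d2[hits])
  )
  cand <- cand[order(cand$distance, cand$monomer, cand$transposase), ]
  used_m <- integer(0); used_t <- integer(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$monomer[i] %in% used_m || cand$transposase[i] %in% used_t) next
    keep[i] <- TRUE
    used_m <- c(used_m, cand$monomer[i])
    used_t <- c(used_t, cand$transposase[i])
  }
  cand[keep, ]
}

#' Convert captured monomers and recycle their transposases
#'
#' Captured native monomers become transposed (type change only; positions
#' and velocities are untouched). The involved transposases are removed
#' and the same number of fresh transposases is added uniformly on the
#' bounding sphere with Maxwell-Boltzmann velocities, conserving the total
#' transposase count.
#'
#' @param state A `polymer_state`.
#' @param params A [sim_params()] object.
#' @param captured Tibble from [detect_captures()].
#' @return The updated state.
#' @export
recycle_transposases <- function(state, params, captured) {
  if (nrow(captured) == 0L) return(state)
  state$kind[captured$monomer] <- 1L
  k <- nrow(captured)
  u <- matrix(rnorm(3 * k), k, 3)
  u <- u / sqrt(rowSums(u^2))
  state$pos[captured$transposase, ] <- u * params$r_bound * 0.999
  m <- transposase_mass(params$s_t)
  state$vel[captured$transposase, ] <-
    matrix(rnorm(3 * k, sd = sqrt(params$temperature / m)), k, 3)
  state
}

# Internal: record one insertion event from the current configuration.
insertion_event <- function(state, site, event, step) {
  chain <- state$pos[seq_len(state$n_chain), , drop = FALSE]
  com <- colMeans(chain)
  rg <- radius_of_gyration(chain)
  d <- sqrt(sum((state$pos[site, ] - com)^2))
  tibble::tibble(event = event, site = site, step = step,
                 r_center = d, rg = rg, r_norm = d / rg)
}

# Internal: mean Rg over the final `tail_frac` of a segment's samples.
segment_tail_rg <- function(state, tail_frac = 0.2) {
  rg <- attr(state, "samples")$rg
  mean(tail(rg, max(1L, ceiling(length(rg) * tail_frac))))
}

new_insertion_run <- function(model, history, trace, state, pars) {
  structure(list(model = model, history = history, trace = trace,
                 state = state, pars = pars),
            class = "insertion_run")
}

#' @export
print.insertion_run <- function(x, ...) {
  cat("<insertion_run> model=", x$model, ", ", nrow(x$history),
      " insertions, final Rg=", round(tail(x$trace$rg, 1), 3), " sigma\n",
      sep = "")
  invisible(x)
}

#' Run the prescribed-adjacency insertion model
#'
#' Starting from an equilibrated all-native chain, transposons are
#' inserted one per segment at fixed intervals: the main block consists of
#' `n_insertions + 1` segments of `segment_steps` timesteps, with an
#' insertion executed at the end of each segment but the last. The site is
#' chosen by [choose_insertion_prescribed()]; conversion changes only the
#' monomer type. The unfolding trace records, for each number of
#' transposed monomers `Ntr`, the mean radius of gyration over the final
#' 20% of the corresponding segment.
#'
#' @param params A [sim_params()] object.
#' @param alpha Placement adjacency in `[0, 1]`.
#' @param n_insertions Number of insertions (default: all monomers).
#' @param segment_steps Timesteps per segment (full scale 100,000;
#'   scaled-down studies use 10,000).
#' @param sample_every Sampling stride within a segment.
#' @param equil_steps Equilibration length before the main block.
#' @param state Optionally, a pre-equilibrated `polymer_state` to reuse.
#' @return An `insertion_run`: list with `history` (tibble of events:
#'   `event`, `site`, `step`, `r_center`, `rg`, `r_norm`), `trace`
#'   (tibble `n_tr`, `rg`), the final `state` and the run parameters.
#' @export
run_prescribed <- function(params, alpha, n_insertions = params$n_monomers,
                           segment_steps = 100000,
                           sample_every = max(1L, segment_steps %/% 100),
                           equil_steps = 20000, state = NULL) {
  stopifnot(n_insertions <= params$n_monomers)
  if (is.null(state)) state <- prepare_polymer(params, equil_steps = equil_steps)
  history <- vector("list", n_insertions)
  trace <- tibble::tibble(n_tr = integer(0), rg = numeric(0))
  for (k in 0:n_insertions) {
    state <- run_dynamics(state, params, segment_steps,
                          sample_every = sample_every)
    trace <- dplyr::bind_rows(trace,
      tibble::tibble(n_tr = k, rg = segment_tail_rg(state)))
    if (k < n_insertions) {
      site <- choose_insertion_prescribed(state$kind[seq_len(state$n_chain)],
                                          alpha)
      history[[k + 1L]] <- insertion_event(state, site, k + 1L, state$steps)
      state$kind[site] <- 1L
    }
  }
  new_insertion_run("prescribed", dplyr::bind_rows(history), trace, state,
                    list(alpha = alpha, n_total = params$n_monomers,
                         segment_steps = segment_steps))
}

#' Run the emergent transposase-mediated insertion model
#'
#' Explicit transposase particles diffuse in from the boundary of the
#' simulation volume; after every segment of `segment_length(k_t)`
#' timesteps, native monomers within the capture radius of a transposase
#' are converted ([detect_captures()]) and the spent transposases are
#' recycled to the boundary ([recycle_transposases()]). The insertion
#' history therefore emerges from transposase-chromatin interactions in
#' space. The run stops when all monomers are transposed, when
#' `max_events` insertions have occurred, or after `max_segments`
#' segments.
#'
#' @param params A [sim_params()] object (its `s_t` sets both the
#'   transposase repulsion range and the capture radius).
#' @param k_t Insertion rate; see [segment_length()].
#' @param max_steps Cap on total main-block timesteps; translated into a
#'   segment cap so cells with short segments get proportionally more
#'   insertion attempts (default 2e6).
#' @param max_segments Hard cap on the number of segments (default:
#'   derived from `max_steps`).
#' @param max_events Event cap (default: chain length).
#' @param rule Capture-radius rule, see [capture_radius()].
#' @param patience Warn (once) if no capture occurs for this many
#'   consecutive segments (default 200); dynamics may simply be slow.
#' @param equil_steps Equilibration length before the main block.
#' @param state Optionally a pre-equilibrated state with transposases.
#' @return An `insertion_run` (see [run_prescribed()]); the trace holds
#'   the mean tail Rg of the segments at each distinct `Ntr`.
#' @export
run_emergent <- function(params, k_t, max_steps = 2e6, max_segments = NULL,
                         max_events = params$n_monomers,
                         rule = c("contact", "sum"), patience = 200,
                         equil_steps = 20000, state = NULL) {
  rule <- match.arg(rule)
  seg <- segment_length(k_t)
  if (is.null(max_segments)) max_segments <- ceiling(max_steps / seg)
  sample_every <- max(1L, seg %/% 20)
  if (is.null(state))
    state <- prepare_polymer(params, include_transposases = TRUE,
                             equil_steps = equil_steps)
  history <- list()
  raw <- list()
  n_event <- 0L
  dry <- 0L
  warned <- FALSE
  for (s in seq_len(max_segments)) {
    state <- run_dynamics(state, params, seg, sample_every = sample_every)
    raw[[s]] <- tibble::tibble(n_tr = sum(state$kind == 1L),
                               rg = segment_tail_rg(state))
    cap <- detect_captures(state, params, rule)
    if (nrow(cap) > 0L) {
      dry <- 0L
      for (i in seq_len(nrow(cap))) {
        n_event <- n_event + 1L
        history[[n_event]] <- insertion_event(state, cap$monomer[i],
                                              n_event, state$steps)
      }
      state <- recycle_transposases(state, params, cap)
    } else {
      dry <- dry + 1L
      if (dry >= patience && !warned) {
        warning("no capture for ", patience, " consecutive segments ",
                "(s_t = ", params$s_t, ", k_t = ", k_t, ")")
        warned <- TRUE
      }
    }
    if (n_event >= max_events || all(state$kind[seq_len(state$n_chain)] == 1L))
      break
  }
  trace <- dplyr::bind_rows(raw) |>
    dplyr::group_by(.data$n_tr) |>
    dplyr::summarise(rg = mean(.data$rg), .groups = "drop") |>
    dplyr::arrange(.data$n_tr)
  new_insertion_run("emergent", dplyr::bind_rows(history), trace, state,
                    list(k_t = k_t, s_t = params$s_t,
                         n_total = params$n_monomers,
                         n_transposase = params$n_transposase, rule = rule))
}
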