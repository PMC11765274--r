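#' Logarithmic logging grid
#'
#' Log-spaced time points (default 20 per decade) with forced points merged
#' in, for recording `N(t)` during the chemical stage.
#'
#' @param t_start,t_end range, ps.
#' @param per_decade log points per decade.
#' @param forced extra times that must be present exactly.
#' @return sorted unique numeric vector within `[t_start, t_end]`.
#' @export
log_time_grid <- function(t_start = 1, t_end = 1e6, per_decade = 20,
                          forced = numeric(0)) {
  n <- ceiling(log10(t_end / t_start) * per_decade)
  g <- t_start * 10^(seq(0, log10(t_end / t_start), length.out = max(n, 2)))
  forced <- sort(unique(c(forced, t_start, t_end)))
  forced <- forced[forced >= t_start - 1e-9 & forced <= t_end + 1e-9]
  # forced points win over floating near-duplicates from the 10^log10 grid
  near <- vapply(g, function(v) any(abs(v - forced) <= 1e-9 * max(1, v)),
                 logical(1))
  g <- sort(c(g[!near], forced))
  g[g >= t_start - 1e-9 & g <= t_end + 1e-9]
}

#' Simulation tables bundle
#'
#' Convenience container for the configuration tables consumed by the
#' multi-track runners.
#'
#' @param species a [species_table()].
#' @param reactions a [reaction_table()].
#' @param branching a [branching_table()].
#' @param radial a [radial_profile()].
#' @param schedule a [timestep_schedule()].
#' @param mean_event_energy mean energy per primary event, eV.
#' @param jitter product placement jitter, nm.
#' @return a named list of validated tables.
#' @export
sim_tables <- function(species = default_species(),
                       reactions = default_reactions(species),
                       branching = default_branching(species),
                       radial = radial_profile(),
                       schedule = timestep_schedule(),
                       mean_event_energy = 62.5,
                       jitter = 0) {
  list(species = species, reactions = reactions, branching = branching,
       radial = radial, schedule = schedule,
       mean_event_energy = mean_event_energy, jitter = jitter)
}

#' Number of replicate simulations for a target energy deposition
#'
#' Replicates are chosen so that the ensemble deposits a target total energy
#' in the scoring volume (default 2 MeV):
#' `count = ceiling(target / (LET x depth x 1000))`.
#'
#' @param target_energy target total deposition, eV.
#' @param spec a [particle_spec()].
#' @return integer replicate count (>= 1).
#' @export
replicate_count <- function(target_energy = 2e6, spec) {
  as.integer(max(1, ceiling(target_energy / (spec$let * spec$depth * 1000))))
}

#' Evolve a pair of tracks separated by dx and dt
#'
#' Track 1 is generated at `(+dx/2, 0)` and track 2 at `(-dx/2, 0)`, both
#' along +z.  Both 1-ps inventories are sampled up front (the physical and
#' prechemical stages of the delayed track are independent of the first),
#' but track 2 is frozen -- inactive, invisible to counts and to `E(t)` --
#' until the global clock reaches the delay `dt` (clamped to no earlier than
#' the 1-ps chemical-stage start).  At activation the timestep schedule is
#' reset to its minimum to resolve the fast kinetics of the fresh track,
#' `E(t)` steps up by the second track's energy, and the two populations
#' react freely with each other until `dt + t_chem` (1 us by default after
#' the second arrival).
#'
#' @param particle a [particle_spec()].
#' @param dx transverse separation, nm (>= 0).
#' @param dt_delay arrival delay of track 2, ps (>= 0).
#' @param tables a [sim_tables()] bundle.
#' @param seed integer seed (expanded into per-track and per-phase streams).
#' @param t_chem chemical evolution time after the second arrival, ps.
#' @param per_decade log points per decade for the output grid.
#' @param extra_log extra forced log times, ps.
#' @return a `pair_run`: list with `gseries` (data frame `time_ps, species,
#'   N, E_eV, G`), per-track energies `E1`, `E2`, per-species counts
#'   `n1_at_act` (track-1 survivors at activation) and `n2_at_1ps`, the
#'   activation time `t_act`, the final `state`, and the reaction log.
#' @export
run_pair <- function(particle, dx, dt_delay, tables = sim_tables(),
                     seed = 1L, t_chem = 1e6, per_decade = 20,
                     extra_log = numeric(0)) {
  if (dx < 0 || dt_delay < 0) stop("`dx` and `dt_delay` must be >= 0")
  sp <- tables$species
  inv1 <- generate_track(particle, tables$branching, sp, tables$radial,
                         tables$mean_event_energy, origin = c(dx / 2, 0),
                         seed = derive_seed(seed, 11, 1), track_id = 1L)
  inv2 <- generate_track(particle, tables$branching, sp, tables$radial,
                         tables$mean_event_energy, origin = c(-dx / 2, 0),
                         seed = derive_seed(seed, 11, 2), track_id = 2L)
  E1 <- attr(inv1, "energy_eV"); E2 <- attr(inv2, "energy_eV")
  n2_at_1ps <- setNames(as.integer(table(factor(inv2$species,
                                                levels = sp$species))),
                        sp$species)
  t_act <- max(dt_delay, 1)  # activation never precedes the chemical stage
  t_end <- t_act + t_chem
  logs <- log_time_grid(1, t_end, per_decade,
                        forced = c(t_act, t_act + t_chem, extra_log))

  both_from_start <- t_act <= 1 + 1e-9
  state <- simulation_state(list(inv1, inv2),
                            active = c(TRUE, both_from_start),
                            time = 1, species = sp)
  if (both_from_start) {
    n1_at_act <- setNames(as.integer(table(factor(inv1$species,
                                                  levels = sp$species))),
                          sp$species)
    res <- evolve(state, t_end, logs, tables$schedule, tables$reactions, sp,
                  seed = derive_seed(seed, 12, 1), sched_origin = 1,
                  jitter = tables$jitter)
    counts <- res$counts
    state <- res$state
  } else {
    res1 <- evolve(state, t_act, logs[logs < t_act - 1e-9], tables$schedule,
                   tables$reactions, sp, seed = derive_seed(seed, 12, 1),
                   sched_origin = 1, jitter = tables$jitter)
    state <- res1$state
    n1_at_act <- state_counts(state, sp)
    # activation: unfreeze track 2, E(t) steps up, schedule clock resets
    state$molecules$active <- TRUE
    state$energy <- rbind(state$energy,
                          data.frame(time_ps = t_act, E_eV = E2))
    res2 <- evolve(state, t_end, logs[logs >= t_act - 1e-9], tables$schedule,
                   tables$reactions, sp, seed = derive_seed(seed, 12, 2),
                   sched_origin = t_act, jitter = tables$jitter)
    state <- res2$state
    counts <- rbind(res1$counts, res2$counts)
    counts <- counts[order(counts$species, counts$time_ps), ]
  }
  gs <- counts
  gs$G <- ifelse(gs$E_eV > 0, gs$N / gs$E_eV * 100, 0)
  rownames(gs) <- NULL
  structure(list(gseries = gs, E1 = E1, E2 = E2,
                 n1_at_act = n1_at_act, n2_at_1ps = n2_at_1ps,
                 t_act = t_act, dx = dx, dt_delay = dt_delay,
                 state = state, rlog = state$rlog,
                 inv = list(inv1, inv2)),
            class = "pair_run")
}

#' Evolve the non-interacting (NI) two-track reference
#'
#' The two tracks are processed entirely independently (the dx -> infinity
#' limit): each single track is evolved alone from 1 ps to `t_chem +
#' dt_delay`, and the NI G-value series combines them,
#' `G_NI(t) = (N1(t) + N2(t)) / (E1 + E2) x 100`, each track at its own
#' chemical age.
#'
#' @inheritParams run_pair
#' @return an `ni_run`: list with the combined `gseries`, `E1`, `E2` and the
#'   two single-track series.
#' @export
run_ni <- function(particle, dt_delay, tables = sim_tables(), seed = 1L,
                   t_chem = 1e6, per_decade = 20, extra_log = numeric(0)) {
  sp <- tables$species
  t_end <- t_chem + max(dt_delay, 0)
  logs <- log_time_grid(1, t_end, per_decade,
                        forced = c(t_chem, extra_log))
  one <- function(tid) {
    inv <- generate_track(particle, tables$branching, sp, tables$radial,
                          tables$mean_event_energy, origin = c(0, 0),
                          seed = derive_seed(seed, 11, tid), track_id = tid)
    st <- simulation_state(list(inv), active = TRUE, time = 1, species = sp)
    res <- evolve(st, t_end, logs, tables$schedule, tables$reactions, sp,
                  seed = derive_seed(seed, 12, tid), sched_origin = 1,
                  jitter = tables$jitter)
    list(E = attr(inv, "energy_eV"), counts = res$counts, state = res$state)
  }
  r1 <- one(1L); r2 <- one(2L)
  gs <- r1$counts
  gs$N <- r1$counts$N + r2$counts$N
  gs$E_eV <- r1$E + r2$E
  gs$G <- ifelse(gs$E_eV > 0, gs$N / gs$E_eV * 100, 0)
  structure(list(gseries = gs, E1 = r1$E, E2 = r2$E,
                 track1 = r1, track2 = r2, dt_delay = dt_delay),
            class = "ni_run")
}

#' Read a G-value series at a target time
#'
#' Returns the value at the nearest logged time at or before the target (no
#' interpolation).
#'
#' @param gseries data frame `(time_ps, species, N, E_eV, G)`.
#' @param time target time, ps.
#' @param value column to read (default `"G"`).
#' @return named vector (by species).
#' @export
g_at <- function(gseries, time, value = "G") {
  tol <- 1e-9 * max(1, abs(time))
  tt <- sort(unique(gseries$time_ps))
  tt <- tt[tt <= time + tol]
  if (length(tt) == 0) stop("no logged time at or before ", time)
  sub <- gseries[abs(gseries$time_ps - max(tt)) <= tol, ]
  setNames(sub[[value]], sub$species)
}

#' NI reference G-value at 1 us after the second arrival
#'
#' The pair run is read out at `t_chem + dt` where the first track has
#' chemical age `t_chem + dt` but the second only `t_chem`; the matching NI
#' reference is the mean `(G_NI(t_chem + dt) + G_NI(t_chem)) / 2`.
#'
#' @param ni an `ni_run` (or its `gseries`).
#' @param dt_delay the pair's arrival delay, ps.
#' @param t_chem chemical time after the second arrival, ps (default 1 us).
#' @return named per-species vector.
#' @export
ni_reference <- function(ni, dt_delay, t_chem = 1e6) {
  gs <- if (inherits(ni, "ni_run")) ni$gseries else ni
  (g_at(gs, t_chem + dt_delay) + g_at(gs, t_chem)) / 2
}
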