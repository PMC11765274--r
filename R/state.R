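#' Adaptive timestep schedule
#'
#' Piecewise-constant mapping from elapsed chemical time (since the stage
#' start or since the last reset) to the step length, bounded by
#' `dt_min = 0.1 ps` (1e-13 s) and `dt_max = 10 ps` (1e-11 s).  The default
#' grows one decade of dt per decade of elapsed time: 0.1 ps below 1 ns,
#' 1 ps below 10 ns, then 10 ps.  On the arrival of a delayed track the
#' elapsed clock is reset so the fast early kinetics of the new track are
#' sampled at `dt_min` again.
#'
#' @param breaks upper edges (ps) of the elapsed-time bins; the last entry
#'   may be `Inf`.
#' @param dts step length (ps) in each bin; must be non-decreasing and
#'   within `[dt_min, dt_max]`.
#' @param dt_min,dt_max hard bounds on the step, ps.
#' @return a `timestep_schedule`.
#' @export
timestep_schedule <- function(breaks = c(1e3, 1e4, Inf),
                              dts = c(0.1, 1, 10),
                              dt_min = 0.1, dt_max = 10) {
  if (length(breaks) != length(dts))
    stop("`breaks` and `dts` must have the same length")
  if (is.unsorted(breaks)) stop("`breaks` must be increasing")
  if (is.unsorted(dts)) stop("`dts` must be non-decreasing between resets")
  if (any(dts < dt_min - 1e-12) || any(dts > dt_max + 1e-12))
    stop("steps must lie within [", dt_min, ", ", dt_max, "] ps")
  structure(list(breaks = breaks, dts = dts,
                 dt_min = dt_min, dt_max = dt_max),
            class = "timestep_schedule")
}

schedule_dt <- function(schedule, elapsed) {
  # dt of bin i applies while elapsed < breaks[i]
  i <- findInterval(elapsed, schedule$breaks) + 1L
  schedule$dts[pmin(i, length(schedule$dts))]
}

#' Assemble a simulation state from species inventories
#'
#' The state carries the time-stamped molecule set (species, position,
#' parent track, active flag, creation time), the deposited-energy step
#' function `E(t)` and cumulative produced/consumed counters.  Inactive
#' molecules (a delayed track before arrival) never move, react, or appear
#' in counts.
#'
#' @param inventories list of `species_inventory` objects (see
#'   [generate_track()]).
#' @param active logical, one per inventory: whether its molecules are
#'   reactive from the start.
#' @param time start time, ps (default 1, the chemical-stage start).
#' @param species a [species_table()].
#' @return a `sim_state`.
#' @export
simulation_state <- function(inventories, active = TRUE, time = 1,
                             species = default_species()) {
  if (inherits(inventories, "species_inventory"))
    inventories <- list(inventories)
  active <- rep_len(active, length(inventories))
  mols <- do.call(rbind, lapply(seq_along(inventories), function(i) {
    inv <- inventories[[i]]
    data.frame(species = inv$species, x_nm = inv$x_nm, y_nm = inv$y_nm,
               z_nm = inv$z_nm, track_id = inv$track_id,
               active = active[i], created = attr(inv, "time_ps"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(mols))
    mols <- data.frame(species = character(0), x_nm = numeric(0),
                       y_nm = numeric(0), z_nm = numeric(0),
                       track_id = integer(0), active = logical(0),
                       created = numeric(0), stringsAsFactors = FALSE)
  species_index(mols$species, species)
  e_active <- sum(vapply(inventories[active], attr, numeric(1), "energy_eV"))
  energy <- data.frame(time_ps = time, E_eV = e_active)
  counters <- data.frame(species = species$species,
                         produced = 0L, consumed = 0L,
                         stringsAsFactors = FALSE)
  structure(list(time = time, molecules = mols, energy = energy,
                 counters = counters,
                 rlog = NULL, n_steps = 0L),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %g ps, %d molecules (%d active), E = %g eV\n",
              x$time, nrow(x$molecules), sum(x$molecules$active),
              state_energy(x, x$time)))
  print(table(x$molecules$species[x$molecules$active]))
  invisible(x)
}

# E(t): deposited energy visible to the G-value at time t (step function)
state_energy <- function(state, t) {
  e <- state$energy
  vapply(t, function(ti) sum(e$E_eV[e$time_ps <= ti + 1e-9]), numeric(1))
}

# counts of alive & active molecules per species
state_counts <- function(state, species = default_species()) {
  m <- state$molecules
  tab <- table(factor(m$species[m$active], levels = species$species))
  setNames(as.integer(tab), species$species)
}

#' Brownian diffusion over one step
#'
#' Every active molecule takes independent Gaussian displacements per axis
#' with standard deviation `sqrt(2 D dt)`; inactive molecules do not move.
#'
#' @param state a `sim_state`.
#' @param dt step, ps (>= 0).
#' @param species a [species_table()].
#' @param seed integer seed.
#' @param box periodic cube edge in nm, or `NULL` for open boundaries.
#' @return the updated state (time unchanged; [step_state()] advances time).
#' @export
diffuse <- function(state, dt, species = default_species(), seed = 1L,
                    box = NULL) {
  if (dt < 0) stop("`dt` must be >= 0")
  m <- state$molecules
  if (nrow(m) == 0 || dt == 0) return(state)
  res <- cpp_diffuse(as.matrix(m[, c("x_nm", "y_nm", "z_nm")]),
                     as.integer(species_index(m$species, species)),
                     m$active, species$D_nm2_ps, dt,
                     if (is.null(box)) -1 else box, as.numeric(seed))
  m[, c("x_nm", "y_nm", "z_nm")] <- res$pos
  state$molecules <- m
  state
}

#' Reaction pass over one step
#'
#' All active-pair distances are checked against the reaction radius of the
#' channel for their species pair; candidate pairs are processed in
#' increasing-distance order and each molecule is consumed at most once per
#' step.  A reacting pair is replaced by its products at the pair midpoint
#' (optionally jittered); the reaction log and the produced/consumed
#' counters are updated.
#'
#' @param state a `sim_state`.
#' @param dt the step length the pass belongs to, ps (used by the
#'   Brownian-bridge acceptance when `bridge = TRUE`).
#' @param reactions a [reaction_table()].
#' @param species a [species_table()].
#' @param seed integer seed.
#' @param jitter product placement jitter (per-axis Gaussian sd, nm).
#' @param box periodic cube edge (nm) or `NULL`.
#' @param bridge apply the Brownian-bridge geminate-recombination
#'   correction for pairs ending outside the radius.  With `FALSE` (and in
#'   any single [react()] call on static positions) the check is the plain
#'   endpoint distance criterion.
#' @return the updated state.
#' @export
react <- function(state, dt, reactions = default_reactions(),
                  species = default_species(), seed = 1L, jitter = 0,
                  box = NULL, bridge = FALSE) {
  m <- state$molecules
  if (nrow(m) == 0) return(state)
  res <- cpp_react(as.matrix(m[, c("x_nm", "y_nm", "z_nm")]),
                   as.integer(species_index(m$species, species)),
                   as.integer(m$track_id), m$active, m$created,
                   species$D_nm2_ps, compile_channels(reactions, species),
                   dt, state$time, jitter,
                   if (is.null(box)) -1 else box, as.numeric(seed), bridge)
  merge_engine_result(state, res, reactions, species)
}

merge_engine_result <- function(state, res, reactions, species) {
  st <- res$state
  state$molecules <- data.frame(
    species = species$species[st$species],
    x_nm = st$pos[, 1], y_nm = st$pos[, 2], z_nm = st$pos[, 3],
    track_id = st$track, active = st$active, created = st$created,
    stringsAsFactors = FALSE)
  state$counters$produced <- state$counters$produced + res$produced
  state$counters$consumed <- state$counters$consumed + res$consumed
  if (length(res$rlog$time_ps) > 0) {
    lg <- as.data.frame(res$rlog)
    lg$channel <- reactions$name[lg$channel + 1L]
    lg$h2o <- reactions$h2o[match(lg$channel, reactions$name)]
    state$rlog <- rbind(state$rlog, lg)
  }
  state
}

#' One step of the chemical stage: diffuse, then react, then advance time
#'
#' @inheritParams react
#' @param schedule a [timestep_schedule()]; the step length is taken from it
#'   at the current elapsed time.
#' @param sched_origin time (ps) of the last schedule reset.
#' @return the updated state, with `time` advanced by the step taken.
#' @export
step_state <- function(state, schedule = timestep_schedule(),
                       reactions = default_reactions(),
                       species = default_species(), seed = 1L,
                       sched_origin = 1, jitter = 0, box = NULL,
                       bridge = TRUE) {
  dt <- schedule_dt(schedule, state$time - sched_origin)
  state <- diffuse(state, dt, species, seed = derive_seed(seed, 1, 0), box = box)
  state$time <- state$time + dt
  state <- react(state, dt, reactions, species,
                 seed = derive_seed(seed, 2, 0), jitter = jitter, box = box,
                 bridge = bridge)
  state$n_steps <- state$n_steps + 1L
  state
}

#' Evolve the chemical stage to a target time
#'
#' Runs the compiled step-by-step loop (diffusion + reactions with the
#' adaptive schedule) from the state's current time to `t_end`, recording
#' the per-species molecule count `N(t)` of active molecules at each
#' requested log time.  Counts include surviving initial species and
#' accumulated products.
#'
#' @inheritParams step_state
#' @param t_end end time, ps (>= current time).
#' @param log_times sorted times (ps) at which to record counts; times at or
#'   before the current time reflect the initial state.
#' @param stop_when_inert stop early (carrying counts forward) once no
#'   reactive pair of species remains; only safe when no inactive molecules
#'   are pending activation.
#' @return list with `state` (advanced to `t_end`) and `counts`, a data
#'   frame `(time_ps, species, N, E_eV)`.
#' @export
evolve <- function(state, t_end, log_times, schedule = timestep_schedule(),
                   reactions = default_reactions(),
                   species = default_species(), seed = 1L,
                   sched_origin = 1, jitter = 0, box = NULL, bridge = TRUE,
                   stop_when_inert = FALSE) {
  if (t_end < state$time) stop("`t_end` must be >= current state time")
  if (is.unsorted(log_times)) stop("`log_times` must be sorted")
  m <- state$molecules
  res <- cpp_evolve(as.matrix(m[, c("x_nm", "y_nm", "z_nm")]),
                    as.integer(species_index(m$species, species)),
                    as.integer(m$track_id), m$active, m$created,
                    species$D_nm2_ps, compile_channels(reactions, species),
                    state$time, t_end, as.numeric(log_times),
                    schedule$breaks, schedule$dts, sched_origin, jitter,
                    if (is.null(box)) -1 else box, as.numeric(seed),
                    bridge, stop_when_inert)
  state <- merge_engine_result(state, res, reactions, species)
  state$time <- res$time
  state$n_steps <- state$n_steps + res$n_steps
  counts <- data.frame(
    time_ps = rep(log_times, times = nrow(species)),
    species = rep(species$species, each = length(log_times)),
    N = as.integer(res$counts),
    stringsAsFactors = FALSE)
  counts$E_eV <- state_energy(state, counts$time_ps)
  list(state = state, counts = counts)
}
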