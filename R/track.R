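#' Sample primary energy-deposition events along a track segment
#'
#' Surrogate for the physical stage (over by ~1 fs): events are placed along
#' +z over the scoring depth, with transverse offsets from the configured
#' [radial_profile()].  The event count is Poisson with mean
#' `LET x depth x 1000 / mean_event_energy`, each event carries
#' `mean_event_energy` eV, so the total deposited energy has expectation
#' `LET x depth` (in keV).  Event classes are drawn from the prechemical
#' class probabilities.
#'
#' @param spec a [particle_spec()].
#' @param mean_event_energy mean energy per primary event, eV (default
#'   62.5 eV, i.e. 16 events per keV; a tunable surrogate parameter).
#' @param class_probs named event-class probabilities (defaults to those of
#'   [default_branching()]).
#' @param radial a [radial_profile()].
#' @param origin transverse `(x, y)` position of the track axis, nm.
#' @param seed integer seed.
#' @return data frame with columns `class`, `x_nm`, `y_nm`, `z_nm`,
#'   `energy_eV`.
#' @export
sample_primary_events <- function(spec, mean_event_energy = 62.5,
                                  class_probs = attr(default_branching(), "class_probs"),
                                  radial = radial_profile(),
                                  origin = c(0, 0), seed = 1L) {
  if (!inherits(spec, "particle_spec")) spec <- do.call(particle_spec, spec)
  if (mean_event_energy <= 0) stop("`mean_event_energy` must be > 0")
  depth_nm <- spec$depth * 1000
  lambda <- spec$let * spec$depth * 1000 / mean_event_energy
  with_seed(seed, {
    n <- rpois(1, lambda)
    cls <- if (n > 0) sample(names(class_probs), n, replace = TRUE,
                             prob = class_probs) else character(0)
    z <- runif(n, 0, depth_nm)
    # transverse offset: Gaussian core, log-uniform heavy tail
    tail <- runif(n) < radial$tail_fraction
    x <- rnorm(n, 0, radial$core_sd_nm)
    y <- rnorm(n, 0, radial$core_sd_nm)
    nt <- sum(tail)
    if (nt > 0) {
      r <- radial$tail_rmin_nm *
        (radial$tail_rmax_nm / radial$tail_rmin_nm)^runif(nt)
      phi <- runif(nt, 0, 2 * pi)
      x[tail] <- r * cos(phi)
      y[tail] <- r * sin(phi)
    }
    data.frame(class = cls,
               x_nm = origin[1] + x,
               y_nm = origin[2] + y,
               z_nm = z,
               energy_eV = rep(mean_event_energy, n),
               stringsAsFactors = FALSE)
  })
}

#' Dissociate primary events into the 1-ps species inventory
#'
#' Surrogate for the prechemical stage (1 fs to 1 ps): each event is
#' replaced by the product multiset of a branching channel sampled within
#' its event class, every product displaced isotropically from the event
#' position by a Gaussian kick with per-axis standard deviation equal to the
#' channel's per-product scale.  Deposited energy is carried through
#' unchanged; the inventory is stamped at 1 ps.
#'
#' @param events output of [sample_primary_events()].
#' @param branching a [branching_table()].
#' @param seed integer seed.
#' @param track_id integer id attached to every molecule.
#' @param species a [species_table()] (products are validated against it).
#' @return a `species_inventory`: data frame (`species`, `x_nm`, `y_nm`,
#'   `z_nm`, `track_id`) with attributes `energy_eV` (sum of event energies,
#'   exact) and `time_ps = 1`.
#' @export
apply_prechemistry <- function(events, branching = default_branching(),
                               seed = 1L, track_id = 1L,
                               species = default_species()) {
  stopifnot(inherits(branching, "branching_table"))
  out <- with_seed(seed, {
    rows <- vector("list", nrow(events))
    for (i in seq_len(nrow(events))) {
      sub <- branching[branching$class == events$class[i], , drop = FALSE]
      if (nrow(sub) == 0)
        stop("no branching channels for event class '", events$class[i], "'")
      j <- if (nrow(sub) == 1) 1L else
        sample.int(nrow(sub), 1, prob = sub$prob)
      prods <- sub$products[[j]]
      np <- length(prods)
      if (np == 0) next
      sc <- sub$scales[[j]]
      rows[[i]] <- data.frame(
        species = prods,
        x_nm = events$x_nm[i] + sc * rnorm(np),
        y_nm = events$y_nm[i] + sc * rnorm(np),
        z_nm = events$z_nm[i] + sc * rnorm(np),
        track_id = track_id,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })
  if (is.null(out))
    out <- data.frame(species = character(0), x_nm = numeric(0),
                      y_nm = numeric(0), z_nm = numeric(0),
                      track_id = integer(0), stringsAsFactors = FALSE)
  species_index(out$species, species)  # validate labels
  rownames(out) <- NULL
  attr(out, "energy_eV") <- sum(events$energy_eV)
  attr(out, "time_ps") <- 1
  class(out) <- c("species_inventory", "data.frame")
  out
}

#' Generate the 1-ps species inventory of one ion track
#'
#' Composition of [sample_primary_events()] and [apply_prechemistry()]:
#' physical + prechemical surrogate for a single track segment.
#' Deterministic given the seed.
#'
#' @inheritParams sample_primary_events
#' @inheritParams apply_prechemistry
#' @param branching a [branching_table()] (its class probabilities drive the
#'   event sampling).
#' @return a `species_inventory` (see [apply_prechemistry()]).
#' @export
generate_track <- function(spec, branching = default_branching(),
                           species = default_species(),
                           radial = radial_profile(),
                           mean_event_energy = 62.5,
                           origin = c(0, 0), seed = 1L, track_id = 1L) {
  ev <- sample_primary_events(spec, mean_event_energy,
                              class_probs = attr(branching, "class_probs"),
                              radial = radial, origin = origin,
                              seed = derive_seed(seed, 1, track_id))
  apply_prechemistry(ev, branching, seed = derive_seed(seed, 2, track_id),
                     track_id = track_id, species = species)
}

#' Export a species inventory as CSV
#'
#' @param inv a `species_inventory`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_inventory <- function(inv, path) {
  write.csv(inv[, c("species", "x_nm", "y_nm", "z_nm", "track_id")],
            path, row.names = FALSE)
  invisible(path)
}
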