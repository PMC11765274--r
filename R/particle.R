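#' Primary particle specification
#'
#' Identifies the ion and the track-segment geometry used for the surrogate
#' physical stage.  The LET (keV/um) and the scoring depth (um, length of
#' the scoring volume along the beam axis) drive the event density and the
#' total deposited energy `LET x depth`; the depth is chosen short enough
#' that the LET is effectively constant over the segment (track-segment
#' condition).
#'
#' @param name ion label, e.g. `"proton"`, `"helium"`, `"carbon"`.
#' @param energy kinetic energy in MeV per nucleon (bookkeeping only; the
#'   surrogate is parameterized by LET).
#' @param let linear energy transfer, keV/um.  Must be > 0.
#' @param depth scoring depth along the beam, um.  Must be > 0.
#' @return a `particle_spec`.
#' @export
particle_spec <- function(name, energy, let, depth) {
  if (!is.character(name) || length(name) != 1)
    stop("`name` must be a single string")
  for (f in c("energy", "let", "depth")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("`", f, "` must be a single positive number")
  }
  structure(list(name = name, energy = energy, let = let, depth = depth),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> %s, %g MeV/u, LET %g keV/um, depth %g um\n",
              x$name, x$energy, x$let, x$depth))
  invisible(x)
}

#' Transverse radial profile of energy-deposition events
#'
#' Two-component surrogate for the transverse track structure: a narrow
#' Gaussian core (nm scale, direct ionizations close to the ion path) plus
#' a heavy log-uniform tail (delta-electron penumbra) reaching out to
#' `tail_rmax_nm`, so that a small configurable fraction of species ends up
#' beyond several hundred nm of the axis.
#'
#' @param core_sd_nm per-axis standard deviation of the Gaussian core, nm.
#' @param tail_fraction probability that an event belongs to the tail.
#' @param tail_rmin_nm,tail_rmax_nm radial range of the log-uniform tail, nm.
#' @return a `radial_profile` list.
#' @export
radial_profile <- function(core_sd_nm = 2, tail_fraction = 0.05,
                           tail_rmin_nm = 5, tail_rmax_nm = 1000) {
  if (core_sd_nm < 0) stop("`core_sd_nm` must be >= 0")
  if (tail_fraction < 0 || tail_fraction > 1)
    stop("`tail_fraction` must be in [0, 1]")
  if (tail_rmin_nm <= 0 || tail_rmax_nm < tail_rmin_nm)
    stop("need 0 < tail_rmin_nm <= tail_rmax_nm")
  structure(list(core_sd_nm = core_sd_nm, tail_fraction = tail_fraction,
                 tail_rmin_nm = tail_rmin_nm, tail_rmax_nm = tail_rmax_nm),
            class = "radial_profile")
}
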