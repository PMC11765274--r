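#' Radiolytic yield (G-value)
#'
#' `G = N / E x 100`: molecules produced or consumed per 100 eV of deposited
#' energy.
#'
#' @param N molecule count at the readout time.
#' @param E deposited energy at the readout time, eV (> 0).
#' @return G-value, molecules per 100 eV.
#' @export
gvalue <- function(N, E) {
  if (any(E <= 0)) stop("`E` must be > 0")
  N / E * 100
}

#' Expected G-value at the arrival peak/drop of the second track
#'
#' At the activation instant the combined G-value is a counting identity:
#' the first track contributes its survivors at the delay, the second its
#' fresh 1-ps inventory, over the summed energies:
#' `(N1 + N2) / (E1 + E2) x 100`.  Primary species peak (but below their
#' 1-ps value); secondary species, none of which arrive with the fresh
#' track, drop.
#'
#' @param N1_at_dt track-1 count at the delay.
#' @param N2_at_1ps track-2 count at 1 ps.
#' @param E1,E2 per-track deposited energies, eV.
#' @return G-value, molecules per 100 eV.
#' @export
peak_drop_expectation <- function(N1_at_dt, N2_at_1ps, E1, E2) {
  gvalue(N1_at_dt + N2_at_1ps, E1 + E2)
}

#' Normalized 1-us G-value difference against the NI reference
#'
#' `(G_pair - G_NI) / G_NI`, the relative intertrack effect on the yield
#' read 1 us after the second track's arrival.
#'
#' @param g_pair pair-run G-value at `1 us + dt`.
#' @param g_ni_ref NI reference (see [ni_reference()]); must be > 0.
#' @return relative difference (dimensionless; multiply by 100 for %).
#' @export
delta_g_mus <- function(g_pair, g_ni_ref) {
  if (any(g_ni_ref <= 0)) stop("NI reference G-value must be > 0")
  (g_pair - g_ni_ref) / g_ni_ref
}

#' Radius containing 80% of the chemical species
#'
#' The smallest transverse distance from the track axis containing at least
#' 80% of the molecules (an order statistic of the radial distances).
#'
#' @param r radial distances to the parent-track axis, nm (or a molecule
#'   data frame with `x_nm`, `y_nm`, in which case the axis is `axis`).
#' @param q quantile (default 0.8).
#' @param axis transverse `(x, y)` position of the track axis, nm.
#' @return radius, nm.
#' @export
r80 <- function(r, q = 0.8, axis = c(0, 0)) {
  if (is.data.frame(r))
    r <- sqrt((r$x_nm - axis[1])^2 + (r$y_nm - axis[2])^2)
  if (length(r) == 0) return(NA_real_)
  sort(r)[ceiling(q * length(r))]
}

#' Percentage of molecules beyond a radius
#'
#' @inheritParams r80
#' @param radius threshold, nm (default 500).
#' @return percentage in `[0, 100]`.
#' @export
fraction_beyond <- function(r, radius = 500, axis = c(0, 0)) {
  if (is.data.frame(r))
    r <- sqrt((r$x_nm - axis[1])^2 + (r$y_nm - axis[2])^2)
  if (length(r) == 0) return(NA_real_)
  100 * mean(r > radius)
}

#' Two-sample significance of an intertrack effect
#'
#' Welch two-sample t-test on per-replicate G-values at the readout time,
#' pair runs against NI references.  Degenerate inputs (zero variance in
#' both arms) return p = 1 when the means agree and p = 0 otherwise.
#'
#' @param pair_g per-replicate pair G-values.
#' @param ni_g per-replicate NI reference G-values.
#' @return p-value in `[0, 1]`.
#' @export
significance <- function(pair_g, ni_g) {
  if (length(pair_g) < 2 || length(ni_g) < 2) return(NA_real_)
  if (sd(pair_g) == 0 && sd(ni_g) == 0)
    return(if (isTRUE(all.equal(mean(pair_g), mean(ni_g)))) 1 else 0)
  tryCatch(t.test(pair_g, ni_g)$p.value, error = function(e) NA_real_)
}

#' Replicated pair + NI experiment at one (dx, dt) condition
#'
#' Runs `replicates` independent pair simulations and (unless a shared NI
#' ensemble is supplied) as many NI references, reads every replicate's
#' G-values at `t_chem + dt` and assembles per-species intertrack
#' statistics.
#'
#' @inheritParams run_pair
#' @param replicates number of independent replicates (>= 1); see
#'   [replicate_count()] for the energy-normalized choice.
#' @param ni_runs optional list of precomputed `ni_run` objects to reuse
#'   across conditions (their log grids must cover `t_chem` and
#'   `t_chem + dt`); NI runs do not depend on dx, and a single ensemble
#'   evolved past the largest delay serves a whole grid.
#' @param keep_runs keep the individual `pair_run` objects.
#' @return a `condition_result`: list with `stats` (data frame per species:
#'   `delta_g`, `se`, `n`, `p`), the per-replicate G matrices, and the
#'   condition parameters.
#' @export
run_condition <- function(particle, dx, dt_delay, replicates,
                          tables = sim_tables(), seed = 1L, t_chem = 1e6,
                          per_decade = 20, ni_runs = NULL,
                          keep_runs = FALSE) {
  sp <- tables$species$species
  pair_g <- matrix(NA_real_, replicates, length(sp),
                   dimnames = list(NULL, sp))
  runs <- if (keep_runs) vector("list", replicates) else NULL
  for (r in seq_len(replicates)) {
    pr <- run_pair(particle, dx, dt_delay, tables,
                   seed = derive_seed(seed, 100 + r, 1),
                   t_chem = t_chem, per_decade = per_decade)
    pair_g[r, ] <- g_at(pr$gseries, pr$t_act + t_chem)[sp]
    if (keep_runs) runs[[r]] <- pr
  }
  if (is.null(ni_runs)) {
    ni_runs <- lapply(seq_len(replicates), function(r)
      run_ni(particle, dt_delay, tables,
             seed = derive_seed(seed, 500 + r, 2),
             t_chem = t_chem, per_decade = per_decade))
  }
  ni_g <- t(vapply(ni_runs, function(nr)
    ni_reference(nr, dt_delay, t_chem)[sp], numeric(length(sp))))
  stats <- data.frame(species = sp, dx_nm = dx, dt_ps = dt_delay,
                      stringsAsFactors = FALSE)
  gp <- colMeans(pair_g); gn <- colMeans(ni_g)
  gn[gn == 0] <- NA_real_  # species absent from the NI reference
  stats$g_pair <- gp
  stats$g_ni <- gn
  stats$delta_g <- (gp - gn) / gn
  # delta-method SE of the ratio-based difference
  se_p <- apply(pair_g, 2, sd) / sqrt(nrow(pair_g))
  se_n <- apply(ni_g, 2, sd) / sqrt(nrow(ni_g))
  stats$se <- sqrt(se_p^2 + (gp / gn)^2 * se_n^2) / gn
  stats$n <- replicates
  stats$p <- vapply(sp, function(s) significance(pair_g[, s], ni_g[, s]),
                    numeric(1))
  structure(list(stats = stats, pair_g = pair_g, ni_g = ni_g,
                 dx = dx, dt_delay = dt_delay, t_chem = t_chem,
                 runs = runs),
            class = "condition_result")
}

#' Assemble a dx/dt grid of intertrack effects
#'
#' Binds the per-condition statistics into the per-species matrix of
#' normalized 1-us G-value differences over (dx, dt), with replicate
#' standard errors and NI significance.
#'
#' @param conditions list of `condition_result` objects (see
#'   [run_condition()]).
#' @return a `delta_g_grid` data frame with columns `species`, `dx_nm`,
#'   `dt_ps`, `g_pair`, `g_ni`, `delta_g`, `se`, `n`, `p`.
#' @export
build_grid <- function(conditions) {
  g <- do.call(rbind, lapply(conditions, function(cr) cr$stats))
  rownames(g) <- NULL
  class(g) <- c("delta_g_grid", "data.frame")
  g
}

#' Sweep the (dx, dt) separation grids
#'
#' Runs [run_condition()] for every combination of `dx_grid` and `dt_grid`,
#' sharing one NI ensemble (evolved past the largest delay) across all
#' conditions, and returns the assembled [build_grid()] result.
#'
#' @inheritParams run_condition
#' @param dx_grid spatial separations, nm.
#' @param dt_grid arrival delays, ps.
#' @param progress emit one message per condition to standard error.
#' @return a `delta_g_grid`.
#' @export
run_grid <- function(particle, dx_grid, dt_grid, replicates,
                     tables = sim_tables(), seed = 1L, t_chem = 1e6,
                     per_decade = 20, progress = FALSE) {
  ni_runs <- lapply(seq_len(replicates), function(r)
    run_ni(particle, max(dt_grid), tables,
           seed = derive_seed(seed, 500 + r, 2), t_chem = t_chem,
           per_decade = per_decade, extra_log = t_chem + dt_grid))
  conds <- list()
  k <- 0L
  for (dt in dt_grid) for (dx in dx_grid) {
    k <- k + 1L
    if (progress)
      message(sprintf("condition %d/%d: dx = %g nm, dt = %g ps",
                      k, length(dx_grid) * length(dt_grid), dx, dt))
    conds[[k]] <- run_condition(particle, dx, dt, replicates, tables,
                                seed = derive_seed(seed, 7, k),
                                t_chem = t_chem, per_decade = per_decade,
                                ni_runs = ni_runs)
  }
  build_grid(conds)
}
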