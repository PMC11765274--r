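#' Deterministic tiny inventories for tests and demonstrations
#'
#' Three miniature 1-ps species inventories:
#' * `"isolated_pair"` -- two molecules (`species` pair, default a solvated
#'   electron and a hydronium ion) at distance `r0` nm, the geminate-pair
#'   oracle geometry;
#' * `"two_oh"` -- two OH radicals at distance `r0`, forcing a single
#'   peroxide-forming recombination when within the reaction radius;
#' * `"mini_track"` -- about 50 molecules scattered around a 100-nm axis
#'   segment with the default branching mix.
#'
#' @param kind one of `"isolated_pair"`, `"two_oh"`, `"mini_track"`.
#' @param seed integer seed; the same seed always returns the identical
#'   fixture.
#' @param r0 pair separation, nm (pair fixtures).
#' @param species_pair labels for `"isolated_pair"`.
#' @return a `species_inventory`.
#' @export
make_fixture <- function(kind = c("isolated_pair", "two_oh", "mini_track"),
                         seed = 1L, r0 = 1,
                         species_pair = c("e_aq", "H3O+")) {
  kind <- match.arg(kind)
  inv <- switch(kind,
    isolated_pair = data.frame(
      species = species_pair,
      x_nm = c(0, r0), y_nm = c(0, 0), z_nm = c(0, 0),
      track_id = 1L, stringsAsFactors = FALSE),
    two_oh = data.frame(
      species = c("OH", "OH"),
      x_nm = c(0, r0), y_nm = c(0, 0), z_nm = c(0, 0),
      track_id = 1L, stringsAsFactors = FALSE),
    mini_track = with_seed(seed, {
      n <- 50L
      labs <- sample(c("OH", "H3O+", "e_aq", "H"), n, replace = TRUE,
                     prob = c(0.35, 0.3, 0.3, 0.05))
      data.frame(species = labs,
                 x_nm = rnorm(n, 0, 2), y_nm = rnorm(n, 0, 2),
                 z_nm = runif(n, 0, 100), track_id = 1L,
                 stringsAsFactors = FALSE)
    }))
  attr(inv, "energy_eV") <- nrow(inv) * 62.5 / 2.57  # nominal bookkeeping
  attr(inv, "time_ps") <- 1
  class(inv) <- c("species_inventory", "data.frame")
  inv
}
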