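# Shared miniature fixtures: an abstract three-species system (A + B -> P,
# all compositions zero so balance holds trivially) for engine oracles, and
# a small low-LET particle for fast end-to-end runs.

abc_species <- function(Da = 5e-3, Db = 5e-3) {
  species_table(data.frame(
    species = c("A", "B", "P"),
    D_nm2_ps = c(Da, Db, 0),
    n_H = 0L, n_O = 0L, charge = 0L,
    stringsAsFactors = FALSE))
}

abc_reaction <- function(radius = NULL, k = 1e10, species = abc_species()) {
  df <- data.frame(name = "A + B -> P", r1 = "A", r2 = "B", k_M_s = k,
                   stringsAsFactors = FALSE)
  df$products <- list("P")
  if (!is.null(radius)) df$radius_nm <- radius
  reaction_table(df, species)
}

# inventory from explicit coordinates
inventory_at <- function(species, x, y, z, track = 1L, energy = 100) {
  inv <- data.frame(species = species, x_nm = x, y_nm = y, z_nm = z,
                    track_id = track, stringsAsFactors = FALSE)
  attr(inv, "energy_eV") <- energy
  attr(inv, "time_ps") <- 1
  class(inv) <- c("species_inventory", "data.frame")
  inv
}

# many independent far-apart A-B pairs at separation r0 in one state
pair_lattice <- function(n, r0 = 1, spacing = 1000) {
  inventory_at(rep(c("A", "B"), n),
               x = rep(c(0, r0), n), y = 0,
               z = rep(seq(0, by = spacing, length.out = n), each = 2))
}

fast_particle <- function(let = 30, depth = 0.1)
  particle_spec("test-ion", 10, let, depth)

# element/charge totals of a molecule table, plus implicit water add-back
balance_totals <- function(mols, rlog, species = default_species()) {
  i <- match(mols$species, species$species)
  h2o <- if (is.null(rlog)) 0L else sum(rlog$h2o)
  c(H = sum(species$n_H[i]) + 2 * h2o,
    O = sum(species$n_O[i]) + h2o,
    charge = sum(species$charge[i]))
}
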