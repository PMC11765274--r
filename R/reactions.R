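#' Reaction radius from a measured rate constant
#'
#' Closure for diffusion-controlled bimolecular kinetics: the reaction
#' radius that reproduces a steady-state Smoluchowski rate
#' `k = 4 pi (Da + Db) R` is
#' `R = k' / (4 pi (Da + Db))`, where `k'` is the molar rate constant
#' converted to per-molecule units (1 M^-1 s^-1 = 1.6606e-12 nm^3/ps).
#' All channels, including partially diffusion-controlled ones, use this
#' fully diffusion-controlled closure (no acceptance probabilities).
#'
#' @param k rate constant, M^-1 s^-1.
#' @param Da,Db diffusion coefficients of the two reactants, nm^2/ps.
#' @return reaction radius in nm.
#' @examples
#' smoluchowski_radius(7.0e9, 5e-3, 5e-3)  # ~0.0925 nm
#' @export
smoluchowski_radius <- function(k, Da, Db) {
  if (any(k < 0)) stop("rate constants must be >= 0")
  drel <- Da + Db
  if (any(drel <= 0 & k > 0))
    stop("both reactants immobile (Da + Db = 0) but k > 0: no encounter possible")
  r <- ifelse(k == 0, 0, k * .K_CONV / (4 * pi * drel))
  as.numeric(r)
}

#' Build and validate a bimolecular reaction table
#'
#' Each channel consumes an unordered pair of tracked species and produces
#' 0-3 tracked species; implicit solvent water closes the balance and is
#' recorded per channel as `h2o` (positive: emitted, negative: consumed,
#' e.g. the hydration reaction of two solvated electrons consumes two
#' waters).  Validation enforces hydrogen, oxygen and charge conservation
#' on every channel; an inconsistent channel is rejected by name.
#'
#' Reaction radii are derived from the rate constants with
#' [smoluchowski_radius()] unless an explicit `radius` column is supplied.
#'
#' @param df data frame with columns `name`, `r1`, `r2` (reactant species),
#'   `products` (list column of character vectors, up to 3 entries),
#'   `k_M_s` and optionally `radius_nm` and `weight` (branching weight when
#'   several channels share a reactant pair; default 1).
#' @param species a [species_table()].
#' @return a `reaction_table` data frame with derived `radius_nm` and `h2o`.
#' @export
reaction_table <- function(df, species = default_species()) {
  need <- c("name", "r1", "r2", "products", "k_M_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("reaction table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  if (!is.list(df$products)) stop("`products` must be a list column")
  if (is.null(df$weight)) df$weight <- 1
  for (i in seq_len(nrow(df))) {
    ch <- df$name[i]
    labs <- c(df$r1[i], df$r2[i], df$products[[i]])
    bad <- setdiff(labs, species$species)
    if (length(bad) > 0)
      stop("reaction '", ch, "' uses unknown species: ",
           paste(bad, collapse = ", "))
    if (length(df$products[[i]]) > 3)
      stop("reaction '", ch, "' has more than 3 tracked products")
  }
  # element / charge balance with implicit H2O: solve the water count from
  # oxygen, then hydrogen and charge must close exactly
  h2o <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    ri <- species_index(c(df$r1[i], df$r2[i]), species)
    pi <- species_index(df$products[[i]], species)
    dO <- sum(species$n_O[ri]) - sum(species$n_O[pi])
    dH <- sum(species$n_H[ri]) - sum(species$n_H[pi])
    dq <- sum(species$charge[ri]) - sum(species$charge[pi])
    if (dH != 2 * dO || dq != 0)
      stop("reaction '", df$name[i], "' does not conserve H/O/charge ",
           "(dH = ", dH, ", dO = ", dO, ", dcharge = ", dq, ")")
    h2o[i] <- dO
  }
  df$h2o <- h2o
  if (is.null(df$radius_nm)) {
    df$radius_nm <- mapply(function(k, a, b) {
      i <- species_index(c(a, b), species)
      smoluchowski_radius(k, species$D_nm2_ps[i[1]], species$D_nm2_ps[i[2]])
    }, df$k_M_s, df$r1, df$r2)
  }
  if (any(df$radius_nm < 0)) stop("reaction radii must be >= 0")
  rownames(df) <- NULL
  class(df) <- c("reaction_table", "data.frame")
  df
}

#' Default reaction set
#'
#' The nine channels closing the chemistry over the seven tracked species:
#' recombination of the solvated electron with itself, OH, H, H3O+ and
#' H2O2; OH-OH recombination to peroxide; OH+H and H+H; and water
#' neutralization H3O+ + OH-.  Rate constants (M^-1 s^-1) are a standard
#' literature compilation used by track-structure chemistry codes; the
#' OH + H2O2 -> HO2 channel is disabled by default to keep the species set
#' closed.
#'
#' @param species a [species_table()].
#' @return a `reaction_table`.
#' @export
default_reactions <- function(species = default_species()) {
  df <- data.frame(
    name = c("e_aq + e_aq -> H2 + 2 OH-",
             "e_aq + OH -> OH-",
             "e_aq + H -> H2 + OH-",
             "e_aq + H3O+ -> H",
             "e_aq + H2O2 -> OH + OH-",
             "OH + OH -> H2O2",
             "OH + H -> H2O",
             "H + H -> H2",
             "H3O+ + OH- -> 2 H2O"),
    r1 = c("e_aq", "e_aq", "e_aq", "e_aq", "e_aq", "OH", "OH", "H", "H3O+"),
    r2 = c("e_aq", "OH", "H", "H3O+", "H2O2", "OH", "H", "H", "OH-"),
    k_M_s = c(0.55e10, 2.95e10, 2.65e10, 2.11e10, 1.41e10,
              0.44e10, 1.44e10, 0.78e10, 11.3e10),
    stringsAsFactors = FALSE
  )
  df$products <- list(c("H2", "OH-", "OH-"),
                      "OH-",
                      c("H2", "OH-"),
                      "H",
                      c("OH", "OH-"),
                      "H2O2",
                      character(0),
                      "H2",
                      character(0))
  reaction_table(df, species)
}

# pack a reaction table into the flat integer/double arrays the C++ engine
# consumes (1-based species indices; product slots padded with 0)
compile_channels <- function(reactions, species) {
  nc <- nrow(reactions)
  prods <- matrix(0L, nrow = max(nc, 1), ncol = 3)
  for (i in seq_len(nc)) {
    p <- species_index(reactions$products[[i]], species)
    if (length(p) > 0) prods[i, seq_along(p)] <- as.integer(p)
  }
  # a reactant pair served by several channels needs branching weights
  key <- apply(cbind(pmin(reactions$r1, reactions$r2),
                     pmax(reactions$r1, reactions$r2)), 1, paste, collapse = "|")
  for (k in unique(key[duplicated(key)])) {
    w <- reactions$weight[key == k]
    if (any(is.na(w)) || all(w == 0))
      stop("reactant pair ", k, " has multiple channels but no usable ",
           "branching weights")
  }
  list(a = as.integer(species_index(reactions$r1, species)),
       b = as.integer(species_index(reactions$r2, species)),
       radius = as.numeric(reactions$radius_nm),
       weight = as.numeric(reactions$weight),
       products = prods,
       h2o = as.integer(reactions$h2o))
}
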