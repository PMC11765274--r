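#' Tracked radiolytic species and their transport properties
#'
#' The chemical stage tracks the seven standard products of water radiolysis:
#' the hydroxyl radical `OH`, the solvated electron `e_aq`, the hydronium ion
#' `H3O+`, the hydrogen atom `H`, molecular hydrogen `H2`, hydrogen peroxide
#' `H2O2` and the hydroxide ion `OH-`.  Solvent water is implicit: reactions
#' may emit or consume it, and the engine logs those emissions so that
#' element and charge balances can be closed.
#'
#' @param df data frame with columns `species`, `D_nm2_ps` (diffusion
#'   coefficient, nm^2/ps), `n_H`, `n_O` (atom counts) and `charge`
#'   (elementary charges).  `e_aq` is bookkept as a bare charge (0 H, 0 O,
#'   charge -1) so that its hydration shell stays with the solvent.
#' @return a `species_table` (validated data frame).
#' @export
species_table <- function(df) {
  need <- c("species", "D_nm2_ps", "n_H", "n_O", "charge")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("species table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$species))
    stop("species labels must be unique")
  if (any(df$D_nm2_ps < 0))
    stop("diffusion coefficients must be >= 0")
  rownames(df) <- NULL
  class(df) <- c("species_table", "data.frame")
  df
}

#' Default species table
#'
#' Diffusion coefficients are the values commonly used by track-structure
#' chemistry codes (in 1e-9 m^2/s: OH 2.8, e_aq 4.9, H3O+ 9.46, H 7.0,
#' H2 4.8, H2O2 2.3, OH- 5.3), converted to nm^2/ps.  They are a literature
#' compilation, configurable through the run configuration.
#'
#' @return a `species_table`.
#' @export
default_species <- function() {
  species_table(data.frame(
    species  = c("OH", "e_aq", "H3O+", "H", "H2", "H2O2", "OH-"),
    D_nm2_ps = c(2.8e-3, 4.9e-3, 9.46e-3, 7.0e-3, 4.8e-3, 2.3e-3, 5.3e-3),
    n_H      = c(1L, 0L, 3L, 1L, 2L, 2L, 1L),
    n_O      = c(1L, 0L, 1L, 0L, 0L, 2L, 1L),
    charge   = c(0L, -1L, 1L, 0L, 0L, 0L, -1L),
    stringsAsFactors = FALSE
  ))
}

species_index <- function(labels, species) {
  i <- match(labels, species$species)
  if (anyNA(i))
    stop("unknown species: ", paste(unique(labels[is.na(i)]), collapse = ", "))
  i
}
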