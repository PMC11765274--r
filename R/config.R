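#' Default run configuration
#'
#' The full configuration of a multi-track study as a plain nested list
#' (YAML-serializable): particle, tables, separation grids, replicate
#' normalization and logging.  The separation grids default to the study
#' grids `dx = 0, 1, 10, 100, 1000 nm` and
#' `dt = 1, 10, 100 ps, 10, 100, 300, 700, 1000 ns`; replicates are
#' normalized to a 2 MeV total deposition.  Rate constants, diffusion
#' coefficients and branching ratios are literature-style defaults (see
#' [default_reactions()], [default_species()], [default_branching()]), all
#' overridable from the file.
#'
#' @return a nested list.
#' @export
default_config <- function() {
  sp <- default_species()
  rx <- default_reactions(sp)
  br <- default_branching(sp)
  list(
    particle = list(name = "carbon", energy_MeV_u = 40,
                    let_keV_um = 30, depth_um = 2),
    mean_event_energy_eV = 62.5,
    radial = list(core_sd_nm = 2, tail_fraction = 0.05,
                  tail_rmin_nm = 5, tail_rmax_nm = 1000),
    species = lapply(seq_len(nrow(sp)), function(i) list(
      label = sp$species[i], D_nm2_ps = sp$D_nm2_ps[i],
      n_H = sp$n_H[i], n_O = sp$n_O[i], charge = sp$charge[i])),
    reactions = lapply(seq_len(nrow(rx)), function(i) list(
      name = rx$name[i], reactants = c(rx$r1[i], rx$r2[i]),
      products = as.list(rx$products[[i]]), k_M_s = rx$k_M_s[i])),
    branching = list(
      class_probs = as.list(attr(br, "class_probs")),
      channels = lapply(seq_len(nrow(br)), function(i) list(
        class = br$class[i], channel = br$channel[i], prob = br$prob[i],
        products = as.list(br$products[[i]]),
        scales = as.list(br$scales[[i]])))),
    schedule = list(breaks_ps = c(1e3, 1e4, "Inf"), dts_ps = c(0.1, 1, 10)),
    grid = list(dx_nm = c(0, 1, 10, 100, 1000),
                dt_ps = c(1, 10, 100, 1e4, 1e5, 3e5, 7e5, 1e6)),
    replicate_target_energy_eV = 2e6,
    t_chem_ps = 1e6,
    logging = list(per_decade = 20),
    product_jitter_nm = 0,
    seed = 1
  )
}

cfg_stop <- function(path, msg) stop("config error at ", path, ": ", msg,
                                     call. = FALSE)

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills every missing field from
#' [default_config()], validates all cross-references (every reactant,
#' product and branching species must exist in the species table; grids and
#' counts must be admissible) and builds the parsed tables.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return a `run_config`: the merged raw list plus parsed `particle`
#'   ([particle_spec()]) and `tables` ([sim_tables()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- utils::modifyList(default_config(), raw, keep.null = TRUE)
  # unnamed list-of-records sections replace the default wholesale rather
  # than merging element-wise
  for (k in c("species", "reactions"))
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  if (!is.null(raw$branching$channels))
    cfg$branching$channels <- raw$branching$channels
  parse_config(cfg)
}

parse_config <- function(cfg) {
  p <- cfg$particle
  for (f in c("let_keV_um", "depth_um", "energy_MeV_u"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || p[[f]] <= 0)
      cfg_stop(paste0("particle.", f), "must be a single positive number")
  particle <- particle_spec(p$name, p$energy_MeV_u, p$let_keV_um, p$depth_um)

  spdf <- do.call(rbind, lapply(cfg$species, function(s)
    data.frame(species = s$label, D_nm2_ps = s$D_nm2_ps, n_H = s$n_H,
               n_O = s$n_O, charge = s$charge, stringsAsFactors = FALSE)))
  species <- tryCatch(species_table(spdf),
                      error = function(e) cfg_stop("species", conditionMessage(e)))

  rxdf <- do.call(rbind, lapply(cfg$reactions, function(r)
    data.frame(name = r$name, r1 = r$reactants[[1]], r2 = r$reactants[[2]],
               k_M_s = r$k_M_s, stringsAsFactors = FALSE)))
  rxdf$products <- lapply(cfg$reactions, function(r)
    as.character(unlist(r$products)))
  reactions <- tryCatch(reaction_table(rxdf, species),
                        error = function(e) cfg_stop("reactions", conditionMessage(e)))

  brdf <- do.call(rbind, lapply(cfg$branching$channels, function(b)
    data.frame(class = b$class, channel = b$channel, prob = b$prob,
               stringsAsFactors = FALSE)))
  brdf$products <- lapply(cfg$branching$channels, function(b)
    as.character(unlist(b$products)))
  brdf$scales <- lapply(cfg$branching$channels, function(b)
    as.numeric(unlist(b$scales)))
  branching <- tryCatch(
    branching_table(brdf, unlist(cfg$branching$class_probs), species),
    error = function(e) cfg_stop("branching", conditionMessage(e)))

  radial <- tryCatch(do.call(radial_profile, cfg$radial),
                     error = function(e) cfg_stop("radial", conditionMessage(e)))
  schedule <- tryCatch(
    timestep_schedule(as.numeric(unlist(cfg$schedule$breaks_ps)),
                      as.numeric(unlist(cfg$schedule$dts_ps))),
    error = function(e) cfg_stop("schedule", conditionMessage(e)))

  if (any(cfg$grid$dx_nm < 0)) cfg_stop("grid.dx_nm", "must be >= 0")
  if (any(cfg$grid$dt_ps < 0)) cfg_stop("grid.dt_ps", "must be >= 0")
  if (cfg$replicate_target_energy_eV <= 0)
    cfg_stop("replicate_target_energy_eV", "must be > 0")
  if (cfg$mean_event_energy_eV <= 0)
    cfg_stop("mean_event_energy_eV", "must be > 0")

  tables <- sim_tables(species, reactions, branching, radial, schedule,
                       mean_event_energy = cfg$mean_event_energy_eV,
                       jitter = cfg$product_jitter_nm)
  structure(list(raw = cfg, particle = particle, tables = tables),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Writes the raw configuration list; [load_config()] on the result
#' round-trips to an identical configuration.
#'
#' @param config a `run_config` (or a raw configuration list).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- if (inherits(config, "run_config")) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}
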