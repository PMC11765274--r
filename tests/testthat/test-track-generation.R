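# Surrogate physical + prechemical stages: event sampling, dissociation,
# 1-ps inventories.

test_that("event sampling honours the LET x depth energy budget", {
  spec <- particle_spec("ion", 10, 30, 2)
  ev <- sample_primary_events(spec, mean_event_energy = 62.5, seed = 4)
  # each event carries the mean event energy, so totals are exact multiples
  expect_equal(sum(ev$energy_eV), nrow(ev) * 62.5)
  expect_true(all(ev$z_nm >= 0 & ev$z_nm <= 2000))

  # Poisson mean 60000 / 62.5 = 960: empirical mean over 500 seeds
  counts <- vapply(1:500, function(s)
    nrow(sample_primary_events(spec, 62.5, seed = s)), numeric(1))
  se <- sqrt(960 / 500)
  expect_lt(abs(mean(counts) - 960), 3 * se)
})

test_that("invalid particle or event configuration is rejected", {
  expect_error(particle_spec("ion", 10, 30, 0), "depth")
  expect_error(particle_spec("ion", 10, -1, 2), "let")
  expect_error(particle_spec("ion", 0, 30, 2), "energy")
  expect_error(sample_primary_events(particle_spec("i", 1, 30, 2),
                                     mean_event_energy = 0),
               "mean_event_energy")
})

test_that("doubling LET doubles the expected event count", {
  s1 <- particle_spec("ion", 10, 15, 1)
  s2 <- particle_spec("ion", 10, 30, 1)
  n1 <- vapply(1:300, function(s) nrow(sample_primary_events(s1, seed = s)),
               numeric(1))
  n2 <- vapply(1:300, function(s) nrow(sample_primary_events(s2, seed = s)),
               numeric(1))
  # ratio of Poisson means 2 within combined 3 SE
  expect_lt(abs(mean(n2) - 2 * mean(n1)),
            3 * sqrt(var(n2) / 300 + 4 * var(n1) / 300))
})

test_that("prechemistry replaces events by sampled product multisets", {
  sp <- default_species()
  # single deterministic ionization -> exactly the three-fragment channel
  df <- data.frame(class = "ionization", channel = "ion", prob = 1)
  df$products <- list(c("OH", "H3O+", "e_aq"))
  df$scales <- list(rep(0, 3))
  br <- branching_table(df, c(ionization = 1), sp)
  ev <- data.frame(class = "ionization", x_nm = 3, y_nm = -2, z_nm = 10,
                   energy_eV = 62.5)
  inv <- apply_prechemistry(ev, br, seed = 1)
  expect_equal(nrow(inv), 3)
  expect_setequal(inv$species, c("OH", "H3O+", "e_aq"))
  # zero displacement scales: all products on the event position
  expect_true(all(inv$x_nm == 3 & inv$y_nm == -2 & inv$z_nm == 10))
  expect_equal(attr(inv, "energy_eV"), 62.5)

  # zero events -> empty inventory with zero energy
  inv0 <- apply_prechemistry(ev[0, ], br, seed = 1)
  expect_equal(nrow(inv0), 0)
  expect_equal(attr(inv0, "energy_eV"), 0)
})

test_that("branching channels are sampled with their probabilities", {
  sp <- default_species()
  df <- data.frame(class = c("excitation", "excitation"),
                   channel = c("a", "b"), prob = c(0.7, 0.3))
  df$products <- list("OH", "H")
  df$scales <- list(0, 0)
  br <- branching_table(df, c(excitation = 1), sp)
  ev <- data.frame(class = "excitation", x_nm = 0, y_nm = 0,
                   z_nm = seq_len(1000), energy_eV = 62.5)
  inv <- apply_prechemistry(ev, br, seed = 9)
  n_oh <- sum(inv$species == "OH")
  expect_lt(abs(n_oh - 700), 3 * sqrt(1000 * 0.7 * 0.3))
})

test_that("unknown species in a branching table is a configuration error", {
  df <- data.frame(class = "ionization", channel = "ion", prob = 1)
  df$products <- list("Xe")
  df$scales <- list(0)
  expect_error(branching_table(df, c(ionization = 1)), "Xe")
})

test_that("track generation is deterministic and energy-exact", {
  spec <- fast_particle()
  a <- generate_track(spec, seed = 77)
  b <- generate_track(spec, seed = 77)
  expect_identical(a, b)
  c <- generate_track(spec, seed = 78)
  expect_false(identical(a, c))
  # energy bookkeeping: inventory energy is an exact multiple of the event
  # energy (sum of event energies, no rounding)
  expect_equal(attr(a, "energy_eV") %% 62.5, 0)
})

test_that("1-ps yields match the branching expectation", {
  spec <- particle_spec("ion", 10, 30, 1)
  br <- default_branching()
  cp <- attr(br, "class_probs")
  # expected products per event: OH from every ionization plus the two
  # excitation channels; e_aq from ionizations only
  expect_per_event <- c(
    OH = unname(cp["ionization"] + cp["excitation"] * (0.5 + 0.15 * 2)),
    e_aq = unname(cp["ionization"]))
  n <- 60
  g_oh <- g_e <- numeric(n)
  for (s in seq_len(n)) {
    inv <- generate_track(spec, seed = s)
    E <- attr(inv, "energy_eV")
    g_oh[s] <- sum(inv$species == "OH") / E * 100
    g_e[s] <- sum(inv$species == "e_aq") / E * 100
  }
  exp_g <- expect_per_event / 62.5 * 100
  expect_lt(abs(mean(g_oh) - exp_g["OH"]), 3 * sd(g_oh) / sqrt(n))
  expect_lt(abs(mean(g_e) - exp_g["e_aq"]), 3 * sd(g_e) / sqrt(n))
})

test_that("transverse tail places the configured fraction far from the axis", {
  spec <- particle_spec("ion", 10, 30, 2)
  rad <- radial_profile(core_sd_nm = 2, tail_fraction = 0.05,
                        tail_rmin_nm = 5, tail_rmax_nm = 1000)
  ev <- do.call(rbind, lapply(1:20, function(s)
    sample_primary_events(spec, radial = rad, seed = s)))
  r <- sqrt(ev$x_nm^2 + ev$y_nm^2)
  # log-uniform tail: P(r > 500) = 0.05 * ln(2) / ln(200)
  p_exp <- 0.05 * log(2) / log(200)
  expect_lt(abs(mean(r > 500) - p_exp), 3 * sqrt(p_exp / length(r)))
  expect_gt(max(r), 500)  # the tail reaches beyond the 500 nm radius
})
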