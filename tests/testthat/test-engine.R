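# Brownian dynamics / reaction engine: diffusion statistics, reaction
# mechanics, activation contract, schedule behaviour.

test_that("diffusion displaces active molecules with sd sqrt(2 D dt)", {
  sp <- abc_species(Da = 5e-3)
  n <- 1e5
  inv <- inventory_at(rep("A", n), 0, 0, seq_len(n) * 10)
  st <- simulation_state(list(inv), species = sp)

  st0 <- diffuse(st, 0, species = sp, seed = 5)
  expect_identical(st0$molecules, st$molecules)  # dt = 0: unchanged

  st1 <- diffuse(st, 0.1, species = sp, seed = 5)
  dx <- st1$molecules$x_nm - st$molecules$x_nm
  v_exp <- 2 * 5e-3 * 0.1
  expect_lt(abs(var(dx) - v_exp), 3 * v_exp * sqrt(2 / n))
  expect_lt(abs(mean(dx)), 3 * sqrt(v_exp / n))
})

test_that("inactive molecules never move nor react", {
  sp <- abc_species()
  inv_a <- inventory_at("A", 0, 0, 0)
  inv_b <- inventory_at("B", 0.1, 0, 0)  # within any radius of A
  st <- simulation_state(list(inv_a, inv_b), active = c(TRUE, FALSE),
                         species = sp)
  st1 <- diffuse(st, 100, species = sp, seed = 3)
  expect_equal(st1$molecules$x_nm[2], 0.1)  # frozen under diffusion
  st2 <- react(st, dt = 1, reactions = abc_reaction(radius = 0.5),
               species = sp, seed = 3)
  expect_equal(nrow(st2$molecules), 2)      # no reaction with a frozen partner
  expect_equal(sum(st2$counters$produced), 0)
})

test_that("a reactive pair within the radius reacts to a midpoint product", {
  sp <- default_species()
  rx <- default_reactions()
  inv <- make_fixture("two_oh", r0 = 0.05)
  st <- simulation_state(list(inv))
  st1 <- react(st, dt = 0, reactions = rx, seed = 1)
  expect_equal(st1$molecules$species, "H2O2")
  expect_equal(st1$molecules$x_nm, 0.025)  # midpoint of (0, 0.05)
  expect_equal(st1$rlog$channel, "OH + OH -> H2O2")

  # hydronium + solvated electron within radius -> a single H atom
  inv2 <- make_fixture("isolated_pair", r0 = 0.05)
  st2 <- react(simulation_state(list(inv2)), dt = 0, reactions = rx, seed = 1)
  expect_equal(st2$molecules$species, "H")

  # no channel between the pair: nothing happens even at distance 0
  inv3 <- inventory_at(c("H2", "OH-"), c(0, 0), 0, 0)
  st3 <- react(simulation_state(list(inv3), species = sp), dt = 0,
               reactions = rx, seed = 1)
  expect_setequal(st3$molecules$species, c("H2", "OH-"))
})

test_that("each molecule reacts at most once per step, closest pair first", {
  sp <- default_species()
  rx <- default_reactions()
  # three OH radicals in a row: only the closest pair (0.02 apart) reacts
  inv <- inventory_at(rep("OH", 3), c(0, 0.05, 0.07), 0, 0)
  st <- react(simulation_state(list(inv), species = sp), dt = 0,
              reactions = rx, seed = 1)
  expect_equal(sort(st$molecules$species), c("H2O2", "OH"))
  expect_equal(st$molecules$x_nm[st$molecules$species == "OH"], 0)
})

test_that("evolution over empty or inert states returns flat counts", {
  sp <- abc_species()
  st <- simulation_state(list(), species = sp)
  res <- evolve(st, 10, c(1, 5, 10), reactions = abc_reaction(),
                species = sp, seed = 1)
  expect_true(all(res$counts$N == 0))

  # a single molecule with no partner survives at every log time
  inv <- inventory_at("A", 0, 0, 0)
  res1 <- evolve(simulation_state(list(inv), species = sp), 1e4,
                 c(1, 10, 100, 1e4), reactions = abc_reaction(),
                 species = sp, seed = 2)
  expect_equal(res1$counts$N[res1$counts$species == "A"], rep(1L, 4))
})

test_that("evolve is reproducible given the seed", {
  inv <- make_fixture("mini_track", seed = 3)
  a <- evolve(simulation_state(list(inv)), 100, c(1, 10, 100), seed = 11)
  b <- evolve(simulation_state(list(inv)), 100, c(1, 10, 100), seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$state$molecules, b$state$molecules)
  c <- evolve(simulation_state(list(inv)), 100, c(1, 10, 100), seed = 12)
  expect_false(identical(a$state$molecules, c$state$molecules))
})

test_that("the timestep schedule is bounded and non-decreasing", {
  sch <- timestep_schedule()
  expect_equal(intertrack:::schedule_dt(sch, c(0, 999, 1e3, 9999, 1e4, 1e6)),
               c(0.1, 0.1, 1, 1, 10, 10))
  expect_error(timestep_schedule(breaks = c(1, Inf), dts = c(10, 1)),
               "non-decreasing")
  expect_error(timestep_schedule(breaks = Inf, dts = 50), "within")
  expect_error(timestep_schedule(breaks = Inf, dts = 0.01), "within")
})

test_that("counting identity: produced minus consumed matches final counts", {
  inv <- make_fixture("mini_track", seed = 8)
  st0 <- simulation_state(list(inv))
  res <- evolve(st0, 1e4, c(1e4), seed = 21)
  n0 <- table(factor(inv$species, levels = default_species()$species))
  nf <- table(factor(res$state$molecules$species,
                     levels = default_species()$species))
  delta <- res$state$counters$produced - res$state$counters$consumed
  expect_equal(as.integer(nf), as.integer(n0) + delta)
})
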