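# Two-track scheduling: freeze/activate semantics, energy step function,
# activation-instant counting identity, NI reference.

test_that("replicate count follows the target-energy normalization", {
  expect_equal(replicate_count(2e6, particle_spec("i", 1, 30, 2)), 34L)
  expect_equal(replicate_count(2e6, particle_spec("i", 1, 100, 2)), 10L)
  # target equal to one track's energy -> a single replicate
  expect_equal(replicate_count(60e3, particle_spec("i", 1, 30, 2)), 1L)
})

pr <- run_pair(fast_particle(let = 10, depth = 0.1), dx = 5, dt_delay = 100,
               seed = 31, t_chem = 1e4)

test_that("E(t) is a two-step function jumping at 1 ps and at the delay", {
  gs <- pr$gseries
  before <- gs$E_eV[gs$time_ps < 100 - 1e-9]
  after <- gs$E_eV[gs$time_ps >= 100 - 1e-9]
  expect_true(all(before == pr$E1))
  expect_true(all(after == pr$E1 + pr$E2))
})

test_that("frozen track-2 molecules contribute nothing before activation", {
  gs <- pr$gseries
  n_1ps <- setNames(gs$N[abs(gs$time_ps - 1) < 1e-9],
                    gs$species[abs(gs$time_ps - 1) < 1e-9])
  inv1 <- pr$inv[[1]]
  tab1 <- table(factor(inv1$species, levels = names(n_1ps)))
  expect_equal(n_1ps, setNames(as.integer(tab1), names(n_1ps)))
  expect_gt(sum(pr$n2_at_1ps), 0)  # track 2 exists, it is just invisible
})

test_that("the activation-instant G equals (N1(dt) + N2(1ps)) / (E1 + E2)", {
  g_act <- g_at(pr$gseries, pr$t_act)
  expected <- peak_drop_expectation(pr$n1_at_act[names(g_act)],
                                    pr$n2_at_1ps[names(g_act)],
                                    pr$E1, pr$E2)
  expect_equal(g_act, expected, tolerance = 1e-12)
})

test_that("element and charge balances close over a full pair run", {
  sp <- default_species()
  init <- rbind(pr$inv[[1]], pr$inv[[2]])
  t_init <- balance_totals(init, NULL, sp)
  t_final <- balance_totals(pr$state$molecules, pr$rlog, sp)
  expect_identical(t_init, t_final)
})

test_that("a zero delay merges both tracks from the chemical-stage start", {
  pr0 <- run_pair(fast_particle(let = 10, depth = 0.1), dx = 0, dt_delay = 0,
                  seed = 55, t_chem = 1e3)
  expect_equal(pr0$t_act, 1)
  gs <- pr0$gseries
  expect_true(all(gs$E_eV == pr0$E1 + pr0$E2))
  n_1ps <- sum(gs$N[abs(gs$time_ps - 1) < 1e-9])
  expect_equal(n_1ps, nrow(pr0$inv[[1]]) + nrow(pr0$inv[[2]]))
})

test_that("NI reference is the mean of the two readout ages", {
  # synthetic series: G(1e6) = 0.9, G(1e6 + dt) = 1.1 -> reference 1.0
  gs <- data.frame(time_ps = c(1e6, 1.5e6), species = "OH",
                   N = c(9L, 11L), E_eV = 1000)
  gs$G <- gs$N / gs$E_eV * 100
  expect_equal(unname(ni_reference(gs, dt_delay = 5e5)),
               (1.1 + 0.9) / 2)
  # dt = 0 reduces to the 1 us value
  expect_equal(unname(ni_reference(gs, dt_delay = 0)), 0.9)
})

test_that("g_at reads the nearest logged time at or before the target", {
  gs <- data.frame(time_ps = c(1, 10, 100), species = "OH",
                   N = c(5L, 4L, 3L), E_eV = 100)
  gs$G <- gs$N
  expect_equal(unname(g_at(gs, 99)), 4)
  expect_equal(unname(g_at(gs, 100)), 3)
  expect_error(g_at(gs, 0.5), "no logged time")
})

test_that("an NI run combines two independent tracks", {
  ni <- run_ni(fast_particle(let = 10, depth = 0.1), dt_delay = 10,
               seed = 99, t_chem = 1e3)
  gs <- ni$gseries
  expect_true(all(gs$E_eV == ni$E1 + ni$E2))
  expect_equal(gs$N, ni$track1$counts$N + ni$track2$counts$N)
})
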