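# Reaction tables: Smoluchowski radii, channel balance validation.

test_that("smoluchowski radius follows the diffusion-controlled closure", {
  expect_equal(smoluchowski_radius(0, 5e-3, 5e-3), 0)
  # hand evaluation: 7e9 * 1.6606e-12 / (4 pi 1e-2) = 0.0925 nm
  expect_equal(smoluchowski_radius(7.0e9, 5e-3, 5e-3),
               7.0e9 * 1.6606e-12 / (4 * pi * 1e-2))
  expect_equal(smoluchowski_radius(7.0e9, 5e-3, 5e-3), 0.0925, tolerance = 1e-3)
  # linear in k
  expect_equal(smoluchowski_radius(2e10, 3e-3, 2e-3),
               2 * smoluchowski_radius(1e10, 3e-3, 2e-3))
  expect_error(smoluchowski_radius(1e9, 0, 0), "immobile")
})

test_that("the default reaction set passes channel-balance validation", {
  rx <- default_reactions()
  expect_s3_class(rx, "reaction_table")
  expect_equal(nrow(rx), 9)
  # implicit water bookkeeping: e_aq + e_aq consumes two waters,
  # H3O+ + OH- emits two, e_aq + H3O+ emits one
  h2o <- setNames(rx$h2o, rx$name)
  expect_equal(unname(h2o["e_aq + e_aq -> H2 + 2 OH-"]), -2L)
  expect_equal(unname(h2o["H3O+ + OH- -> 2 H2O"]), 2L)
  expect_equal(unname(h2o["e_aq + H3O+ -> H"]), 1L)
  expect_true(all(rx$radius_nm > 0))
})

test_that("unbalanced or ill-formed channels are rejected by name", {
  sp <- default_species()
  bad <- data.frame(name = "OH + OH -> H2", r1 = "OH", r2 = "OH",
                    k_M_s = 1e9, stringsAsFactors = FALSE)
  bad$products <- list("H2")
  expect_error(reaction_table(bad, sp), "OH \\+ OH -> H2")

  unk <- data.frame(name = "OH + X -> H2O2", r1 = "OH", r2 = "X",
                    k_M_s = 1e9, stringsAsFactors = FALSE)
  unk$products <- list("H2O2")
  expect_error(reaction_table(unk, sp), "unknown species")
})

test_that("an explicit radius column overrides the derived radius", {
  rx <- abc_reaction(radius = 0.5)
  expect_equal(rx$radius_nm, 0.5)
})
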