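# Yield analysis: G-values, peak/drop arithmetic, radial statistics,
# significance testing, grid assembly.

test_that("G-value arithmetic", {
  expect_equal(gvalue(120, 6000), 2.0)
  expect_equal(gvalue(0, 500), 0)
  expect_equal(gvalue(100, 10000), 1.0)
  expect_error(gvalue(10, 0), "E")
})

test_that("peak/drop expectation mixes the two tracks' ages", {
  expect_equal(peak_drop_expectation(50, 80, 5000, 5000), 1.3)
  # secondary species arrive with no fresh molecules: drop toward half
  expect_equal(peak_drop_expectation(40, 0, 5000, 5000), 0.4)
  # symmetric tracks: equals the plain G-value of either
  expect_equal(peak_drop_expectation(30, 30, 4000, 4000), gvalue(30, 4000))
})

test_that("normalized 1-us difference", {
  expect_equal(delta_g_mus(0.9, 1.0), -0.1)
  expect_equal(delta_g_mus(1.0, 1.0), 0)
  # reference from its two components then the relative difference
  ref <- (1.1 + 0.9) / 2
  expect_equal(delta_g_mus(1.2, ref), 0.2)
  expect_error(delta_g_mus(1, 0), "> 0")
})

test_that("r80 is the 80% order statistic of radial distances", {
  expect_equal(r80(1:10), 8)
  expect_equal(r80(rep(0, 5)), 0)
  # uniform disk of radius Rd: r80 -> sqrt(0.8) Rd for large n
  set.seed(17)
  Rd <- 50
  r <- Rd * sqrt(runif(2e5))
  expect_equal(r80(r), sqrt(0.8) * Rd, tolerance = 0.005)
  # data-frame input measures transverse distance to the given axis
  df <- data.frame(x_nm = c(3, 0), y_nm = c(0, 4))
  expect_equal(r80(df, q = 1), 4)
})

test_that("fraction beyond a radius", {
  expect_equal(fraction_beyond(c(rep(10, 7), rep(600, 3))), 30)
  expect_equal(fraction_beyond(rep(1, 4)), 0)
  expect_equal(fraction_beyond(rep(1000, 4)), 100)
})

test_that("significance handles identical, disjoint and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(significance(x, x), 1)
  set.seed(4)
  a <- rnorm(10, 0, 0.1); b <- rnorm(10, 10, 0.1)
  expect_lt(significance(a, b), 1e-6)
  expect_equal(significance(rep(2, 5), rep(2, 5)), 1)
  expect_equal(significance(rep(1, 5), rep(2, 5)), 0)
  expect_true(is.na(significance(1, c(1, 2))))
})

test_that("t-test type-I rate is calibrated near 5% at alpha 0.05", {
  set.seed(2024)
  n_sim <- 2000
  rej <- vapply(seq_len(n_sim), function(i)
    significance(rnorm(30), rnorm(30)) < 0.05, logical(1))
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("build_grid assembles per-condition statistics", {
  p <- fast_particle(let = 10, depth = 0.05)
  cr <- run_condition(p, dx = 2, dt_delay = 1, replicates = 3, seed = 8,
                      t_chem = 1e3)
  g <- build_grid(list(cr))
  expect_s3_class(g, "delta_g_grid")
  expect_setequal(g$species, default_species()$species)
  expect_true(all(c("delta_g", "se", "n", "p") %in% names(g)))
  expect_true(all(g$n == 3))
  # finite wherever the NI reference is populated
  expect_true(all(is.finite(g$delta_g[!is.na(g$g_ni)])))
  expect_true(all(g$p >= 0 & g$p <= 1, na.rm = TRUE))
})
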