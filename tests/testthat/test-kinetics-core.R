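test_that("rate equations reproduce hand-evaluated derivatives", {
  p <- rate_parameters(1e7, 0.14, 0.56)

  # empty system: no species, no flux
  d0 <- rate_equations(species_state(0, 0), p)
  expect_identical(unname(unclass(d0)), rep(0, 5))

  # binding flux only: 1e7 * 2e-8 * 5e-9 = 1e-9 M/s into t_only
  d1 <- rate_equations(species_state(input = 2e-8, probe = 5e-9), p)
  expect_equal(d1[["t_only"]], 1e-9)
  expect_equal(d1[["F"]], 0)
  expect_equal(d1[["input"]], -1e-9)
  expect_equal(d1[["probe"]], d1[["input"]])

  # intermediate decay only, with the single-bulge fitted rates
  d2 <- rate_equations(species_state(0, 0, t_only = 1e-9), p)
  expect_equal(d2[["F"]], 5.6e-10)
  expect_equal(d2[["Q"]], d2[["F"]])
  expect_equal(d2[["input"]], 1.4e-10)
  expect_equal(d2[["t_only"]], -(1.4e-10 + 5.6e-10))
})

test_that("parameter and state validation rejects unphysical inputs", {
  expect_error(rate_parameters(-1, 0.1, 0.1), "non-negative")
  expect_error(rate_parameters(1e11, 0.1, 0.1), "ceiling")
  expect_error(species_state(-1e-9, 5e-9), "negative concentration")
  p <- rate_parameters(1e7, 0.1, 0.1)
  expect_error(simulate_deterministic(p, 5e-9, 1e-7, c(1, 2, 3)), "start at 0")
  expect_error(simulate_deterministic(p, 5e-9, 1e-7, c(0, 2, 1)),
               "strictly increasing")
  expect_error(simulate_deterministic(p, -5e-9, 1e-7, c(0, 1, 2)), "positive")
})

test_that("deterministic traces conserve totals, stay monotone, and saturate", {
  p <- rate_parameters(1e7, 0.14, 0.56)
  for (input0 in c(2e-8, 1e-6)) {
    tr <- simulate_deterministic(p, 5e-9, input0, seq(0, 120, by = 0.5))
    sp <- attr(tr, "species")
    probe_tot <- sp[, "probe"] + sp[, "t_only"] + sp[, "F"]
    input_tot <- sp[, "input"] + sp[, "t_only"] + sp[, "F"]
    expect_lt(max(abs(probe_tot - 5e-9)) / 5e-9, 1e-6)
    expect_lt(max(abs(input_tot - input0)) / input0, 1e-6)
    expect_equal(sp[, "Q"], sp[, "F"])
    expect_true(all(diff(tr$signal) >= -1e-9))
    expect_lt(abs(tr$signal[length(tr$signal)] - 1), 1e-3)
  }

  # no product channel: signal identically zero
  tr0 <- simulate_deterministic(rate_parameters(1e7, 0.14, 0), 5e-9, 1e-6,
                                seq(0, 60, by = 1))
  expect_identical(max(abs(tr0$signal)), 0)
})

test_that("stiff integration matches the closed-form excess-input oracle", {
  p <- rate_parameters(1e7, 0.14, 0.56)
  tm <- seq(0, 30, by = 0.1)
  tr <- simulate_deterministic(p, 5e-9, 1e-6, tm)
  expect_lt(max(abs(tr$signal - analytic_excess_input(p, 1e-6, tm))), 1e-3)
})

test_that("closed-form oracle obeys its analytic limits", {
  p <- rate_parameters(1e7, 0.14, 0.56)
  expect_identical(analytic_excess_input(p, 1e-6, 0), 0)

  # k_off = 0: textbook irreversible sequential reaction A -> B -> C
  pirr <- rate_parameters(1e7, 0, 0.56)
  c0 <- 1e-6; ka <- 1e7 * c0; kb <- 0.56
  tm <- seq(0, 20, by = 0.25)
  textbook <- 1 - (kb * exp(-ka * tm) - ka * exp(-kb * tm)) / (kb - ka)
  expect_equal(analytic_excess_input(pirr, c0, tm), textbook, tolerance = 1e-10)

  # k_bm -> infinity: binding-limited, 1 - exp(-k_on c0 t)
  pfast <- rate_parameters(1e7, 0.14, 1e6)
  expect_equal(analytic_excess_input(pfast, c0, tm), 1 - exp(-ka * tm),
               tolerance = 1e-4)

  # repeated eigenvalue (k_off = 0, k_on c0 = k_bm): limiting formula,
  # continuous against a nearly degenerate neighbour
  pdeg <- rate_parameters(1e7, 0, 1)        # ka = kbm = 1 at c0 = 1e-7
  pnear <- rate_parameters(1e7, 1e-7, 1)
  tm2 <- seq(0, 10, by = 0.1)
  exact_deg <- 1 - exp(-tm2) * (1 + tm2)    # double-root solution by hand
  expect_equal(analytic_excess_input(pdeg, 1e-7, tm2), exact_deg,
               tolerance = 1e-9)
  expect_equal(analytic_excess_input(pnear, 1e-7, tm2),
               analytic_excess_input(pdeg, 1e-7, tm2), tolerance = 1e-5)
})

test_that("signal is monotone in input concentration and saturates at k_eff", {
  p <- rate_parameters(1e7, 0.14, 0.56)
  tm <- seq(0, 40, by = 0.5)
  sigs <- lapply(c(2e-8, 5e-8, 2e-7, 1e-6), function(c0)
    simulate_deterministic(p, 5e-9, c0, tm)$signal)
  for (i in seq_len(length(sigs) - 1L))
    expect_true(all(sigs[[i + 1L]] - sigs[[i]] >= -1e-9))

  # deep saturation: trace approaches 1 - exp(-k_eff t)
  c0 <- 1e-5
  ka <- p$k_on * c0
  keff <- p$k_bm * ka / (ka + p$k_off + p$k_bm)
  tr <- simulate_deterministic(p, 5e-9, c0, seq(0, 10, by = 0.05))
  expect_lt(max(abs(tr$signal - (1 - exp(-keff * tr$times)))), 0.02)
})
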