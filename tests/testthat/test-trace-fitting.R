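test_that("noiseless single-bulge panel refits to the generating rates", {
  truth <- rate_parameter_presets()[["1bulge_present"]]
  fit <- global_fit(noiseless_panel("1bulge_present"), fixed_kon = 1e7,
                    n_starts = 16, seed = 1)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$estimates[["k_off"]], truth$k_off), 0.01)
  expect_lt(rel_err(fit$estimates[["k_bm"]], truth$k_bm), 0.01)
  expect_lt(fit$objective / fit$n_points, 1e-8)
  # optimizer sanity: returned optimum beats every tried start
  expect_true(all(fit$objective <= fit$start_objectives + 1e-8))
})

test_that("a generator with k_bm = k_off is recovered with unit ratio", {
  truth <- rate_parameters(1e7, 0.3, 0.3)
  panel <- generate_series(truth, experiment_design(replicates = 1),
                           noise_model(signal_sd = 0))
  fit <- global_fit(panel, n_starts = 9, seed = 2)
  expect_lt(abs(fit$estimates[["k_bm"]] / fit$estimates[["k_off"]] - 1), 0.01)
})

test_that("refitting curves simulated from a fit is a fixed point", {
  fit1 <- global_fit(noiseless_panel("1bulge_present"), n_starts = 9, seed = 1)
  regen <- generate_series(
    rate_parameters(1e7, fit1$estimates[["k_off"]], fit1$estimates[["k_bm"]]),
    experiment_design(replicates = 1), noise_model(signal_sd = 0))
  fit2 <- global_fit(regen, n_starts = 9, seed = 1)
  expect_lt(rel_err(fit2$estimates[["k_off"]], fit1$estimates[["k_off"]]), 1e-3)
  expect_lt(rel_err(fit2$estimates[["k_bm"]], fit1$estimates[["k_bm"]]), 1e-3)
})

test_that("estimates are invariant to time-grid density", {
  truth <- rate_parameter_presets()[["1bulge_present"]]
  des_coarse <- experiment_design(duration = 48, sample_interval = 0.8,
                                  replicates = 1)
  des_fine <- experiment_design(duration = 48, sample_interval = 0.4,
                                replicates = 1)
  f1 <- global_fit(generate_series(truth, des_coarse, noise_model(signal_sd = 0)),
                   n_starts = 9, seed = 1)
  f2 <- global_fit(generate_series(truth, des_fine, noise_model(signal_sd = 0)),
                   n_starts = 9, seed = 1)
  expect_lt(rel_err(f1$estimates[["k_off"]], f2$estimates[["k_off"]]), 1e-3)
  expect_lt(rel_err(f1$estimates[["k_bm"]], f2$estimates[["k_bm"]]), 1e-3)
})

test_that("a single-concentration series is flagged as weakly identified", {
  panel <- noiseless_panel("1bulge_present")
  concs <- vapply(panel$traces, function(tr) tr$input_conc, numeric(1))
  one_conc <- panel$traces[concs == max(concs)]
  fit <- global_fit(one_conc, n_starts = 4, seed = 1)
  expect_true(fit$identifiability_warning)
  full <- global_fit(panel, n_starts = 4, seed = 1)
  expect_false(full$identifiability_warning)
})

test_that("bootstrap CIs collapse on noiseless data and are seed-reproducible", {
  panel <- generate_series(rate_parameter_presets()[["1bulge_present"]],
                           experiment_design(duration = 48, sample_interval = 1.2,
                                             replicates = 1),
                           noise_model(signal_sd = 0))
  fit <- global_fit(panel, n_starts = 4, seed = 1)
  fit <- bootstrap_ci(panel, fit, n_boot = 100, seed = 7)
  widths <- fit$ci95[, "upper"] - fit$ci95[, "lower"]
  expect_lt(widths[["k_off"]] / fit$estimates[["k_off"]], 1e-4)
  expect_lt(widths[["k_bm"]] / fit$estimates[["k_bm"]], 1e-4)
  expect_true(all(fit$ci95[, "lower"] <= fit$estimates),
              info = "interval brackets the estimate")
  expect_true(all(fit$estimates <= fit$ci95[, "upper"]))

  fit_b <- bootstrap_ci(panel, global_fit(panel, n_starts = 4, seed = 1),
                        n_boot = 100, seed = 7)
  expect_identical(fit$ci95, fit_b$ci95)
  expect_error(bootstrap_ci(panel, fit, n_boot = 50), ">= 100")
})

test_that("doubling the noise does not shrink bootstrap intervals", {
  truth <- rate_parameter_presets()[["1bulge_present"]]
  des <- experiment_design(duration = 48, sample_interval = 1.2, replicates = 1)
  width <- function(sd) {
    panel <- generate_series(truth, des, noise_model(signal_sd = sd, seed = 31))
    fit <- bootstrap_ci(panel, global_fit(panel, n_starts = 4, seed = 1),
                        n_boot = 100, seed = 5)
    fit$ci95[, "upper"] - fit$ci95[, "lower"]
  }
  w1 <- width(0.005); w2 <- width(0.01)
  expect_true(all(w2 >= w1))
})

test_that("k_on sensitivity scan handles single values and flags binding-limited data", {
  panel <- noiseless_panel("1bulge_present")
  solo <- kon_sensitivity(panel, kon_values = 1e7, n_starts = 4, seed = 1)
  expect_identical(solo$max_relative_deviation, 0)
  expect_identical(solo$regime_flag, "ok")

  # k_bm >> k_on * c for every concentration: the data carry no information
  # about k_bm, so the estimate must swing with the assumed k_on
  bl_truth <- rate_parameters(1e7, 0.1, 50)
  bl <- generate_series(bl_truth, experiment_design(replicates = 1),
                        noise_model(signal_sd = 0))
  scan <- kon_sensitivity(bl, kon_values = c(1e6, 1e7, 1e8),
                          n_starts = 6, seed = 1)
  expect_gt(scan$max_relative_deviation, 0.25)
  expect_identical(scan$regime_flag, "non_saturated")
})
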