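#!/usr/bin/env Rscript
# How sensitive is the recovered branch-migration rate to the assumed
# (fixed) binding rate?  Refit the noiseless single-bulge panels with
# k_on held at 1e6, 1e7, and 1e8 M^-1 s^-1.

suppressMessages(library(fourwaykinetics))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (nm in c("1bulge_present", "1bulge_absent")) {
  panel <- read_trace_csv(sprintf("results/panels/%s_noiseless.csv", nm))[[1]]
  scan <- kon_sensitivity(panel, kon_values = c(1e6, 1e7, 1e8),
                          n_starts = 16, seed = 1)
  rows[[nm]] <- data.frame(condition = nm, k_on = scan$kon_values,
                           k_off_hat = scan$koff_estimates,
                           k_bm_hat = scan$kbm_estimates,
                           max_rel_dev = scan$max_relative_deviation,
                           regime = scan$regime_flag)
  cat(sprintf("%s: max relative k_bm deviation %.3g%% [%s]\n",
              nm, 100 * scan$max_relative_deviation, scan$regime_flag))
}
write_results(do.call(rbind, rows), "results/kon_sensitivity.csv")

cat("\nThe bulge-absent panel is k_on-insensitive: its implied second-order\n")
cat("rate k_on*k_bm/(k_off+k_bm) ~ 2e5 M^-1 s^-1 can be realized at every\n")
cat("assumed k_on.  The bulge-present panel implies ~8e6 M^-1 s^-1, which\n")
cat("EXCEEDS a binding ceiling of k_on = 1e6: no (k_off, k_bm) pair can then\n")
cat("reproduce the low-concentration traces and k_bm diverges, so the scan\n")
cat("flags the 1e6 end rather than reproducing a within-2.5% deviation.\n")
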