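#!/usr/bin/env Rscript
# Lattice model of bulge diffusion and branch migration: stationary
# occupancy/free-energy profiles of the frozen-junction chain (the
# bulge-diffusion observable), cross-checked against Gillespie sampling,
# and the mean first-passage time to complete displacement as bulge
# mobility varies.

suppressMessages(library(fourwaykinetics))
dir.create("results", showWarnings = FALSE)

## Frozen-junction occupancy, unbiased hops: one bulge over 0..20,
## two bulges over 0..21 (the displacement-domain coordinates).
for (nb in 1:2) {
  cfg <- walk_config(20, n_bulges = nb, freeze_junction = TRUE,
                     absorb_at_end = FALSE, seed = 7)
  prof <- stationary_exact(cfg)
  write_results(as.data.frame(prof), sprintf("results/walk_profile_%dbulge.csv", nb))
  emp <- occupancy_profile(gillespie_run(cfg, t_max = 5000))
  cat(sprintf("%d-bulge frozen chain: %d positions, max |MC - exact| = %.3g\n",
              nb, nrow(prof), max(abs(emp$probability - prof$probability))))
}

## An end-attracting energy table reproduces a bimodal profile
## (junction-proximal and far-end preference) qualitatively.
M <- 20
energy <- 0.6 * pmin(0:M, M - (0:M)) / (M / 2)   # wells at both ends
cfgb <- walk_config(20, n_bulges = 1, freeze_junction = TRUE,
                    absorb_at_end = FALSE, energy = energy, seed = 7)
profb <- stationary_exact(cfgb)
write_results(as.data.frame(profb), "results/walk_profile_biased.csv")
cat(sprintf("biased chain: P(0) = %.3f, P(%d) = %.3f, interior min = %.3f\n",
            profb$probability[1], M, profb$probability[M + 1],
            min(profb$probability)))

## Displacement kinetics: bulge mobility suspends the assisted pathway,
## so the mean first-passage time grows with the hop rate.
rows <- lapply(c(0, 0.2, 0.5, 1, 2, 5, 10), function(hop) {
  cfg <- walk_config(10, n_bulges = 1, bulge_domain_length = 10,
                     rate_half_step = 10, rate_migration_nobulge = 0.1,
                     rate_bulge_hop = hop)
  m <- mean_first_passage(cfg)
  data.frame(rate_bulge_hop = hop, mfpt_s = m$mfpt, eff_rate = m$rate)
})
tab <- do.call(rbind, rows)
write_results(tab, "results/walk_mfpt_vs_hop.csv")
cat("\nMFPT to complete displacement vs bulge hop rate:\n")
print(transform(tab, mfpt_s = signif(mfpt_s, 4), eff_rate = signif(eff_rate, 4)))
cat("\nFaster bulge diffusion away from the junction slows displacement,\n")
cat("mirroring the loss of bulge-assisted acceleration when the bulge\n")
cat("is not at the junction core.\n")
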