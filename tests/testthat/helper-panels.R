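# Shared synthetic panels, memoized so repeated tests pay for one simulation.

.panel_cache <- new.env(parent = emptyenv())

noiseless_panel <- function(preset, replicates = 1L) {
  key <- paste(preset, replicates, sep = "|")
  if (is.null(.panel_cache[[key]])) {
    truth <- rate_parameter_presets()[[preset]]
    .panel_cache[[key]] <- generate_series(
      truth,
      experiment_design(replicates = replicates,
                        bulge_count = attr(truth, "bulge_count")),
      noise_model(signal_sd = 0)
    )
  }
  .panel_cache[[key]]
}

rel_err <- function(est, truth) abs(est - truth) / truth
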