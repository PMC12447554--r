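#' Design of a synthetic fluorescence experiment
#'
#' Describes one panel of the fluorescence experiment: 5 nM probe duplex
#' titrated with input duplex across six concentrations, monitored over
#' time, in a given duplex design (bulge count, toehold length), with
#' replicate wells.
#'
#' @param probe0 Probe-duplex concentration (M); default 5 nM.
#' @param input_concs Input-duplex concentrations (M); default
#'   20, 50, 100, 200, 500, 1000 nM.
#' @param duration Run length (s).  `NULL` (default) lets
#'   [generate_series()] pick a horizon long enough for the slowest
#'   trace (lowest concentration) to reach >= 95% completion.
#' @param sample_interval Sampling interval (s); `NULL` defaults to
#'   `duration / 300`.
#' @param bulge_count Bulges in the design: 0, 1, or 2.
#' @param toehold_length_nt Toehold length (nt), 3..6; default 5.
#' @param replicates Independent repeats per concentration; default 2.
#' @param label Optional condition label.
#' @return An object of class `fw_design`.
#' @export
experiment_design <- function(probe0 = 5e-9,
                              input_concs = c(20, 50, 100, 200, 500, 1000) * 1e-9,
                              duration = NULL, sample_interval = NULL,
                              bulge_count = 1L, toehold_length_nt = 5L,
                              replicates = 2L, label = NULL) {
  if (!is.numeric(probe0) || probe0 <= 0) .fw_stop("'probe0' must be positive (molar)")
  if (!is.numeric(input_concs) || length(input_concs) < 1L || any(input_concs <= 0))
    .fw_stop("'input_concs' must be positive (molar)")
  if (!is.null(duration) && (!is.numeric(duration) || duration <= 0))
    .fw_stop("'duration' must be positive (seconds)")
  if (!is.null(sample_interval)) {
    if (!is.numeric(sample_interval) || sample_interval <= 0)
      .fw_stop("'sample_interval' must be positive (seconds)")
    if (!is.null(duration) && sample_interval >= duration)
      .fw_stop("'sample_interval' must be smaller than 'duration'")
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) .fw_stop("'replicates' must be >= 1")
  condition <- .fw_check_condition(list(
    bulge_count = bulge_count, toehold_length_nt = toehold_length_nt,
    label = if (is.null(label)) NA_character_ else label))
  structure(list(probe0 = probe0, input_concs = sort(input_concs),
                 duration = duration, sample_interval = sample_interval,
                 condition = condition, replicates = replicates),
            class = "fw_design")
}

#' Measurement-noise model for synthetic traces
#'
#' Additive iid Gaussian noise on the normalized signal (default sd 0.01,
#' matching the small, roughly homoscedastic replicate spread of the
#' experiments), plus an optional per-replicate multiplicative lognormal
#' error on the probe concentration emulating pipetting/truncated-strand
#' errors (off by default).
#'
#' @param signal_sd Additive Gaussian sd on the normalized signal, >= 0.
#' @param probe_error_cv Coefficient of variation of the per-replicate
#'   probe-concentration multiplier, >= 0 (0 disables it).
#' @param seed Integer seed.
#' @return An object of class `fw_noise`.
#' @export
noise_model <- function(signal_sd = 0.01, probe_error_cv = 0, seed = 1L) {
  if (!is.numeric(signal_sd) || signal_sd < 0) .fw_stop("'signal_sd' must be >= 0")
  if (!is.numeric(probe_error_cv) || probe_error_cv < 0)
    .fw_stop("'probe_error_cv' must be >= 0")
  structure(list(signal_sd = signal_sd, probe_error_cv = probe_error_cv,
                 seed = as.integer(seed)),
            class = "fw_noise")
}

## Horizon long enough for the slowest (lowest-concentration) trace to
## reach >= 95% completion: 6 / k_eff with the pseudo-first-order
## effective rate k_eff = k_bm k_a / (k_a + k_off + k_bm), padded because
## probe depletion at near-stoichiometric input slows the tail.
.fw_default_duration <- function(truth, design) {
  ka <- truth$k_on * min(design$input_concs)
  keff <- truth$k_bm * ka / (ka + truth$k_off + truth$k_bm)
  if (keff <= 0) .fw_stop("cannot choose a duration: k_bm or k_on is zero")
  6 / keff
}

#' Generate a synthetic fluorescence panel
#'
#' Simulates the deterministic two-step model for every (concentration,
#' replicate) cell of the design, applies the per-replicate probe
#' multiplier, adds iid Gaussian noise to the normalized signal, and
#' clips below 0.  Fully reproducible for a given `noise$seed`; the
#' generating truth travels with the returned set.
#'
#' @param truth A [rate_parameters()] object (the generating rates).
#' @param design An [experiment_design()].
#' @param noise A [noise_model()].
#' @return A [trace_set()] with attributes `truth`, `design`, `noise`.
#' @examples
#' truth <- rate_parameter_presets()[["1bulge_present"]]
#' panel <- generate_series(truth, experiment_design(replicates = 1),
#'                          noise_model(signal_sd = 0))
#' @export
generate_series <- function(truth, design = experiment_design(),
                            noise = noise_model()) {
  truth <- .fw_check_rates(truth)
  if (!inherits(design, "fw_design")) .fw_stop("'design' must be an fw_design")
  if (!inherits(noise, "fw_noise")) .fw_stop("'noise' must be an fw_noise")

  duration <- design$duration %||% .fw_default_duration(truth, design)
  interval <- design$sample_interval %||% (duration / 300)
  times <- seq(0, duration, by = interval)
  if (length(times) < 2L) .fw_stop("design yields fewer than 2 samples")

  set.seed(noise$seed)
  mult <- if (noise$probe_error_cv > 0) {
    sdlog <- sqrt(log1p(noise$probe_error_cv^2))
    exp(rnorm(design$replicates, mean = -sdlog^2 / 2, sd = sdlog))
  } else rep(1, design$replicates)

  traces <- list()
  for (r in seq_len(design$replicates)) {
    probe_r <- design$probe0 * mult[r]
    for (conc in design$input_concs) {
      tr <- simulate_deterministic(truth, probe_r, conc, times,
                                   condition = design$condition, replicate = r)
      tr$signal <- pmax(0, tr$signal + rnorm(length(times), sd = noise$signal_sd))
      ## the recorded concentration is the nominal one; the pipetting error
      ## is invisible to the experimenter (normalization uses the actual
      ## plateau, which simulate_deterministic already applied)
      tr$probe_conc <- design$probe0
      attr(tr, "species") <- NULL
      traces[[length(traces) + 1L]] <- tr
    }
  }
  set <- trace_set(traces)
  attr(set, "truth") <- truth
  attr(set, "design") <- design
  attr(set, "noise") <- noise
  set
}

`%||%` <- function(a, b) if (is.null(a)) b else a
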