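## Global least-squares fitting of the two-step model to trace panels.
##
## All fits run on log10(k_off), log10(k_bm) with k_on held fixed: the two
## free rates are positive and span ~5 decades across designs, so the log
## scale is both a positivity constraint and a sane metric for multi-start.

.fw_as_trace_list <- function(series) {
  if (inherits(series, "fw_trace_set")) return(series$traces)
  if (inherits(series, "fw_trace")) return(list(series))
  if (is.list(series) && length(series) > 0L &&
      all(vapply(series, inherits, logical(1L), "fw_trace")))
    return(series)
  .fw_stop("'series' must be an fw_trace_set, an fw_trace, or a list of fw_trace")
}

## Group traces into unique simulation tasks (same concentrations + grid)
## so replicate traces cost one ODE solve per objective evaluation.
.fw_sim_plan <- function(traces) {
  keys <- vapply(traces, function(tr)
    paste(tr$input_conc, tr$probe_conc, length(tr$times), tr$times[length(tr$times)],
          sep = "|"), character(1L))
  groups <- split(seq_along(traces), keys)
  lapply(groups, function(idx) {
    list(idx = idx,
         input_conc = traces[[idx[1L]]]$input_conc,
         probe_conc = traces[[idx[1L]]]$probe_conc,
         times = traces[[idx[1L]]]$times)
  })
}

## Residual vector (model - observed) pooled over all traces; integration
## failures are mapped to a large finite penalty so optimizers can retreat.
.fw_residual_fun <- function(traces, fixed_kon,
                             rtol = 1e-6, atol = 1e-13) {
  ## fitting integrates at tolerances well below the measurement noise
  ## (signal sd ~1e-2) but looser than the reporting tolerances, for speed
  plan <- .fw_sim_plan(traces)
  obs <- lapply(traces, function(tr) tr$signal)
  ## batch tasks sharing a time grid into one solver call each
  tkey <- vapply(plan, function(task)
    paste(length(task$times), task$times[length(task$times)], sep = "|"),
    character(1L))
  batches <- lapply(split(plan, tkey), function(tasks) {
    list(tasks = tasks,
         times = tasks[[1L]]$times,
         probe0s = vapply(tasks, `[[`, numeric(1L), "probe_conc"),
         input0s = vapply(tasks, `[[`, numeric(1L), "input_conc"))
  })
  function(logpar) {
    params <- rate_parameters(fixed_kon, 10^logpar[1L], 10^logpar[2L])
    res <- vector("list", length(traces))
    for (batch in batches) {
      sim <- .fw_integrate_multi(params, batch$probe0s, batch$input0s,
                                 batch$times, rtol = rtol, atol = atol)
      if (is.null(sim))
        sim <- matrix(1e3, length(batch$times), length(batch$tasks))
      for (b in seq_along(batch$tasks)) {
        for (i in batch$tasks[[b]]$idx) res[[i]] <- sim[, b] - obs[[i]]
      }
    }
    unlist(res, use.names = FALSE)
  }
}

## Deterministic multi-start grid: log-uniform over [1e-4, 1e4]^2 plus
## seeded Gaussian jitter (sd 0.15 decades).
.fw_start_grid <- function(n_starts, seed) {
  side <- ceiling(sqrt(n_starts))
  g <- seq(-4, 4, length.out = side)
  grid <- as.matrix(expand.grid(log_koff = g, log_kbm = g))[seq_len(n_starts), , drop = FALSE]
  set.seed(seed)
  grid + matrix(rnorm(2L * n_starts, sd = 0.15), ncol = 2L)
}

#' Global fit of the two-step model to a panel of traces
#'
#' Fits `k_off` and `k_bm` by pooled (unweighted) least squares over every
#' trace in the panel simultaneously -- one parameter set for all input
#' concentrations -- with `k_on` held fixed (default 1e7 M^-1 s^-1, the
#' maximum hybridization rate).  Optimization runs on `log10` parameters
#' with `minpack.lm::nls.lm` from a deterministic multi-start grid
#' (log-uniform over `[1e-4, 1e4]` s^-1 plus seeded jitter); ties are
#' broken by lowest objective, then lowest `k_off`.
#'
#' @param series An [trace_set()] (or list of [trace()] objects).
#' @param fixed_kon Fixed bimolecular binding rate (M^-1 s^-1), > 0.
#' @param n_starts Number of optimizer starts, >= 1 (default 16).
#' @param seed Integer seed for the start-grid jitter.
#' @param lower,upper Box bounds on the free rates (s^-1).
#' @return An object of class `fw_fit` with elements `estimates`
#'   (`k_off`, `k_bm`), `fixed` (`k_on`), `ci95` (`NULL` until
#'   [bootstrap_ci()] is run), `objective` (sum of squared residuals),
#'   `n_points`, `converged`, `n_starts`, `best_start`,
#'   `start_objectives`, `fitted` (per-trace fitted curves), `residuals`,
#'   `identifiability_warning`, and `seed`.
#' @examples
#' \donttest{
#' truth <- rate_parameter_presets()[["1bulge_present"]]
#' panel <- generate_series(truth, experiment_design(duration = 60, sample_interval = 1),
#'                          noise_model(signal_sd = 0))
#' fit <- global_fit(panel, fixed_kon = 1e7, n_starts = 4, seed = 1)
#' }
#' @export
global_fit <- function(series, fixed_kon = 1e7, n_starts = 16L, seed = 1L,
                       lower = 1e-8, upper = 1e8) {
  traces <- .fw_as_trace_list(series)
  if (!is.numeric(fixed_kon) || fixed_kon <= 0)
    .fw_stop("'fixed_kon' must be positive")
  n_starts <- as.integer(n_starts)
  if (is.na(n_starts) || n_starts < 1L) .fw_stop("'n_starts' must be >= 1")
  fn <- .fw_residual_fun(traces, fixed_kon)
  starts <- .fw_start_grid(n_starts, seed)
  lo <- log10(c(lower, lower)); hi <- log10(c(upper, upper))
  starts <- pmin(pmax(starts, matrix(lo, n_starts, 2L, byrow = TRUE)),
                 matrix(hi, n_starts, 2L, byrow = TRUE))

  results <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    results[[i]] <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi, fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
  }
  ok <- vapply(results, function(r) !inherits(r, "error"), logical(1L))
  if (!any(ok)) {
    diag <- vapply(which(!ok), function(i)
      sprintf("start %d (%g, %g): %s", i, 10^starts[i, 1L], 10^starts[i, 2L],
              conditionMessage(results[[i]])), character(1L))
    .fw_stop("all %d optimizer starts failed:\n%s", n_starts,
             paste(diag, collapse = "\n"))
  }
  dev <- vapply(results, function(r) if (inherits(r, "error")) Inf else r$deviance,
                numeric(1L))
  koff_hat <- vapply(results, function(r)
    if (inherits(r, "error")) Inf else 10^r$par[1L], numeric(1L))
  best <- order(dev, koff_hat)[1L]
  br <- results[[best]]
  estimates <- c(k_off = unname(10^br$par[1L]), k_bm = unname(10^br$par[2L]))

  ## fitted curves at the optimum (per trace, for residual bootstrap);
  ## extreme optima (e.g. binding-limited panels pushing k_bm to the
  ## bound) may defeat the strict reporting tolerances, so fall back to
  ## the fitting tolerances rather than fail
  params_hat <- rate_parameters(fixed_kon, estimates[["k_off"]], estimates[["k_bm"]])
  fitted <- lapply(traces, function(tr) {
    out <- .fw_integrate_quiet(params_hat, tr$probe_conc, tr$input_conc, tr$times)
    if (is.null(out))
      out <- .fw_integrate_quiet(params_hat, tr$probe_conc, tr$input_conc,
                                 tr$times, rtol = 1e-6, atol = 1e-13)
    if (is.null(out))
      .fw_stop("cannot simulate the fitted optimum (k_off=%g, k_bm=%g)",
               params_hat$k_off, params_hat$k_bm)
    out[, 5L] / min(tr$probe_conc, tr$input_conc)
  })
  residuals <- Map(function(tr, f) tr$signal - f, traces, fitted)
  objective <- sum(unlist(residuals, use.names = FALSE)^2)

  n_conc <- length(unique(vapply(traces, function(tr) tr$input_conc, numeric(1L))))
  structure(list(
    estimates = estimates,
    fixed = c(k_on = fixed_kon),
    ci95 = NULL,
    objective = objective,
    n_points = sum(lengths(fitted)),
    converged = br$info %in% 1:3,
    n_starts = n_starts,
    best_start = c(k_off = unname(10^starts[best, 1L]),
                   k_bm = unname(10^starts[best, 2L])),
    start_objectives = dev,
    fitted = fitted,
    residuals = residuals,
    identifiability_warning = n_conc < 2L,
    seed = as.integer(seed),
    bounds = c(lower = lower, upper = upper)
  ), class = "fw_fit")
}

#' @export
print.fw_fit <- function(x, ...) {
  cat(sprintf("<fw_fit> k_off = %.4g s^-1, k_bm = %.4g s^-1 (k_on fixed at %g M^-1 s^-1)\n",
              x$estimates[["k_off"]], x$estimates[["k_bm"]], x$fixed[["k_on"]]))
  cat(sprintf("  SSR = %.4g over %d points; %d starts; converged: %s\n",
              x$objective, x$n_points, x$n_starts, x$converged))
  if (!is.null(x$ci95)) {
    cat(sprintf("  95%% CI k_off [%.4g, %.4g], k_bm [%.4g, %.4g] (%d bootstrap replicates)\n",
                x$ci95["k_off", 1L], x$ci95["k_off", 2L],
                x$ci95["k_bm", 1L], x$ci95["k_bm", 2L], x$boot$n_boot))
  }
  if (x$identifiability_warning)
    cat("  warning: single input concentration; parameters may be unidentifiable\n")
  invisible(x)
}

#' Residual-bootstrap 95% confidence intervals for a panel fit
#'
#' Resamples the pooled fit residuals with replacement, adds them to the
#' fitted curves, and refits each synthetic replicate starting from the
#' original optimum.  The 95% interval per free parameter is the 2.5/97.5
#' percentile of the replicate estimates, widened if necessary to include
#' the point estimate (so the interval always brackets it).
#'
#' @param series The panel the fit was computed on.
#' @param fit An [global_fit()] result (must have converged).
#' @param n_boot Number of bootstrap replicates, >= 100 (default 500).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return The `fw_fit` updated with `ci95` (matrix with rows `k_off`,
#'   `k_bm`, columns `lower`, `upper`) and a `boot` record (`n_boot`,
#'   `seed`, `estimates` matrix, `n_failed`).
#' @export
bootstrap_ci <- function(series, fit, n_boot = 500L, seed = 1L) {
  if (!inherits(fit, "fw_fit")) .fw_stop("'fit' must be an fw_fit")
  if (!isTRUE(fit$converged)) .fw_stop("bootstrap requires a converged fit")
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 100L) .fw_stop("'n_boot' must be >= 100")
  traces <- .fw_as_trace_list(series)
  if (length(traces) != length(fit$fitted))
    .fw_stop("'series' does not match the panel the fit was computed on")

  pooled <- unlist(fit$residuals, use.names = FALSE)
  lens <- lengths(fit$fitted)
  par0 <- log10(fit$estimates)
  lo <- log10(c(fit$bounds[["lower"]], fit$bounds[["lower"]]))
  hi <- log10(c(fit$bounds[["upper"]], fit$bounds[["upper"]]))
  kon <- fit$fixed[["k_on"]]

  set.seed(seed)
  est <- matrix(NA_real_, n_boot, 2L, dimnames = list(NULL, c("k_off", "k_bm")))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    draw <- sample(pooled, length(pooled), replace = TRUE)
    split_draw <- split(draw, rep(seq_along(lens), lens))
    boot_traces <- Map(function(tr, f, e) {
      tr$signal <- f + e
      tr
    }, traces, fit$fitted, split_draw)
    fn <- .fw_residual_fun(boot_traces, kon)
    r <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par0, lower = lo, upper = hi, fn = fn,
                           control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL
    )
    if (is.null(r) || !(r$info %in% 1:3)) {
      n_failed <- n_failed + 1L
    } else {
      est[b, ] <- 10^r$par
    }
  }
  if (n_failed > 0.10 * n_boot)
    .fw_stop("%d of %d bootstrap refits failed (%.1f%% > 10%% threshold)",
             n_failed, n_boot, 100 * n_failed / n_boot)

  ci <- t(apply(est, 2L, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  ci[, "lower"] <- pmin(ci[, "lower"], fit$estimates)
  ci[, "upper"] <- pmax(ci[, "upper"], fit$estimates)
  fit$ci95 <- ci
  fit$boot <- list(n_boot = n_boot, seed = as.integer(seed),
                   estimates = est, n_failed = n_failed)
  fit
}

#' Sensitivity of the branch-migration estimate to the fixed k_on
#'
#' Refits the panel for each fixed `k_on` value and reports the recovered
#' `k_bm` estimates together with their maximum pairwise relative
#' deviation, `(max(k_bm) - min(k_bm)) / min(k_bm)`.
#'
#' A large deviation (> 25%) indicates the scan left the regime in which
#' `k_bm` is identifiable independently of the assumed binding rate
#' (e.g. binding-limited data); the result then carries
#' `regime_flag = "non_saturated"`.
#'
#' @param series The trace panel.
#' @param kon_values Positive fixed binding rates to scan
#'   (default `c(1e6, 1e7, 1e8)` M^-1 s^-1).
#' @param n_starts,seed Passed to [global_fit()].
#' @return Object of class `fw_sensitivity`: list with `kon_values`,
#'   `koff_estimates`, `kbm_estimates`, `max_relative_deviation`,
#'   `regime_flag`, and the underlying `fits`.
#' @export
kon_sensitivity <- function(series, kon_values = c(1e6, 1e7, 1e8),
                            n_starts = 16L, seed = 1L) {
  if (!is.numeric(kon_values) || length(kon_values) < 1L || any(kon_values <= 0))
    .fw_stop("'kon_values' must be positive")
  fits <- vector("list", length(kon_values))
  for (i in seq_along(kon_values)) {
    fits[[i]] <- tryCatch(
      global_fit(series, fixed_kon = kon_values[i], n_starts = n_starts, seed = seed),
      error = function(e)
        .fw_stop("fit failed at fixed k_on = %g: %s", kon_values[i],
                 conditionMessage(e))
    )
  }
  kbm <- vapply(fits, function(f) f$estimates[["k_bm"]], numeric(1L))
  koff <- vapply(fits, function(f) f$estimates[["k_off"]], numeric(1L))
  dev <- if (length(kbm) > 1L) (max(kbm) - min(kbm)) / min(kbm) else 0
  structure(list(
    kon_values = kon_values,
    koff_estimates = koff,
    kbm_estimates = kbm,
    max_relative_deviation = dev,
    regime_flag = if (dev > 0.25) "non_saturated" else "ok",
    fits = fits
  ), class = "fw_sensitivity")
}

#' @export
print.fw_sensitivity <- function(x, ...) {
  cat("<fw_sensitivity>\n")
  for (i in seq_along(x$kon_values))
    cat(sprintf("  k_on = %g: k_off = %.4g, k_bm = %.4g s^-1\n",
                x$kon_values[i], x$koff_estimates[i], x$kbm_estimates[i]))
  cat(sprintf("  max relative deviation of k_bm: %.3g%% [%s]\n",
              100 * x$max_relative_deviation, x$regime_flag))
  invisible(x)
}
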