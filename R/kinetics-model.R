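#' Concentrations of the five modelled species
#'
#' The two-step model tracks five species: the free `input` duplex, the
#' free `probe` duplex, the toehold-bound intermediate `t_only`, the
#' fluorescent product `F`, and the released quenched complex `Q`.  All
#' concentrations are molar.
#'
#' @param input,probe,t_only,F,Q Non-negative molar concentrations.
#' @return An object of class `fw_state`: named numeric vector of length 5.
#' @examples
#' species_state(input = 2e-8, probe = 5e-9)
#' @export
species_state <- function(input, probe, t_only = 0, F = 0, Q = 0) {
  y <- c(input = input, probe = probe, t_only = t_only, F = F, Q = Q)
  if (!is.numeric(y) || length(y) != 5L || anyNA(y))
    .fw_stop("species concentrations must be single finite numbers")
  if (any(y < 0))
    .fw_stop("negative concentration: %s = %g",
             names(y)[which(y < 0)[1L]], y[which(y < 0)[1L]])
  structure(y, class = "fw_state")
}

#' Time derivatives of the two-step strand-exchange model
#'
#' Evaluates the right-hand sides of the five coupled rate equations:
#' \deqn{d[input]/dt = k_{off}[t_{only}] - k_{on}[input][probe]}
#' \deqn{d[probe]/dt = d[input]/dt}
#' \deqn{d[t_{only}]/dt = k_{on}[input][probe] - k_{off}[t_{only}] - k_{bm}[t_{only}]}
#' \deqn{d[F]/dt = k_{bm}[t_{only}]}
#' \deqn{d[Q]/dt = d[F]/dt}
#'
#' @param state A [species_state()] (or named numeric vector with elements
#'   `input`, `probe`, `t_only`, `F`, `Q`), molar.
#' @param params A [rate_parameters()] object.
#' @return Named numeric vector of per-species derivatives (M/s), same
#'   names as the state.
#' @examples
#' s <- species_state(input = 2e-8, probe = 5e-9)
#' rate_equations(s, rate_parameters(1e7, 0.14, 0.56))
#' @export
rate_equations <- function(state, params) {
  params <- .fw_check_rates(params)
  if (!inherits(state, "fw_state"))
    state <- species_state(state[["input"]], state[["probe"]],
                           state[["t_only"]], state[["F"]], state[["Q"]])
  bind    <- params$k_on * state[["input"]] * state[["probe"]]
  unbind  <- params$k_off * state[["t_only"]]
  resolve <- params$k_bm * state[["t_only"]]
  c(input = unbind - bind,
    probe = unbind - bind,
    t_only = bind - unbind - resolve,
    F = resolve,
    Q = resolve)
}

## Integrate the compiled five-species system from (input0, probe0, 0, 0, 0).
## Returns the deSolve output matrix; stops if the integrator fails.
.fw_integrate <- function(params, probe0, input0, times,
                          rtol = .fw_rtol, atol = .fw_atol) {
  y0 <- c(input0, probe0, 0, 0, 0)
  out <- deSolve::lsoda(
    y = y0, times = times, func = "fourway_derivs",
    parms = c(params$k_on, params$k_off, params$k_bm),
    dllname = "fourwaykinetics", initfunc = "fourway_initmod",
    jacfunc = "fourway_jac", jactype = "fullusr",
    rtol = rtol, atol = atol, maxsteps = 5000L
  )
  istate <- attr(out, "istate")[1L]
  if (is.null(istate) || istate < 0 || anyNA(out[, -1L]))
    .fw_stop(paste0("ODE integration failed (istate = %s) at rtol = %g, ",
                    "atol = %g; parameters k_on=%g k_off=%g k_bm=%g"),
             as.character(istate), rtol, atol,
             params$k_on, params$k_off, params$k_bm)
  out
}

## Batched integration: one solver call for several initial-condition
## blocks sharing the parameter set and time grid.  Returns a matrix of
## normalized signals (rows = times, cols = blocks), or NULL on failure.
.fw_integrate_multi <- function(params, probe0s, input0s, times,
                                rtol = .fw_rtol, atol = .fw_atol) {
  nb <- length(probe0s)
  y0 <- as.vector(rbind(input0s, probe0s, 0, 0, 0))
  out <- NULL
  utils::capture.output(
    out <- tryCatch(suppressWarnings(deSolve::lsoda(
      y = y0, times = times, func = "fourway_derivs_multi",
      parms = c(params$k_on, params$k_off, params$k_bm),
      dllname = "fourwaykinetics", initfunc = "fourway_initmod",
      jacfunc = "fourway_jac_multi", jactype = "fullusr",
      rtol = rtol, atol = atol, maxsteps = 5000L
    )), error = function(e) NULL)
  )
  if (is.null(out)) return(NULL)
  istate <- attr(out, "istate")[1L]
  if (is.null(istate) || istate < 0 || anyNA(out[, -1L])) return(NULL)
  f <- out[, 1L + 5L * seq_len(nb) - 1L, drop = FALSE]   # F column per block
  sweep(f, 2L, pmin(probe0s, input0s), "/")
}

## Same integration but returning NULL on failure, for use inside optimizers
## where a diverged parameter set must yield penalty residuals, not an error.
.fw_integrate_quiet <- function(params, probe0, input0, times,
                                rtol = .fw_rtol, atol = .fw_atol) {
  out <- NULL
  ## capture.output also swallows the FORTRAN solver's console chatter
  ## when the optimizer visits pathological parameter regions
  utils::capture.output(
    out <- tryCatch(
      suppressWarnings(.fw_integrate(params, probe0, input0, times, rtol, atol)),
      error = function(e) NULL
    )
  )
  out
}

.fw_check_tgrid <- function(t_grid) {
  if (!is.numeric(t_grid) || length(t_grid) < 2L || anyNA(t_grid))
    .fw_stop("'t_grid' must be a numeric vector of length >= 2")
  if (t_grid[1L] != 0)
    .fw_stop("'t_grid' must start at 0 (got %g)", t_grid[1L])
  if (any(diff(t_grid) <= 0))
    .fw_stop("'t_grid' must be strictly increasing (violation at index %d)",
             which(diff(t_grid) <= 0)[1L] + 1L)
  t_grid
}

#' Deterministic simulation of a strand-exchange trace
#'
#' Integrates the five-species rate equations from the initial condition
#' `(input0, probe0, 0, 0, 0)` with a stiff-capable integrator
#' (`deSolve::lsoda`, relative tolerance 1e-8, absolute tolerance 1e-15 M)
#' and returns the normalized fluorescence trace
#' `signal(t) = F(t) / min(probe0, input0)`, i.e. product over the
#' limiting reagent's total.
#'
#' @param params A [rate_parameters()] object.
#' @param probe0 Initial probe-duplex concentration (M), > 0.
#' @param input0 Initial input-duplex concentration (M), > 0.
#' @param t_grid Strictly increasing time grid (s) starting at 0.
#' @param condition Optional condition record (see [trace()]).
#' @param replicate Replicate index for the returned trace.
#' @return A [trace()] object.  The full species matrix is attached as
#'   attribute `"species"` (columns `time`, `input`, `probe`, `t_only`,
#'   `F`, `Q`), so conservation laws can be checked on the output.
#' @examples
#' p <- rate_parameters(1e7, 0.14, 0.56)
#' tr <- simulate_deterministic(p, probe0 = 5e-9, input0 = 1e-6,
#'                              t_grid = seq(0, 30, by = 0.5))
#' @export
simulate_deterministic <- function(params, probe0, input0, t_grid,
                                   condition = NULL, replicate = 1L) {
  params <- .fw_check_rates(params)
  if (!is.numeric(probe0) || probe0 <= 0 || !is.numeric(input0) || input0 <= 0)
    .fw_stop("'probe0' and 'input0' must be positive concentrations (molar)")
  t_grid <- .fw_check_tgrid(t_grid)
  out <- .fw_integrate(params, probe0, input0, t_grid)
  limiting <- min(probe0, input0)
  signal <- out[, 5L] / limiting
  ## integration tolerance can leave O(atol/limiting) negatives at t ~ 0
  signal[signal < 0 & signal > -1e-9] <- 0
  tr <- trace(times = t_grid, signal = signal,
              input_conc = input0, probe_conc = probe0,
              condition = condition, replicate = replicate)
  species <- cbind(time = out[, 1L], input = out[, 2L], probe = out[, 3L],
                   t_only = out[, 4L], F = out[, 5L], Q = out[, 6L])
  attr(tr, "species") <- species
  attr(tr, "params") <- params
  tr
}

#' Closed-form excess-input signal (pseudo-first-order oracle)
#'
#' When the input duplex is in large excess over the probe, `[input]` is
#' effectively constant at `c0` and the model reduces to the linear
#' two-state system `probe -> t_only` (rate `k_on * c0`), `t_only -> probe`
#' (rate `k_off`), `t_only -> F` (rate `k_bm`).  This function returns the
#' exact solution `F(t)/probe_total` of that linear system from its
#' eigenvalues, independently of any ODE integrator, and is used as an
#' oracle for [simulate_deterministic()].
#'
#' The two eigenvalues are the roots of
#' `lambda^2 + (k_a + k_off + k_bm) lambda + k_a k_bm = 0` with
#' `k_a = k_on * c0`; nearly repeated roots are handled by the limiting
#' (repeated-root) formula rather than by failure.
#'
#' @param params A [rate_parameters()] object.
#' @param c0 Constant input concentration (M), > 0.
#' @param t Vector of times (s).
#' @return Numeric vector of normalized signal values in `[0, 1]`.
#' @examples
#' analytic_excess_input(rate_parameters(1e7, 0.14, 0.56), 1e-6, c(0, 1, 10))
#' @export
analytic_excess_input <- function(params, c0, t) {
  params <- .fw_check_rates(params)
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0)
    .fw_stop("'c0' must be a single positive concentration (molar)")
  ka <- params$k_on * c0
  s <- ka + params$k_off + params$k_bm
  prod_ <- ka * params$k_bm
  if (prod_ == 0) return(rep(0, length(t)))
  disc <- s^2 - 4 * prod_
  disc <- max(disc, 0)
  d <- sqrt(disc)
  l1 <- (-s + d) / 2
  l2 <- (-s - d) / 2
  ## F(t)/T = kbm * ka * [ (e^{l1 t}-1)/l1 - (e^{l2 t}-1)/l2 ] / (l1 - l2)
  if (d > 1e-9 * s) {
    f <- prod_ * ((expm1(l1 * t)) / l1 - (expm1(l2 * t)) / l2) / (l1 - l2)
  } else {
    ## repeated root l = -s/2: F(t)/T = 1 - e^{l t} (1 - l t)
    l <- -s / 2
    f <- 1 - exp(l * t) * (1 - l * t)
  }
  pmin(pmax(f, 0), 1)
}
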