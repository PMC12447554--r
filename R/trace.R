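#' A normalized fluorescence trace
#'
#' A single time-resolved, normalized fluorescence curve from one well:
#' time stamps in seconds (strictly increasing, starting at 0), the
#' dimensionless normalized signal, the input- and probe-duplex
#' concentrations (molar), a condition record, and a replicate index.
#'
#' @param times Numeric vector of times (s), strictly increasing, first 0.
#' @param signal Numeric vector of normalized fluorescence, same length as
#'   `times` (target range `[0, 1]`; noisy data may exceed it slightly).
#' @param input_conc Input-duplex concentration (M), > 0.
#' @param probe_conc Probe-duplex concentration (M), > 0.
#' @param condition A list with elements `bulge_count` (0, 1, or 2),
#'   `toehold_length_nt` (3..6) and optional `label`.  Defaults to a
#'   single-bulge, 5 nt toehold design.
#' @param replicate Integer replicate index, >= 1.
#' @return An object of class `fw_trace`.
#' @export
trace <- function(times, signal, input_conc, probe_conc,
                  condition = NULL, replicate = 1L) {
  if (is.null(condition))
    condition <- list(bulge_count = 1L, toehold_length_nt = 5L, label = NA_character_)
  condition <- .fw_check_condition(condition)
  if (!is.numeric(times) || !is.numeric(signal))
    .fw_stop("'times' and 'signal' must be numeric")
  if (length(times) != length(signal) || length(times) < 2L)
    .fw_stop("'times' and 'signal' must have equal length >= 2")
  .fw_check_tgrid(times)
  if (anyNA(signal)) .fw_stop("'signal' must not contain NA")
  if (!is.numeric(input_conc) || input_conc <= 0 ||
      !is.numeric(probe_conc) || probe_conc <= 0)
    .fw_stop("'input_conc' and 'probe_conc' must be positive (molar)")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    .fw_stop("'replicate' must be an integer >= 1")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 input_conc = input_conc, probe_conc = probe_conc,
                 condition = condition, replicate = replicate),
            class = "fw_trace")
}

.fw_check_condition <- function(condition) {
  if (!is.list(condition)) .fw_stop("'condition' must be a list")
  bc <- condition$bulge_count
  th <- condition$toehold_length_nt
  if (is.null(bc) || !(bc %in% 0:2))
    .fw_stop("condition$bulge_count must be 0, 1, or 2")
  if (is.null(th) || !(th %in% 3:6))
    .fw_stop("condition$toehold_length_nt must be in 3..6")
  if (is.null(condition$label)) condition$label <- NA_character_
  list(bulge_count = as.integer(bc), toehold_length_nt = as.integer(th),
       label = as.character(condition$label))
}

.fw_same_condition <- function(a, b) {
  a$bulge_count == b$bulge_count &&
    a$toehold_length_nt == b$toehold_length_nt &&
    (is.na(a$label) && is.na(b$label) || identical(a$label, b$label))
}

#' @export
print.fw_trace <- function(x, ...) {
  cat(sprintf(
    "<fw_trace> %d points over %g s; input %g nM, probe %g nM, %d bulge(s), %d nt toehold, rep %d\n",
    length(x$times), max(x$times), x$input_conc * 1e9, x$probe_conc * 1e9,
    x$condition$bulge_count, x$condition$toehold_length_nt, x$replicate))
  invisible(x)
}

#' A panel of traces sharing one chemistry
#'
#' A trace set collects traces that share the probe concentration and
#' condition but differ in input-duplex concentration (and possibly
#' replicate), i.e. one panel of kinetic curves fitted with a single
#' parameter set.
#'
#' @param traces A list of [trace()] objects covering at least two
#'   distinct input concentrations, all sharing `probe_conc` and
#'   `condition`.
#' @return An object of class `fw_trace_set` with elements `traces`,
#'   `probe_conc`, `condition`.
#' @export
trace_set <- function(traces) {
  if (!is.list(traces) || length(traces) < 2L ||
      !all(vapply(traces, inherits, logical(1L), "fw_trace")))
    .fw_stop("'traces' must be a list of >= 2 fw_trace objects")
  probe <- traces[[1L]]$probe_conc
  cond <- traces[[1L]]$condition
  for (i in seq_along(traces)) {
    if (traces[[i]]$probe_conc != probe)
      .fw_stop("trace %d has probe_conc %g M, expected %g M (sets share one probe concentration)",
               i, traces[[i]]$probe_conc, probe)
    if (!.fw_same_condition(traces[[i]]$condition, cond))
      .fw_stop("trace %d has a different condition than trace 1", i)
  }
  concs <- vapply(traces, function(tr) tr$input_conc, numeric(1L))
  if (length(unique(concs)) < 2L)
    .fw_stop("a trace set needs >= 2 distinct input concentrations")
  structure(list(traces = traces, probe_conc = probe, condition = cond),
            class = "fw_trace_set")
}

#' @export
print.fw_trace_set <- function(x, ...) {
  concs <- sort(unique(vapply(x$traces, function(tr) tr$input_conc, numeric(1L))))
  cat(sprintf(
    "<fw_trace_set> %d traces, input %s nM, probe %g nM, %d bulge(s), %d nt toehold\n",
    length(x$traces), paste(concs * 1e9, collapse = "/"), x$probe_conc * 1e9,
    x$condition$bulge_count, x$condition$toehold_length_nt))
  invisible(x)
}

#' @export
length.fw_trace_set <- function(x) length(x$traces)
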