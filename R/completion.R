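#' Time to a given fraction of reaction completion
#'
#' Model-free completion statistic: the plateau is estimated as the mean
#' of the final 5% of samples, the threshold is `fraction * plateau`, and
#' the reported time is the earliest upward crossing of the threshold,
#' located by linear interpolation between the bracketing samples.
#'
#' A trace that never crosses its threshold (including a flat-zero trace)
#' yields `NA_real_` with attribute `undefined = TRUE` -- a flag, not an
#' error -- so partial condition grids can still be tabulated.
#'
#' @param trace A [trace()] object (>= 2 points).
#' @param fraction Completion fraction in (0, 1); default 0.9 gives the
#'   90%-completion time.
#' @return Time in seconds, or flagged `NA_real_` if undefined.
#' @examples
#' tm <- seq(0, 80, by = 0.1)
#' tr <- trace(tm, 1 - exp(-0.1 * tm), input_conc = 1e-6, probe_conc = 5e-9)
#' time_to_fraction(tr)  # ~ log(10)/0.1 = 23.03 s
#' @export
time_to_fraction <- function(trace, fraction = 0.9) {
  if (!inherits(trace, "fw_trace")) .fw_stop("'trace' must be an fw_trace")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    .fw_stop("'fraction' must be in (0, 1)")
  s <- trace$signal; tm <- trace$times
  n <- length(s)
  plateau <- mean(s[seq.int(n - max(1L, ceiling(0.05 * n)) + 1L, n)])
  threshold <- fraction * plateau
  undefined <- structure(NA_real_, undefined = TRUE)
  if (threshold <= 0) return(undefined)
  if (s[1L] >= threshold) return(tm[1L])
  cross <- which(s[-1L] >= threshold & s[-n] < threshold)
  if (length(cross) == 0L) return(undefined)
  i <- cross[1L]
  tm[i] + (threshold - s[i]) * (tm[i + 1L] - tm[i]) / (s[i + 1L] - s[i])
}

.fw_cell_time <- function(traces, fraction) {
  tt <- vapply(traces, function(tr) as.numeric(time_to_fraction(tr, fraction)),
               numeric(1L))
  if (all(is.na(tt))) NA_real_ else mean(tt, na.rm = TRUE)
}

#' Reaction enhancement factors T0/Tb across a condition grid
#'
#' Pairs completion times measured without (`T0`) and with (`Tb`)
#' bulge(s) by `(toehold_length_nt, input_conc)` and reports the
#' enhancement factor `T0/Tb`.  Replicate traces in a cell are averaged
#' (over the replicates whose completion time is defined).  Cells whose
#' `T0` or `Tb` is undefined are kept with `enhancement = NA`.
#'
#' @param no_bulge,with_bulge A [trace_set()] or list of trace sets.  The
#'   two collections must cover the same `(toehold length, concentration)`
#'   grid; an unpaired cell is an error naming the orphan.
#' @param fraction Completion fraction (default 0.9).
#' @return A `data.frame` with columns `toehold_length_nt`, `input_conc`
#'   (molar), `T0`, `Tb` (seconds) and `enhancement` (`T0/Tb`).
#' @export
enhancement_table <- function(no_bulge, with_bulge, fraction = 0.9) {
  flatten <- function(x) {
    if (inherits(x, "fw_trace_set")) return(x$traces)
    if (is.list(x) && all(vapply(x, inherits, logical(1L), "fw_trace_set")))
      return(unlist(lapply(x, function(s) s$traces), recursive = FALSE))
    .fw_as_trace_list(x)
  }
  t0 <- flatten(no_bulge); tb <- flatten(with_bulge)
  key <- function(tr) sprintf("%d nt toehold @ %g nM",
                              tr$condition$toehold_length_nt, tr$input_conc * 1e9)
  g0 <- split(t0, vapply(t0, key, character(1L)))
  gb <- split(tb, vapply(tb, key, character(1L)))
  orphans <- c(setdiff(names(g0), names(gb)), setdiff(names(gb), names(g0)))
  if (length(orphans) > 0L)
    .fw_stop("unpairable condition cell(s): %s", paste(orphans, collapse = "; "))

  cells <- names(g0)
  rows <- lapply(cells, function(k) {
    trs <- g0[[k]]
    T0 <- .fw_cell_time(trs, fraction)
    Tb <- .fw_cell_time(gb[[k]], fraction)
    data.frame(toehold_length_nt = trs[[1L]]$condition$toehold_length_nt,
               input_conc = trs[[1L]]$input_conc,
               T0 = T0, Tb = Tb,
               enhancement = if (is.na(T0) || is.na(Tb)) NA_real_ else T0 / Tb)
  })
  out <- do.call(rbind, rows)
  out[order(out$toehold_length_nt, out$input_conc), , drop = FALSE]
}
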