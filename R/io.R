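## Plain-text I/O.  Internal concentrations are molar; files use
## nanomolar, matching the experimental convention for axis labels.

.fw_trace_csv_cols <- c("time_s", "signal", "input_nM", "probe_nM",
                        "bulge_count", "toehold_nt", "replicate")

#' Write traces to the standard trace CSV
#'
#' Columns: `time_s`, `signal`, `input_nM`, `probe_nM`, `bulge_count`,
#' `toehold_nt`, `replicate`; UTF-8, '.' decimal separator, header
#' required.
#'
#' @param x An `fw_trace`, `fw_trace_set`, or list of either.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  flatten <- function(z) {
    if (inherits(z, "fw_trace")) return(list(z))
    if (inherits(z, "fw_trace_set")) return(z$traces)
    if (is.list(z)) return(unlist(lapply(z, flatten), recursive = FALSE))
    .fw_stop("cannot write object of class '%s' as traces", class(z)[1L])
  }
  traces <- flatten(x)
  rows <- lapply(traces, function(tr) {
    data.frame(time_s = tr$times, signal = tr$signal,
               input_nM = tr$input_conc * 1e9, probe_nM = tr$probe_conc * 1e9,
               bulge_count = tr$condition$bulge_count,
               toehold_nt = tr$condition$toehold_length_nt,
               replicate = tr$replicate)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trace sets from the standard trace CSV
#'
#' Groups rows into one trace per (`input_nM`, `replicate`) and one trace
#' set per (`bulge_count`, `toehold_nt`, `probe_nM`); validates the
#' schema and the trace invariants, reporting the offending file row
#' (counting the header as row 1) on failure.
#'
#' @param path CSV file path.
#' @return A list of [trace_set()] objects (possibly of length 1).
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) .fw_stop("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.fw_trace_csv_cols, names(df))
  if (length(missing) > 0L)
    .fw_stop("missing column(s) in %s: %s", path, paste(missing, collapse = ", "))
  if (nrow(df) == 0L) .fw_stop("no data rows in %s", path)
  df$.row <- seq_len(nrow(df)) + 1L   # file row numbers (header = row 1)

  set_key <- interaction(df$bulge_count, df$toehold_nt, df$probe_nM, drop = TRUE)
  sets <- lapply(split(df, set_key), function(g) {
    traces <- lapply(split(g, interaction(g$input_nM, g$replicate, drop = TRUE)),
                     function(tg) {
      bad <- which(diff(tg$time_s) <= 0)
      if (length(bad) > 0L)
        .fw_stop("non-monotone time within a trace at file row %d (input %g nM, replicate %d)",
                 tg$.row[bad[1L] + 1L], tg$input_nM[1L], tg$replicate[1L])
      tryCatch(
        trace(times = tg$time_s, signal = tg$signal,
              input_conc = tg$input_nM[1L] * 1e-9,
              probe_conc = tg$probe_nM[1L] * 1e-9,
              condition = list(bulge_count = tg$bulge_count[1L],
                               toehold_length_nt = tg$toehold_nt[1L]),
              replicate = tg$replicate[1L]),
        error = function(e)
          .fw_stop("invalid trace starting at file row %d: %s",
                   tg$.row[1L], conditionMessage(e)))
    })
    tryCatch(trace_set(unname(traces)),
             error = function(e)
               .fw_stop("invalid trace set (bulge_count %s, toehold %s nt, probe %s nM): %s",
                        g$bulge_count[1L], g$toehold_nt[1L], g$probe_nM[1L],
                        conditionMessage(e)))
  })
  unname(sets)
}

.fw_fit_to_list <- function(fit) {
  out <- unclass(fit)
  if (!is.null(out$ci95)) {
    out$ci95 <- list(k_off = as.numeric(out$ci95["k_off", ]),
                     k_bm = as.numeric(out$ci95["k_bm", ]))
  }
  if (!is.null(out$boot)) out$boot$estimates <- NULL  # bulky; summarized by ci95
  out$fitted <- NULL; out$residuals <- NULL           # recomputable from the panel
  out$estimates <- as.list(out$estimates)
  out$fixed <- as.list(out$fixed)
  out$best_start <- as.list(out$best_start)
  out$bounds <- as.list(out$bounds)
  out
}

#' Write a fit result or a table of results
#'
#' `fw_fit` objects are serialized as JSON at full numeric precision
#' (including the seed, multi-start record, and confidence intervals);
#' data frames (completion tables, occupancy profiles, sensitivity
#' tables) are written as CSV.
#'
#' @param x An `fw_fit` or a `data.frame`.
#' @param path Output file path (`.json` or `.csv` by object type).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "fw_fit")) {
    jsonlite::write_json(.fw_fit_to_list(x), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  } else if (is.data.frame(x)) {
    write.csv(x, path, row.names = FALSE, quote = FALSE)
  } else {
    .fw_stop("cannot serialize object of class '%s'", class(x)[1L])
  }
  invisible(path)
}

#' Read a fit result written by [write_results()]
#'
#' @param path JSON file path.
#' @return An `fw_fit` object (without the per-trace fitted curves, which
#'   are recomputable from the panel).
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) .fw_stop("file not found: %s", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$estimates <- unlist(x$estimates)
  x$fixed <- unlist(x$fixed)
  x$best_start <- unlist(x$best_start)
  x$bounds <- unlist(x$bounds)
  if (!is.null(x$ci95)) {
    x$ci95 <- matrix(c(x$ci95$k_off, x$ci95$k_bm), nrow = 2L, byrow = TRUE,
                     dimnames = list(c("k_off", "k_bm"), c("lower", "upper")))
  }
  structure(x, class = "fw_fit")
}
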