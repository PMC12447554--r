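#' Rate constants of the two-step strand-exchange model
#'
#' Bundles the three rate constants of the two-step model of four-way
#' toehold-mediated strand exchange: bimolecular toehold binding `k_on`
#' (M^-1 s^-1), unimolecular toehold unbinding `k_off` (s^-1), and the
#' effective branch-migration/resolution rate `k_bm` (s^-1).  Branch
#' migration is treated as a single irreversible step.
#'
#' @param k_on Bimolecular association rate constant (M^-1 s^-1).  Must be
#'   non-negative and below the diffusion ceiling of 1e10 M^-1 s^-1.
#' @param k_off Toehold unbinding rate constant (s^-1), non-negative.
#' @param k_bm Branch-migration (resolution) rate constant (s^-1),
#'   non-negative.
#' @return An object of class `fw_rates`: a named list with elements
#'   `k_on`, `k_off`, `k_bm`.
#' @examples
#' rate_parameters(k_on = 1e7, k_off = 0.14, k_bm = 0.56)
#' @export
rate_parameters <- function(k_on, k_off, k_bm) {
  for (nm in c("k_on", "k_off", "k_bm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      .fw_stop("'%s' must be a single non-negative number", nm)
  }
  if (k_on > .fw_kon_ceiling)
    .fw_stop("k_on = %g exceeds the diffusion-limited ceiling of %g M^-1 s^-1",
             k_on, .fw_kon_ceiling)
  structure(list(k_on = k_on, k_off = k_off, k_bm = k_bm),
            class = "fw_rates")
}

#' @export
print.fw_rates <- function(x, ...) {
  cat(sprintf("<fw_rates> k_on = %g M^-1 s^-1, k_off = %g s^-1, k_bm = %g s^-1\n",
              x$k_on, x$k_off, x$k_bm))
  invisible(x)
}

.fw_check_rates <- function(params) {
  if (!inherits(params, "fw_rates"))
    .fw_stop("'params' must be created by rate_parameters()")
  params
}

#' Published rate-constant presets for the four experimental conditions
#'
#' Returns the four fitted parameter sets for the 5 nt toehold designs:
#' single-bulge and two-bulge input duplexes, each with the bulge(s)
#' present or absent.  All four share the fixed hybridization rate
#' `k_on` = 1e7 M^-1 s^-1.  These sets serve as generator truths for the
#' synthetic panels.
#'
#' @return A named list of [rate_parameters()] objects with names
#'   `"1bulge_present"`, `"1bulge_absent"`, `"2bulge_present"`,
#'   `"2bulge_absent"`.  Each element carries attributes `bulge_count`
#'   (0, 1, or 2 bulges physically present in the design) and `label`.
#' @examples
#' rate_parameter_presets()[["1bulge_present"]]
#' @export
rate_parameter_presets <- function() {
  mk <- function(k_off, k_bm, bulge_count, label) {
    p <- rate_parameters(k_on = 1e7, k_off = k_off, k_bm = k_bm)
    attr(p, "bulge_count") <- bulge_count
    attr(p, "label") <- label
    p
  }
  list(
    "1bulge_present" = mk(1.4e-1, 5.6e-1, 1L, "1bulge_present"),
    "1bulge_absent"  = mk(8.6e-1, 1.9e-2, 0L, "1bulge_absent"),
    "2bulge_present" = mk(1.0e2,  1.1e2,  2L, "2bulge_present"),
    "2bulge_absent"  = mk(8.0e0,  1.6e0,  0L, "2bulge_absent")
  )
}
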