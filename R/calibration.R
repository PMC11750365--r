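#' Fit an optical-density calibration curve
#'
#' Least-squares line through the origin relating blank-corrected OD750 to
#' algal cell concentration, the standard reference-curve construction for
#' a spectrophotometric cell-count proxy. ODs are blank-corrected before
#' fitting.
#'
#' @param od750 raw optical densities at 750 nm (>= 3 points).
#' @param cells_per_ml matching cell concentrations (e.g. 10^6 cells ml^-1).
#' @param blank_od OD of the pure-medium blank (default 0).
#' @return A `calibration_curve` list: `slope` (cells per OD unit),
#'   `blank_od`, `residual_sd`, `n`.
#' @examples
#' cc <- fit_calibration(c(0.1, 0.5, 1.0), c(1, 5, 10))
#' od_to_cells(0.75, cc)
#' @export
fit_calibration <- function(od750, cells_per_ml, blank_od = 0) {
  if (length(od750) != length(cells_per_ml))
    stop("od750 and cells_per_ml must have equal length", call. = FALSE)
  if (length(od750) < 3)
    stop("need at least 3 calibration points", call. = FALSE)
  x <- od750 - blank_od
  if (all(x == 0)) stop("all blank-corrected ODs are zero; cannot fit",
                        call. = FALSE)
  slope <- sum(x * cells_per_ml) / sum(x * x)
  if (slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  resid <- cells_per_ml - slope * x
  structure(list(slope = slope, blank_od = blank_od,
                 residual_sd = if (length(x) > 1) stats::sd(resid) else 0,
                 n = length(x)),
            class = "calibration_curve")
}

#' @rdname fit_calibration
#' @param od OD750 value(s) to convert.
#' @param curve a fitted `calibration_curve`.
#' @return `od_to_cells()` returns cell concentrations, floored at 0.
#' @export
od_to_cells <- function(od, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  pmax(0, curve$slope * (od - curve$blank_od))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "OD750 calibration: cells = %g * (OD - %g); residual SD %g (n = %d)\n",
    x$slope, x$blank_od, x$residual_sd, x$n))
  invisible(x)
}

#' Read a calibration CSV (`od750, cells_per_ml`)
#' @param path file path.
#' @param blank_od blank OD passed to [fit_calibration()].
#' @return A fitted `calibration_curve`.
#' @export
read_calibration <- function(path, blank_od = 0) {
  d <- read.csv(path)
  stopifnot(all(c("od750", "cells_per_ml") %in% names(d)))
  fit_calibration(d$od750, d$cells_per_ml, blank_od = blank_od)
}
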