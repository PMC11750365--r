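#' Per-capita growth rate
#'
#' The average exponential growth rate per individual per day,
#' `ln(n_final/n0)/duration` — the fitness measure used throughout the
#' assay pipeline. A final density of 0 has no finite log-growth; it is
#' returned as `-Inf` so callers can count and exclude collapsed replicates
#' from regression-style fits.
#'
#' @param n0 initial density (> 0); vectorised.
#' @param n_final final density (>= 0); vectorised.
#' @param duration elapsed time in days (> 0); vectorised.
#' @return Per-capita growth (per day); `-Inf` where `n_final = 0`.
#' @examples
#' per_capita_growth(5, 40, 7)      # ln(8)/7
#' per_capita_growth(1000, 500, 7)  # negative
#' @export
per_capita_growth <- function(n0, n_final, duration) {
  if (any(n0 <= 0) || any(duration <= 0) || any(n_final < 0))
    stop("need n0 > 0, duration > 0, n_final >= 0", call. = FALSE)
  ifelse(n_final == 0, -Inf, log(n_final / n0) / duration)
}

#' Normalized fitness change between herbivory and control
#'
#' `(SAherb - SActr)/max(SAherb, SActr)`, a bounded contrast in `[-1, 1]`
#' of surface coverage (or any non-negative abundance proxy) between a
#' compartment exposed to herbivores and its herbivore-free control.
#' Positive values mean herbivory increased coverage.
#'
#' @param sa_herb coverage under herbivory (>= 0); vectorised.
#' @param sa_ctr coverage in the control (>= 0); vectorised.
#' @return Normalized fitness change; `NA` (with a warning) where both
#'   inputs are 0, since the contrast is undefined there.
#' @examples
#' normalized_fitness(80, 50)  # 0.375
#' @export
normalized_fitness <- function(sa_herb, sa_ctr) {
  if (any(sa_herb < 0) || any(sa_ctr < 0))
    stop("coverages must be >= 0", call. = FALSE)
  both0 <- sa_herb == 0 & sa_ctr == 0
  if (any(both0))
    warning("normalized fitness undefined where both coverages are 0; NA returned")
  out <- (sa_herb - sa_ctr) / pmax(sa_herb, sa_ctr)
  out[both0] <- NA_real_
  out
}
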