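#' Zero-growth isoclines
#'
#' The focal species' zero-net-growth density as a function of the
#' competitor's density: `N1 = (1 - a12*N2 - beta1*Nh)/a11` for species 1
#' and `N2 = (1 - a21*N1 - beta2*Nh)/a22` for species 2. Values may be
#' negative (the caller decides how to truncate for plotting); wherever the
#' returned density is positive, [rhs()] evaluates to exactly zero growth
#' for that species.
#'
#' @param params a [model_params()] object.
#' @param other numeric vector of competitor densities.
#' @param species which species' isocline (1 or 2).
#' @return Numeric vector of zero-growth densities, same length as `other`.
#' @examples
#' p <- fixture_params(Nh = 0)
#' isocline(p, other = c(0, 5, 10), species = 1)
#' @export
isocline <- function(params, other, species = 1) {
  params <- validate_params(params)
  other <- as.numeric(other)
  if (species == 1) {
    (1 - params$a12 * other - params$beta1 * params$Nh) / params$a11
  } else if (species == 2) {
    (1 - params$a21 * other - params$beta2 * params$Nh) / params$a22
  } else stop("species must be 1 or 2", call. = FALSE)
}

#' Isocline table over a competitor grid
#'
#' Convenience wrapper returning both isoclines on shared grids, the shape
#' the `phase`/`predict` pipeline subcommands write as CSV.
#'
#' @inheritParams isocline
#' @param n2_grid grid of species-2 densities for species 1's isocline.
#' @param n1_grid grid of species-1 densities for species 2's isocline.
#' @return data.frame with columns `species`, `other_density`,
#'   `zero_growth_density`.
#' @export
isocline_table <- function(params, n2_grid, n1_grid) {
  rbind(
    data.frame(species = 1L, other_density = n2_grid,
               zero_growth_density = isocline(params, n2_grid, 1)),
    data.frame(species = 2L, other_density = n1_grid,
               zero_growth_density = isocline(params, n1_grid, 2)))
}

#' Invasion-growth-rate analysis of the focal species
#'
#' Computes the resident equilibrium of species 2 alone with and without
#' herbivory, `N2w = (1 - beta2*Nh)/a22` (floored at 0 when herbivory alone
#' collapses the resident, which is flagged) and `N2wo = 1/a22`, and the
#' focal species' invasion growth rates into those residents,
#' `IGRw = r1*(1 - a12*N2w - beta1*Nh)` and `IGRwo = r1*(1 - a12*N2wo)`.
#' The herbivore benefits the focal species when `IGRw > IGRwo`, which for
#' `beta2 > 0, Nh > 0` is equivalent to the density-independent coefficient
#' condition `beta1/beta2 < a12/a22` (the report's `margin` is
#' `a12/a22 - beta1/beta2`) as long as the resident persists under
#' herbivory (`beta2*Nh < 1`, the interior-equilibrium domain of the
#' derivation); once herbivory alone collapses the resident the floored
#' `N2w = 0` takes over and only the IGR comparison remains meaningful.
#'
#' @param params a [model_params()] object.
#' @return An `invasion_report` list: `N2w`, `N2wo`, `IGRw`, `IGRwo`,
#'   `benefit` in `{"benefit","harm","neutral"}`, `margin` (NA with
#'   `margin_defined = FALSE` when `beta2 = 0`), `resident_collapsed`.
#' @examples
#' invasion_analysis(fixture_params(Nh = 1))
#' @export
invasion_analysis <- function(params) {
  params <- validate_params(params)
  press <- params$beta2 * params$Nh
  resident_collapsed <- (1 - press) < 0
  N2w <- max(0, 1 - press) / params$a22
  N2wo <- 1 / params$a22
  IGRw <- params$r1 * (1 - params$a12 * N2w - params$beta1 * params$Nh)
  IGRwo <- params$r1 * (1 - params$a12 * N2wo)
  benefit <- if (IGRw > IGRwo) "benefit" else if (IGRw < IGRwo) "harm"
             else "neutral"
  margin_defined <- params$beta2 > 0
  margin <- if (margin_defined)
    params$a12 / params$a22 - params$beta1 / params$beta2 else NA_real_
  structure(list(N2w = N2w, N2wo = N2wo, IGRw = IGRw, IGRwo = IGRwo,
                 benefit = benefit, margin = margin,
                 margin_defined = margin_defined,
                 resident_collapsed = resident_collapsed),
            class = "invasion_report")
}

#' @export
print.invasion_report <- function(x, ...) {
  cat("Invasion analysis (focal = species 1)\n")
  cat(sprintf("  resident sp2 equilibrium: N2wo = %g (no herbivore), N2w = %g%s\n",
              x$N2wo, x$N2w,
              if (x$resident_collapsed) " [collapsed under herbivory]" else ""))
  cat(sprintf("  IGRwo = %g, IGRw = %g per day\n", x$IGRwo, x$IGRw))
  cat(sprintf("  verdict: %s (margin a12/a22 - beta1/beta2 = %s)\n",
              x$benefit,
              if (x$margin_defined) format(x$margin) else "undefined: beta2 = 0"))
  invisible(x)
}

#' Does herbivory benefit the focal species?
#'
#' Pure coefficient-ratio check: the focal species gains from herbivory iff
#' the ratio of consumption pressures `beta1/beta2` is smaller than the
#' competition ratio `a12/a22`. The verdict is independent of both species'
#' densities and of the (positive) herbivore abundance, and agrees with the
#' invasion-growth-rate comparison of [invasion_analysis()] whenever
#' `beta2 > 0` and `0 < beta2*Nh < 1` (resident persists under herbivory).
#'
#' @param params a [model_params()] object; requires `beta2 > 0`.
#' @return List with `verdict` in `{"benefit","harm","neutral"}` and
#'   `margin = a12/a22 - beta1/beta2`.
#' @export
herbivory_benefit <- function(params) {
  params <- validate_params(params)
  if (params$beta2 <= 0)
    stop("herbivory_benefit is undefined when beta2 = 0", call. = FALSE)
  margin <- params$a12 / params$a22 - params$beta1 / params$beta2
  verdict <- if (margin > 0) "benefit" else if (margin < 0) "harm"
             else "neutral"
  list(verdict = verdict, margin = margin)
}

#' Classify the long-run two-species outcome
#'
#' Mutual-invasibility classification under constant herbivory. Each
#' species' invasion growth rate into the other's (herbivory-adjusted)
#' single-species resident equilibrium is
#' `IGR1 = r1*(1 - a12*max(0, 1 - beta2*Nh)/a22 - beta1*Nh)` and
#' symmetrically for species 2. If herbivory alone makes both growth
#' brackets non-positive (`beta_i*Nh >= 1` for both), both populations
#' collapse. Otherwise: both IGRs strictly positive gives coexistence; a
#' single positive IGR gives exclusion by that species; neither positive
#' gives founder control (the initially abundant species wins). Ties are
#' broken to the weaker label: coexistence requires strict positivity.
#'
#' @param params a [model_params()] object.
#' @return An `outcome_label` list: `label` in `{"coexistence",
#'   "species1_excludes", "species2_excludes", "founder_control",
#'   "both_collapse"}`, plus `IGR1`, `IGR2`.
#' @examples
#' classify_outcome(fixture_params(Nh = 0))$label  # coexistence
#' classify_outcome(fixture_params(Nh = 2))$label  # both_collapse
#' @export
classify_outcome <- function(params) {
  params <- validate_params(params)
  b1 <- 1 - params$beta1 * params$Nh
  b2 <- 1 - params$beta2 * params$Nh
  N2res <- max(0, b2) / params$a22
  N1res <- max(0, b1) / params$a11
  IGR1 <- params$r1 * (1 - params$a12 * N2res - params$beta1 * params$Nh)
  IGR2 <- params$r2 * (1 - params$a21 * N1res - params$beta2 * params$Nh)
  label <- if (b1 <= 0 && b2 <= 0) {
    "both_collapse"
  } else if (IGR1 > 0 && IGR2 > 0) {
    "coexistence"
  } else if (IGR1 > 0) {
    "species1_excludes"
  } else if (IGR2 > 0) {
    "species2_excludes"
  } else {
    "founder_control"
  }
  structure(list(label = label, IGR1 = IGR1, IGR2 = IGR2),
            class = "outcome_label")
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(sprintf("Predicted outcome: %s (IGR1 = %g, IGR2 = %g per day)\n",
              x$label, x$IGR1, x$IGR2))
  invisible(x)
}

#' Smallest herbivore number that collapses both species
#'
#' Scans integer herbivore abundances `1..max_herbivores` and returns the
#' first at which [classify_outcome()] reports `both_collapse` (both growth
#' brackets made non-positive by herbivory alone), mirroring the prediction
#' that too many grazers extinguish both competitors.
#'
#' @param params a [model_params()] object; its `Nh` field is ignored.
#' @param max_herbivores largest abundance scanned (>= 1).
#' @return List with `min_collapse_Nh` (integer, or `NA` if no collapse
#'   within range) and `outcomes`, a data.frame of `Nh` and outcome label
#'   for every scanned abundance.
#' @examples
#' collapse_search(fixture_params(), max_herbivores = 4)$min_collapse_Nh
#' @export
collapse_search <- function(params, max_herbivores = 10) {
  params <- validate_params(params)
  if (max_herbivores < 1) stop("max_herbivores must be >= 1", call. = FALSE)
  nh <- seq_len(max_herbivores)
  labels <- vapply(nh, function(h) {
    p <- params; p$Nh <- h
    classify_outcome(p)$label
  }, character(1))
  hit <- which(labels == "both_collapse")
  list(min_collapse_Nh = if (length(hit)) nh[hit[1]] else NA_integer_,
       outcomes = data.frame(Nh = nh, label = labels))
}
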