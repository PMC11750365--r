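#' Measurement-noise model for the synthetic generator
#'
#' Final densities receive multiplicative lognormal noise with coefficient
#' of variation `cv` (mean-preserving: the log-scale mean is `-sigma^2/2`).
#' Focal counts of species 1 (fronds) are additionally rounded to the
#' nearest integer, minimum 1 unless truly extinct, when `integerize` is
#' `TRUE`. With `cv = 0` generation is deterministic; rounding is then also
#' disabled by default so that a noiseless table is the exact idealized
#' model output (the identity check the round-trip tests rely on).
#'
#' @param cv coefficient of variation (>= 0; default 0.1, a realistic
#'   replicate scatter for count/OD endpoints).
#' @param integerize round species-1 counts to integers; default `cv > 0`.
#' @param seed integer seed; required whenever `cv > 0`.
#' @return A `noise_model` list.
#' @export
noise_model <- function(cv = 0.1, integerize = cv > 0, seed = NULL) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (cv > 0 && is.null(seed))
    stop("a seed is required when cv > 0", call. = FALSE)
  structure(list(cv = cv, integerize = integerize, seed = seed),
            class = "noise_model")
}

noise_sigma <- function(noise) sqrt(log(1 + noise$cv^2))

apply_noise <- function(x, noise, integer_counts = FALSE) {
  if (noise$cv > 0) {
    sig <- noise_sigma(noise)
    x <- x * rlnorm(length(x), meanlog = -sig^2 / 2, sdlog = sig)
  }
  if (integer_counts && noise$integerize)
    x <- ifelse(x == 0, 0, pmax(1, round(x)))
  x
}

#' Default laboratory assay design
#'
#' Mirrors the model-guided two-species assay grid: a duckweed monoculture
#' gradient of 5-1000 fronds in triplicate over 7 days; an algae gradient
#' of 0.0095-9.24 (10^6 cells ml^-1, n = 4) over 7 days; the same gradients
#' against a fixed competitor (algae held at 1.33 with daily resets;
#' duckweed held at 100 fronds with resets on days 2 and 5); and 24 h
#' feeding assays (duckweed: 100 fronds vs one snail, n = 6, control n = 4;
#' algae: 12.6 starting concentration vs one snail, n = 8, control n = 4).
#'
#' @param n_rep optional single replicate count overriding every arm (used
#'   by the simulation studies).
#' @return A `design_spec` list, one element per assay type.
#' @export
design_spec <- function(n_rep = NULL) {
  d <- list(
    mono_1 = list(levels = c(5, 50, 100, 300, 600, 1000), n_rep = 3,
                  duration = 7, competitor = 0, resets = numeric(), nh = 0),
    mono_2 = list(levels = c(0.0095, 0.59, 0.13, 1.64, 3.91, 7.66, 9.24),
                  n_rep = 4, duration = 7, competitor = 0,
                  resets = numeric(), nh = 0),
    inter_1 = list(levels = c(5, 50, 100, 300, 600, 1000), n_rep = 3,
                   duration = 7, competitor = 1.33, resets = 1:6, nh = 0),
    inter_2 = list(levels = c(0.0095, 0.59, 0.13, 1.64, 3.91, 7.66, 9.24),
                   n_rep = 4, duration = 7, competitor = 100,
                   resets = c(2, 5), nh = 0),
    feed_1 = list(levels = 100, n_rep = 6, n_rep_ctrl = 4, duration = 1,
                  competitor = 0, resets = numeric(), nh = 1),
    feed_2 = list(levels = 12.6, n_rep = 8, n_rep_ctrl = 4, duration = 1,
                  competitor = 0, resets = numeric(), nh = 1))
  if (!is.null(n_rep)) {
    d <- lapply(d, function(a) {
      a$n_rep <- n_rep
      if (!is.null(a$n_rep_ctrl)) a$n_rep_ctrl <- n_rep
      a
    })
  }
  structure(d, class = "design_spec")
}

# deterministic model endpoint for one assay record
assay_endpoint <- function(truth, type, n0, duration, competitor, resets,
                           nh, fixed_mode = "clamp") {
  focal <- as.integer(substring(type, nchar(type)))
  pv <- params_vector(truth)
  pv[9] <- nh
  init <- if (focal == 1) c(n0, competitor) else c(competitor, n0)
  if (competitor > 0) {
    if (fixed_mode == "clamp") {
      # freeze the background species by zeroing its intrinsic rate
      pv[if (focal == 1) 2 else 1] <- 0
    } else {
      p <- truth; p$Nh <- nh
      sch <- reset_schedule(time = resets,
                            species = rep(if (focal == 1) 2L else 1L,
                                          length(resets)),
                            value = rep(competitor, length(resets)))
      tr <- simulate_model(p, init, t_end = duration, schedule = sch,
                           times = duration, rtol = 1e-10, atol = 1e-12)
      return(tr[[if (focal == 1) "N1" else "N2"]][nrow(tr)])
    }
  }
  out <- rk45_lv2(init, 0, duration, pv, 1e-10, 1e-12, 1e-12)
  out[1, focal + 1]
}

#' Generate a synthetic assay table from known ground truth
#'
#' For every replicate of every assay arm, integrates the two-species model
#' under the arm's conditions (absent species at 0, herbivores as a constant
#' `Nh`), applies the noise model to the final density, and emits the
#' standard assay-table schema. The fixed competitor in `inter_*` assays is
#' by default held exactly constant (`fixed_mode = "clamp"`), the
#' idealization the laboratory reset protocol approximates and the regime
#' under which the constant-competitor estimators are exactly consistent;
#' `fixed_mode = "reset"` instead lets the background species grow and
#' resets it at the protocol's reset days (deliberately inconsistent with
#' the constant-competitor fit; useful for robustness checks).
#'
#' @param truth a [model_params()] object (its `Nh` field is ignored; each
#'   arm sets its own herbivore count).
#' @param design a [design_spec()].
#' @param noise a [noise_model()].
#' @param fixed_mode `"clamp"` (default) or `"reset"`.
#' @return A validated assay table (data.frame).
#' @examples
#' tab <- gen_assay_table(fixture_params(), noise = noise_model(cv = 0))
#' head(tab)
#' @export
gen_assay_table <- function(truth, design = design_spec(),
                            noise = noise_model(cv = 0),
                            fixed_mode = c("clamp", "reset")) {
  truth <- validate_params(truth)
  fixed_mode <- match.arg(fixed_mode)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  rows <- list()
  for (type in names(design)) {
    arm <- design[[type]]
    is_feed <- grepl("^feed", type)
    reps <- expand.grid(n0 = arm$levels, rep = seq_len(arm$n_rep))
    reps$nh <- arm$nh
    if (is_feed) {
      ctrl <- expand.grid(n0 = arm$levels, rep = seq_len(arm$n_rep_ctrl))
      ctrl$nh <- 0
      reps <- rbind(reps, ctrl)
    }
    # one deterministic endpoint per (level, nh); replicate then add noise
    key <- paste(reps$n0, reps$nh)
    ends <- vapply(unique(key), function(k) {
      i <- match(k, key)
      assay_endpoint(truth, type, reps$n0[i], arm$duration, arm$competitor,
                     arm$resets, reps$nh[i], fixed_mode)
    }, numeric(1))
    nf <- apply_noise(ends[key], noise,
                      integer_counts = grepl("1$", type))
    rows[[type]] <- data.frame(
      assay_type = type,
      replicate = stats::ave(reps$n0, key, FUN = seq_along),
      n0 = reps$n0, n_final = unname(nf), duration_days = arm$duration,
      competitor_density = arm$competitor, n_herbivores = reps$nh,
      reset_times = paste(arm$resets, collapse = ";"))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  validate_assay_table(tab)
  tab
}

#' Generate synthetic OD750 calibration points
#'
#' Evenly spaced blank-corrected ODs from 0 (the blank itself) to `od_max`,
#' with `cells = slope * od` plus multiplicative noise.
#'
#' @param slope true cells (10^6 ml^-1) per OD unit (default 10, i.e. an
#'   OD of 1 is about 10^7 cells ml^-1, covering a 0-22 concentration range
#'   at `od_max = 2.2`).
#' @param n_points number of points including the blank (>= 3).
#' @param noise a [noise_model()].
#' @param od_max largest blank-corrected OD.
#' @param blank_od OD of the pure-medium blank.
#' @return data.frame with `od750`, `cells_per_ml`.
#' @export
gen_calibration <- function(slope = 10, n_points = 12,
                            noise = noise_model(cv = 0), od_max = 2.2,
                            blank_od = 0.04) {
  if (slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  x <- seq(0, od_max, length.out = n_points)
  cells <- apply_noise(slope * x, noise)
  cells[x == 0] <- 0  # the blank has no cells by construction
  data.frame(od750 = blank_od + x, cells_per_ml = cells)
}

#' Generate a three-species indoor microcosm endpoint table
#'
#' Simulates every combination of starting densities and herbivore counts
#' for `days` days with full two-species dynamics (no clamping of either
#' competitor) and emits noisy endpoints for both species, enabling
#' end-to-end prediction-versus-observation checks. Default starting
#' combinations span high duckweed/low algae through low duckweed/high
#' algae, and herbivore counts 0, 1 and 2.
#'
#' @param truth a [model_params()] object (`Nh` ignored).
#' @param inits data.frame with columns `n1_0`, `n2_0` (default: the four
#'   standard combinations).
#' @param nh_levels herbivore counts (default `c(0, 1, 2)`).
#' @param days assay duration (default 14).
#' @param n_rep replicates per treatment (default 6).
#' @param noise a [noise_model()].
#' @return data.frame with one row per replicate beaker: `treatment`,
#'   `n1_0`, `n2_0`, `n_herbivores`, `replicate`, `duration_days`,
#'   `n1_final`, `n2_final`.
#' @export
gen_microcosm <- function(truth,
                          inits = data.frame(
                            n1_0 = c(1000, 600, 300, 100),
                            n2_0 = c(0.9, 4.1, 4.1, 5.8)),
                          nh_levels = c(0, 1, 2), days = 14, n_rep = 6,
                          noise = noise_model(cv = 0)) {
  truth <- validate_params(truth)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  rows <- list()
  k <- 0
  for (i in seq_len(nrow(inits))) for (nh in nh_levels) {
    pv <- params_vector(truth)
    pv[9] <- nh
    end <- rk45_lv2(c(inits$n1_0[i], inits$n2_0[i]), 0, days, pv,
                    1e-8, 1e-10, 1e-12)
    n1 <- apply_noise(rep(end[1, 2], n_rep), noise, integer_counts = TRUE)
    n2 <- apply_noise(rep(end[1, 3], n_rep), noise)
    k <- k + 1
    rows[[k]] <- data.frame(
      treatment = sprintf("d%g_a%g_h%d", inits$n1_0[i], inits$n2_0[i], nh),
      n1_0 = inits$n1_0[i], n2_0 = inits$n2_0[i], n_herbivores = nh,
      replicate = seq_len(n_rep), duration_days = days,
      n1_final = n1, n2_final = n2)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Surface-coverage trajectory of the focal species
#'
#' Maps simulated focal-species density to percentage surface coverage,
#' `100 * N1 * a11` capped at 100 (full cover at carrying capacity), sampled
#' weekly — the shape of the outdoor pond observations.
#'
#' @param params a [model_params()] object (including the compartment's
#'   `Nh`).
#' @param weeks number of weeks observed.
#' @param init initial state `c(N1, N2)`.
#' @return Numeric vector of coverages (%) at weeks `0..weeks`.
#' @export
coverage_trajectory <- function(params, weeks, init = c(100, 1)) {
  tr <- simulate_model(params, init, t_end = 7 * weeks,
                       times = 7 * (0:weeks))
  pmin(100, 100 * tr$N1 * params$a11)
}

#' Generate a paired weekly coverage series
#'
#' Emits the herbivory/control compartment pair consumed by the normalized
#' fitness metric. The truth is a pair of coverage trajectories (e.g. from
#' [coverage_trajectory()] with `Nh > 0` and `Nh = 0`); noise is applied
#' independently to each compartment, and coverages are capped at 100%.
#'
#' @param sa_herb,sa_ctr numeric coverage trajectories of equal length
#'   (weeks 0..W).
#' @param noise a [noise_model()].
#' @return data.frame with `week`, `sa_herb`, `sa_ctr`, `nfc` (normalized
#'   fitness change).
#' @export
gen_field_series <- function(sa_herb, sa_ctr, noise = noise_model(cv = 0)) {
  if (length(sa_herb) != length(sa_ctr) || length(sa_herb) < 2)
    stop("need coverage trajectories of equal length >= 2 (weeks >= 1)",
         call. = FALSE)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  h <- pmin(100, apply_noise(sa_herb, noise))
  c0 <- pmin(100, apply_noise(sa_ctr, noise))
  data.frame(week = seq_along(h) - 1, sa_herb = h, sa_ctr = c0,
             nfc = suppressWarnings(normalized_fitness(h, c0)))
}

#' Write a complete worked-example fixture directory
#'
#' Emits every input the pipeline consumes: `assays.csv`, `calibration.csv`,
#' `microcosm.csv`, `field.csv` and the ground truth `truth.json`.
#'
#' @param dir output directory (created if needed).
#' @param truth a [model_params()] object.
#' @param design a [design_spec()].
#' @param noise a [noise_model()].
#' @return The directory path, invisibly.
#' @export
write_fixtures <- function(dir, truth = fixture_params(),
                           design = design_spec(),
                           noise = noise_model(cv = 0.1, seed = 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_assay_table(gen_assay_table(truth, design, noise),
                    file.path(dir, "assays.csv"))
  write.csv(gen_calibration(noise = noise), file.path(dir, "calibration.csv"),
            row.names = FALSE)
  write.csv(gen_microcosm(truth, noise = noise),
            file.path(dir, "microcosm.csv"), row.names = FALSE)
  ph <- truth; ph$Nh <- 1
  pc <- truth; pc$Nh <- 0
  herb <- coverage_trajectory(ph, weeks = 9, init = c(1000, 1))
  ctr <- coverage_trajectory(pc, weeks = 9, init = c(1000, 1))
  write.csv(gen_field_series(herb, ctr, noise), file.path(dir, "field.csv"),
            row.names = FALSE)
  write_params(truth, file.path(dir, "truth.json"))
  invisible(dir)
}
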