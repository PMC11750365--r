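#' Model parameters for two competing species sharing a herbivore
#'
#' Bundles the coefficients of the competition-with-herbivory model
#' \deqn{dN_1/dt = r_1 N_1 (1 - a_{11} N_1 - a_{12} N_2 - \beta_1 N_h)}
#' \deqn{dN_2/dt = r_2 N_2 (1 - a_{22} N_2 - a_{21} N_1 - \beta_2 N_h)}
#' The herbivore population `Nh` is a fixed constant (no herbivore
#' dynamics). The engine is unit-agnostic: the two species may be counted in
#' different density units (e.g. duckweed fronds vs 10^6 algal cells per ml)
#' because every cross coefficient absorbs the scale of the density it
#' multiplies.
#'
#' @param r1,r2 intrinsic growth rates (per day); must be > 0.
#' @param a11,a22 intraspecific competition coefficients (per unit of own
#'   density); must be > 0 so growth is self-limited.
#' @param a12,a21 interspecific competition coefficients (per unit of the
#'   other species' density); must be >= 0. `a12` is the effect of species 2
#'   on species 1.
#' @param beta1,beta2 herbivore consumption coefficients (per herbivore
#'   individual); must be >= 0. Herbivory pressure on species i is
#'   `beta_i * Nh`.
#' @param Nh herbivore abundance (individuals, constant); must be >= 0.
#' @return An object of class `model_params` (a named list of the nine
#'   coefficients).
#' @examples
#' p <- model_params(r1 = 0.3, r2 = 0.7, a11 = 0.001, a12 = 0.09,
#'                   a21 = 0, a22 = 0.1, beta1 = 0.6, beta2 = 1.1, Nh = 1)
#' p
#' @export
model_params <- function(r1, r2, a11, a12, a21, a22, beta1, beta2, Nh = 0) {
  p <- list(r1 = r1, r2 = r2, a11 = a11, a12 = a12, a21 = a21, a22 = a22,
            beta1 = beta1, beta2 = beta2, Nh = Nh)
  validate_params(p)
}

#' @rdname model_params
#' @param x a list or named numeric vector with the nine parameter fields.
#' @export
as_model_params <- function(x) {
  x <- as.list(x)
  need <- param_names()
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing parameter field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  do.call(model_params, lapply(x[need], as.numeric))
}

param_names <- function() {
  c("r1", "r2", "a11", "a12", "a21", "a22", "beta1", "beta2", "Nh")
}

validate_params <- function(p) {
  v <- unlist(p[param_names()])
  if (any(!is.finite(v)))
    stop("non-finite model parameter(s): ",
         paste(param_names()[!is.finite(v)], collapse = ", "), call. = FALSE)
  if (p$r1 <= 0 || p$r2 <= 0)
    stop("intrinsic growth rates r1, r2 must be > 0", call. = FALSE)
  if (p$a11 <= 0 || p$a22 <= 0)
    stop("intraspecific coefficients a11, a22 must be > 0 (self-limitation)",
         call. = FALSE)
  if (p$a12 < 0 || p$a21 < 0 || p$beta1 < 0 || p$beta2 < 0 || p$Nh < 0)
    stop("a12, a21, beta1, beta2 and Nh must be >= 0", call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-species competition/herbivory parameters\n")
  cat(sprintf("  r1 = %g, a11 = %g, a12 = %g, beta1 = %g\n",
              x$r1, x$a11, x$a12, x$beta1))
  cat(sprintf("  r2 = %g, a22 = %g, a21 = %g, beta2 = %g\n",
              x$r2, x$a22, x$a21, x$beta2))
  cat(sprintf("  Nh = %g herbivore(s)\n", x$Nh))
  invisible(x)
}

params_vector <- function(p) {
  unlist(p[param_names()], use.names = FALSE)
}

#' Read or write model parameters as JSON
#'
#' Parameter files are flat JSON objects with the nine coefficient fields
#' (`r1 r2 a11 a12 a21 a22 beta1 beta2 Nh`), the schema every pipeline
#' subcommand consumes and emits.
#'
#' @param path file path.
#' @return `read_params()` returns a `model_params` object;
#'   `write_params()` invisibly returns `path`.
#' @export
read_params <- function(path) {
  as_model_params(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_params
#' @param params a `model_params` object.
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  jsonlite::write_json(params[param_names()], path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Default ground-truth parameter set used by the worked examples
#'
#' A fixture in the qualitative regime reported for the
#' duckweed-algae-snail system: asymmetric competition (algae suppress
#' duckweed, duckweed does not measurably suppress algae, `a21 = 0`), the
#' herbivory-benefit condition `beta1/beta2 < a12/a22` holding, coexistence
#' without the herbivore with a small focal population, focal dominance at
#' one herbivore, and collapse of both species at two herbivores. The
#' numeric values are package fixture choices, not measured coefficients.
#'
#' @param Nh herbivore abundance to embed (default 1).
#' @return A `model_params` object.
#' @export
fixture_params <- function(Nh = 1) {
  model_params(r1 = 0.3, r2 = 0.7, a11 = 0.001, a12 = 0.09, a21 = 0,
               a22 = 0.1, beta1 = 0.6, beta2 = 1.1, Nh = Nh)
}
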