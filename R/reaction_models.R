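#' Solid-state reaction model catalogue
#'
#' Constructs a differential mechanism function f(alpha) from the standard
#' ICTAC families used by model-free kinetic studies:
#'
#' * `"Fn"` reaction order, f = (1 - a)^n (shortcuts `"F0.5"`, `"F1"`,
#'   `"F2"` fix n);
#' * `"A2"`, `"A3"` Avrami-Erofeev nucleation,
#'   f = m (1 - a) \[-ln(1 - a)\]^(1 - 1/m);
#' * `"D1"`, `"D2"`, `"D3"` diffusion models;
#' * `"R2"`, `"R3"` contracting area / volume.
#'
#' @param model_id one of `"F0.5"`, `"F1"`, `"F2"`, `"Fn"`, `"A2"`, `"A3"`,
#'   `"D1"`, `"D2"`, `"D3"`, `"R2"`, `"R3"`.
#' @param n reaction order, required (and only used) when `model_id = "Fn"`.
#' @return an object of class `reaction_model` with elements `model_id`,
#'   `parameters` and `f`, the vectorised mechanism function valid on the
#'   open interval (0, 1).
#' @examples
#' m <- reaction_model("F1")
#' m$f(0.5)  # 0.5
#' @export
reaction_model <- function(model_id, n = NULL) {
  families <- c("F0.5", "F1", "F2", "Fn", "A2", "A3",
                "D1", "D2", "D3", "R2", "R3")
  model_id <- match.arg(model_id, families)
  if (model_id == "Fn") {
    if (is.null(n) || !is.finite(n)) {
      stop("model 'Fn' requires a finite reaction order `n`", call. = FALSE)
    }
  } else if (startsWith(model_id, "F")) {
    n <- as.numeric(sub("^F", "", model_id))
  }
  f <- switch(model_id,
    "F0.5" = , "F1" = , "F2" = , "Fn" = {
      force(n)
      function(alpha) (1 - alpha)^n
    },
    "A2" = function(alpha) 2 * (1 - alpha) * (-log1p(-alpha))^(1 / 2),
    "A3" = function(alpha) 3 * (1 - alpha) * (-log1p(-alpha))^(2 / 3),
    "D1" = function(alpha) 1 / (2 * alpha),
    "D2" = function(alpha) 1 / (-log1p(-alpha)),
    "D3" = function(alpha) {
      3 * (1 - alpha)^(2 / 3) / (2 * (1 - (1 - alpha)^(1 / 3)))
    },
    "R2" = function(alpha) 2 * (1 - alpha)^(1 / 2),
    "R3" = function(alpha) 3 * (1 - alpha)^(2 / 3)
  )
  structure(
    list(model_id = model_id,
         parameters = if (startsWith(model_id, "F")) c(n = n) else numeric(),
         f = f),
    class = "reaction_model"
  )
}

#' @export
print.reaction_model <- function(x, ...) {
  pars <- if (length(x$parameters)) {
    paste0(" (", paste(names(x$parameters), x$parameters,
                       sep = " = ", collapse = ", "), ")")
  } else ""
  cat("<reaction_model> ", x$model_id, pars, "\n", sep = "")
  invisible(x)
}

#' Kinetic triplet (Ea, A, f(alpha))
#'
#' Bundles the activation energy, pre-exponential factor and reaction model
#' that fully specify single-step solid-state kinetics under the Arrhenius
#' rate constant k(T) = A exp(-Ea / (R T)).
#'
#' @param Ea activation energy, J mol^-1 (> 0).
#' @param A pre-exponential factor, min^-1 (> 0).
#' @param model a [reaction_model()], or a model id string passed through to
#'   [reaction_model()].
#' @return an object of class `kinetic_triplet`.
#' @examples
#' kinetic_triplet(Ea = 105e3, A = 1e9, model = "F1")
#' @export
kinetic_triplet <- function(Ea, A, model = "F1") {
  stopifnot(is.numeric(Ea), length(Ea) == 1L, is.numeric(A), length(A) == 1L)
  if (!is.finite(Ea) || Ea <= 0) stop("Ea must be positive", call. = FALSE)
  if (!is.finite(A) || A <= 0) stop("A must be positive", call. = FALSE)
  if (is.character(model)) model <- reaction_model(model)
  if (!inherits(model, "reaction_model")) {
    stop("`model` must be a reaction_model", call. = FALSE)
  }
  structure(list(Ea = Ea, A = A, model = model), class = "kinetic_triplet")
}

#' @export
print.kinetic_triplet <- function(x, ...) {
  cat(sprintf("<kinetic_triplet> Ea = %.4g kJ/mol, A = %.4g /min, model %s\n",
              x$Ea / 1000, x$A, x$model$model_id))
  invisible(x)
}

#' Linear heating program
#'
#' @param beta heating rate, K min^-1 (> 0).
#' @param T_start,T_end temperature range, K (`T_end > T_start`).
#' @param step temperature sampling interval, K; must not exceed
#'   `(T_end - T_start) / 50`.
#' @return an object of class `heating_program`.
#' @examples
#' heating_program(beta = 10, T_start = 450, T_end = 800)
#' @export
heating_program <- function(beta, T_start, T_end, step = 0.5) {
  stopifnot(is.numeric(beta), is.numeric(T_start), is.numeric(T_end),
            is.numeric(step))
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (T_end <= T_start) stop("T_end must exceed T_start", call. = FALSE)
  if (step <= 0 || step > (T_end - T_start) / 50) {
    stop("step must be positive and at most (T_end - T_start)/50",
         call. = FALSE)
  }
  structure(list(beta = beta, T_start = T_start, T_end = T_end, step = step),
            class = "heating_program")
}

#' Noise specification for synthetic thermograms
#'
#' @param mass_noise_sd relative standard deviation of multiplicative
#'   Gaussian mass noise (>= 0).
#' @param drift linear baseline drift per kelvin, as a fraction of the
#'   initial mass.
#' @param seed integer random seed; a fixed seed yields identical output.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(mass_noise_sd = 0, drift = 0, seed = 1L) {
  stopifnot(is.numeric(mass_noise_sd), is.numeric(drift))
  if (mass_noise_sd < 0) stop("mass_noise_sd must be >= 0", call. = FALSE)
  structure(list(mass_noise_sd = mass_noise_sd, drift = drift,
                 seed = as.integer(seed)),
            class = "noise_spec")
}
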