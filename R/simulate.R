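#' Simulate a conversion curve for a single-step decomposition
#'
#' Integrates the non-isothermal single-step rate law
#' d(alpha)/dT = (A / beta) f(alpha) exp(-Ea / (R T))
#' over the heating program, using an adaptive stiff-capable solver
#' (`deSolve::lsoda`) with relative tolerance 1e-8 and absolute tolerance
#' 1e-12. The temperature integral has no closed form, so the curve is the
#' numerical solution sampled on the program's temperature grid.
#'
#' The returned rate d(alpha)/dT is evaluated from the rate-law right-hand
#' side at the solved alpha values, not by finite differencing.
#'
#' @param triplet a [kinetic_triplet()].
#' @param program a [heating_program()].
#' @return an object of class `conversion_curve`: list with `temperature`
#'   (K, strictly increasing), `alpha` (non-decreasing, in \[0, 1\]),
#'   `rate` (d(alpha)/dT, K^-1) and `beta` (K min^-1).
#' @examples
#' tr <- kinetic_triplet(120e3, 1e10, "F1")
#' pr <- heating_program(10, 300, 900)
#' curve <- simulate_conversion(tr, pr)
#' @export
simulate_conversion <- function(triplet, program) {
  stopifnot(inherits(triplet, "kinetic_triplet"),
            inherits(program, "heating_program"))
  Ea <- triplet$Ea
  A <- triplet$A
  f <- triplet$model$f
  beta <- program$beta
  grid <- seq(program$T_start, program$T_end, by = program$step)
  if (grid[length(grid)] < program$T_end) grid <- c(grid, program$T_end)

  # alpha = 0 is singular for diffusion/nucleation models; start a hair in.
  alpha0 <- 1e-10
  cap <- 1 - 1e-12
  rhs <- function(T, y, parms) {
    a <- min(max(y[1], alpha0), cap)
    list((A / beta) * f(a) * exp(-Ea / (R_GAS * T)))
  }
  sol <- try(deSolve::lsoda(y = alpha0, times = grid, func = rhs,
                            parms = NULL, rtol = 1e-8, atol = 1e-12),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(grid) ||
      anyNA(sol[, 2])) {
    stop(sprintf(
      "integration failed for triplet (Ea = %.4g J/mol, A = %.4g /min, %s)",
      Ea, A, triplet$model$model_id), call. = FALSE)
  }
  alpha <- as.numeric(sol[, 2]) - alpha0  # alpha(T_start) is exactly 0
  if (any(alpha > cap & grid < program$T_end)) {
    warning("alpha reached 1 before T_end; clamped", call. = FALSE)
  }
  alpha <- pmin(pmax(alpha, 0), 1)
  alpha <- cummax(alpha)  # solver wiggle below tolerance
  a_eval <- pmin(pmax(alpha, alpha0), cap)
  rate <- (A / beta) * f(a_eval) * exp(-Ea / (R_GAS * grid))
  rate[alpha >= cap] <- 0
  new_conversion_curve(grid, alpha, rate, beta)
}

new_conversion_curve <- function(temperature, alpha, rate, beta) {
  structure(list(temperature = temperature, alpha = alpha,
                 rate = rate, beta = beta),
            class = "conversion_curve")
}

#' @export
print.conversion_curve <- function(x, ...) {
  cat(sprintf(
    "<conversion_curve> beta = %g K/min, %d points, T %g-%g K, alpha %.3g-%.3g\n",
    x$beta, length(x$temperature), min(x$temperature), max(x$temperature),
    min(x$alpha), max(x$alpha)))
  invisible(x)
}

#' Convert a conversion curve into a mass-loss thermogram
#'
#' Inverts the conversion definition alpha = (w0 - wt) / (w0 - wf):
#' mass(T) = w0 - alpha(T) (w0 - wf), with time = (T - T_start) / beta.
#'
#' @param curve a `conversion_curve`.
#' @param w0 initial sample mass, mg (> `wf`).
#' @param wf final sample mass, mg (>= 0).
#' @param beta heating rate, K min^-1; defaults to the curve's.
#' @param label sample label stored in the thermogram metadata.
#' @return an object of class `thermogram`: `time` (min), `temperature` (K),
#'   `mass` (mg), `beta`, `meta`.
#' @export
conversion_to_thermogram <- function(curve, w0, wf, beta = curve$beta,
                                     label = "synthetic") {
  stopifnot(inherits(curve, "conversion_curve"))
  if (!is.numeric(w0) || !is.numeric(wf) || wf < 0 || w0 <= wf) {
    stop("require w0 > wf >= 0", call. = FALSE)
  }
  temperature <- curve$temperature
  mass <- w0 - curve$alpha * (w0 - wf)
  time <- (temperature - temperature[1]) / beta
  new_thermogram(time, temperature, mass, beta,
                 meta = list(label = label, w0 = w0, wf = wf))
}

new_thermogram <- function(time, temperature, mass, beta, meta = list()) {
  stopifnot(length(time) == length(temperature),
            length(mass) == length(temperature))
  if (length(temperature) < 50L) {
    stop("thermogram needs at least 50 points", call. = FALSE)
  }
  if (any(diff(temperature) <= 0)) {
    stop("temperature must be strictly increasing", call. = FALSE)
  }
  structure(list(time = time, temperature = temperature, mass = mass,
                 beta = beta, meta = meta),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf(
    "<thermogram> '%s': beta = %g K/min, %d points, T %g-%g K, mass %.3g-%.3g mg\n",
    if (is.null(x$meta$label)) "" else x$meta$label, x$beta,
    length(x$temperature), min(x$temperature), max(x$temperature),
    min(x$mass), max(x$mass)))
  invisible(x)
}

#' Add instrument-like noise to a thermogram
#'
#' Applies multiplicative Gaussian noise and a linear baseline drift:
#' mass_i <- mass_i (1 + eps_i) + drift (T_i - T_1) w0, with
#' eps_i ~ Normal(0, mass_noise_sd). Deterministic under a fixed seed.
#'
#' @param tg a `thermogram`.
#' @param spec a [noise_spec()].
#' @return a `thermogram` with perturbed mass.
#' @export
add_noise <- function(tg, spec) {
  stopifnot(inherits(tg, "thermogram"), inherits(spec, "noise_spec"))
  if (spec$mass_noise_sd == 0 && spec$drift == 0) return(tg)
  w0 <- if (!is.null(tg$meta$w0)) tg$meta$w0 else tg$mass[1]
  # scoped RNG: restore caller's stream afterwards
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(spec$seed)
  e <- stats::rnorm(length(tg$mass), mean = 0, sd = spec$mass_noise_sd)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  tg$mass <- tg$mass * (1 + e) +
    spec$drift * (tg$temperature - tg$temperature[1]) * w0
  tg$meta$noise <- spec
  tg
}

#' Predict the DTG peak temperature of a first-order decomposition
#'
#' For the F1 model the maximum of d(alpha)/dT occurs where
#' Ea beta / (R Tp^2) = A exp(-Ea / (R Tp)), the stationarity condition
#' behind the Kissinger peak-shift regression. The unique root is found by
#' bracketed bisection/interpolation to a relative tolerance of 1e-10.
#'
#' @param triplet a [kinetic_triplet()] whose model is `"F1"`.
#' @param beta heating rate, K min^-1.
#' @return peak temperature Tp, K.
#' @export
predict_peak_temperature <- function(triplet, beta) {
  stopifnot(inherits(triplet, "kinetic_triplet"), is.numeric(beta), beta > 0)
  if (triplet$model$model_id != "F1") {
    stop("analytic peak prediction is only defined for the F1 model",
         call. = FALSE)
  }
  Ea <- triplet$Ea
  A <- triplet$A
  # log form: g(T) = ln(Ea beta / (R T^2)) + Ea/(R T) - ln A, decreasing in T
  g <- function(T) log(Ea * beta / (R_GAS * T^2)) + Ea / (R_GAS * T) - log(A)
  lo <- 100; hi <- 3000
  while (g(hi) > 0 && hi < 1e6) hi <- hi * 2
  while (g(lo) < 0 && lo > 1e-3) lo <- lo / 2
  if (g(lo) < 0 || g(hi) > 0) {
    stop("no DTG peak in the bracketable temperature range", call. = FALSE)
  }
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-10 * (lo + hi) / 2)
  # polish to requested relative tolerance
  stats::uniroot(g, c(r$root * (1 - 1e-4), r$root * (1 + 1e-4)),
                 tol = 1e-10 * r$root, extendInt = "downX")$root
}
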