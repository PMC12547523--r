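#' Kissinger peak-shift regression
#'
#' Regresses ln(beta / Tp^2) on 1/Tp across heating rates. The slope gives
#' Ea = -slope * R and the intercept ln(A R / Ea) gives
#' A = (Ea / R) exp(intercept), with A in min^-1 when beta is in K min^-1.
#'
#' @param peaks a list of `peak_info` objects (or a data frame with columns
#'   `Tp` and `beta`) at >= 3 distinct heating rates.
#' @return list with `Ea` (J/mol), `A` (min^-1), `r2`, `slope`, `intercept`.
#' @export
kissinger_regression <- function(peaks) {
  if (is.data.frame(peaks)) {
    Tp <- peaks$Tp; beta <- peaks$beta
  } else {
    stopifnot(all(vapply(peaks, inherits, TRUE, "peak_info")))
    Tp <- vapply(peaks, `[[`, numeric(1), "Tp")
    beta <- vapply(peaks, `[[`, numeric(1), "beta")
  }
  if (length(Tp) < 3L) stop("need at least 3 peaks", call. = FALSE)
  dup <- duplicated(beta) | duplicated(beta, fromLast = TRUE)
  if (any(dup)) {
    agg <- tapply(Tp, beta, function(v) diff(range(v)))
    if (any(agg > 0)) {
      stop("duplicate heating rates with conflicting peak temperatures",
           call. = FALSE)
    }
  }
  fit <- .ols(1 / Tp, log(beta / Tp^2))
  Ea <- -fit$slope * R_GAS
  list(Ea = Ea, A = Ea / R_GAS * exp(fit$intercept), r2 = fit$r2,
       slope = fit$slope, intercept = fit$intercept)
}

#' Frequency factor from activation energy and peak temperature
#'
#' Direct evaluation of A = beta Ea exp(Ea / (R Tp)) / (R Tp^2). Linear in
#' beta; units min^-1 when beta is K min^-1.
#'
#' @param Ea activation energy, J mol^-1.
#' @param beta heating rate, K min^-1.
#' @param Tp DTG peak temperature, K.
#' @return A, min^-1 (vectorised over the inputs).
#' @export
frequency_factor <- function(Ea, beta, Tp) {
  if (any(Ea <= 0) || any(beta <= 0) || any(Tp <= 0)) {
    stop("Ea, beta and Tp must be positive", call. = FALSE)
  }
  beta * Ea * exp(Ea / (R_GAS * Tp)) / (R_GAS * Tp^2)
}

#' Per-conversion frequency factor combined across heating rates
#'
#' Evaluates the frequency factor at each (beta, Tp) pair for one
#' activation energy and combines them as a geometric mean, the natural
#' average for a quantity that enters the rate law exponentially.
#'
#' @param Ea activation energy, J mol^-1.
#' @param betas heating rates, K min^-1.
#' @param Tps peak temperatures, K (one per heating rate).
#' @return list with `per_beta_A` (min^-1, named by beta), `A` (geometric
#'   mean, min^-1), `Ea_used` and `Tp_used`.
#' @export
frequency_factors <- function(Ea, betas, Tps) {
  stopifnot(length(betas) == length(Tps))
  per <- frequency_factor(Ea, betas, Tps)
  names(per) <- format(betas)
  list(per_beta_A = per, A = exp(mean(log(per))), Ea_used = Ea,
       Tp_used = Tps)
}

#' Activation thermodynamics at a conversion level
#'
#' Transition-state quantities from the kinetic parameters:
#' * Gibbs energy of activation
#'   dG = Ea + R Tp ln(Kb Tp / (h A_s)), with the frequency factor
#'   converted to s^-1 (A_s = A / 60) because Kb T / h has units s^-1;
#' * enthalpy of activation dH = Ea - R T_alpha, with T_alpha the
#'   temperature characteristic of the conversion level;
#' * entropy of activation dS = (dH - dG) / Tm.
#'
#' The dH and dS identities hold exactly by construction, so the returned
#' values always satisfy dH = Ea - R T_alpha and dS = (dH - dG) / Tm.
#'
#' @param Ea activation energy, J mol^-1.
#' @param A frequency factor, min^-1.
#' @param T_alpha temperature used in the enthalpy relation, K.
#' @param Tp DTG peak temperature used in the Gibbs relation, K.
#' @param Tm reference temperature for the entropy relation, K; defaults to
#'   `Tp`.
#' @param alpha optional conversion label carried through.
#' @return an object of class `thermo_params`: `alpha`, `dG`, `dH` (J/mol),
#'   `dS` (J mol^-1 K^-1), `T_alpha`, `Tp`, `Tm`.
#' @export
thermo_params <- function(Ea, A, T_alpha, Tp, Tm = Tp, alpha = NA_real_) {
  if (any(c(T_alpha, Tp, Tm) <= 0)) {
    stop("temperatures must be positive", call. = FALSE)
  }
  if (A <= 0 || Ea <= 0) stop("Ea and A must be positive", call. = FALSE)
  A_s <- A / 60
  dG <- Ea + R_GAS * Tp * log(K_BOLTZMANN * Tp / (H_PLANCK * A_s))
  dH <- Ea - R_GAS * T_alpha
  dS <- (dH - dG) / Tm
  structure(list(alpha = alpha, dG = dG, dH = dH, dS = dS,
                 T_alpha = T_alpha, Tp = Tp, Tm = Tm, Ea = Ea, A = A),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "<thermo_params>%s dG = %.2f, dH = %.2f kJ/mol, dS = %.2f J/(mol K)\n",
    if (is.na(x$alpha)) "" else sprintf(" alpha = %.2f:", x$alpha),
    x$dG / 1000, x$dH / 1000, x$dS))
  invisible(x)
}

#' Per-conversion thermodynamic table for an Ea profile
#'
#' Combines an activation-energy profile with the iso-conversional
#' temperature table and DTG peak temperatures: for each conversion level,
#' the frequency factor is computed from that level's Ea at every
#' (beta, Tp) pair and geometric-mean combined, T_alpha is the mean over
#' heating rates of T(alpha), and the activation thermodynamics follow.
#'
#' @param profile an `ea_profile`.
#' @param table the `iso_table` of temperatures the profile was fitted on.
#' @param peaks list of `peak_info` (one per heating rate).
#' @param Tm reference temperature for the entropy relation; default
#'   `"lowest_beta_peak"` uses the DTG peak at the lowest heating rate, or
#'   supply a number in K.
#' @return data frame with one row per conversion: `method`, `alpha`,
#'   `Ea_kJ_mol`, `A_per_min`, `dH_kJ_mol`, `dG_kJ_mol`, `dS_J_molK`.
#' @export
thermo_table <- function(profile, table, peaks, Tm = "lowest_beta_peak") {
  stopifnot(inherits(profile, "ea_profile"), inherits(table, "iso_table"))
  Tps <- vapply(peaks, `[[`, numeric(1), "Tp")
  pbetas <- vapply(peaks, `[[`, numeric(1), "beta")
  ord <- order(pbetas)
  Tps <- Tps[ord]; pbetas <- pbetas[ord]
  Tm_val <- if (identical(Tm, "lowest_beta_peak")) Tps[1] else as.numeric(Tm)
  rows <- lapply(seq_len(nrow(profile$fits)), function(i) {
    a <- profile$fits$alpha[i]
    Ea <- profile$fits$Ea[i]
    ia <- which.min(abs(table$alpha_grid - a))
    T_alpha <- mean(table$T[ia, ], na.rm = TRUE)
    ff <- frequency_factors(Ea, pbetas, Tps)
    tp <- thermo_params(Ea, ff$A, T_alpha = T_alpha, Tp = Tps[1],
                        Tm = Tm_val, alpha = a)
    data.frame(method = profile$method, alpha = a, Ea_kJ_mol = Ea / 1000,
               A_per_min = ff$A, dH_kJ_mol = tp$dH / 1000,
               dG_kJ_mol = tp$dG / 1000, dS_J_molK = tp$dS)
  })
  do.call(rbind, rows)
}
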