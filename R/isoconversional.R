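#' Model-free isoconversional methods
#'
#' Constructs one of the four linearizations used to estimate the
#' activation energy at fixed conversion from how the temperature required
#' to reach that conversion shifts with heating rate:
#'
#' | method     | ordinate                 | Ea from slope          |
#' |------------|--------------------------|------------------------|
#' | `KAS`      | ln(beta / T^2)           | -slope * R             |
#' | `FWO`      | ln(beta)                 | -slope * R / 1.052     |
#' | `STARINK`  | ln(beta / T^1.92)        | -slope * R / 1.0037    |
#' | `FRIEDMAN` | ln(beta * d(alpha)/dT)   | -slope * R             |
#'
#' Each per-conversion fit is an ordinary least-squares regression of the
#' ordinate on 1/T across heating rates. FWO uses the Doyle approximation
#' constants 5.331 and 1.052; Starink uses exponent 1.92 and factor 1.0037.
#'
#' @param name one of `"KAS"`, `"FWO"`, `"STARINK"`, `"FRIEDMAN"`
#'   (case-insensitive; `"FRD"` is accepted for Friedman).
#' @return an object of class `iso_method` with elements `name`,
#'   `ordinate(beta, T, rate)` and `slope_to_Ea(slope)`.
#' @examples
#' iso_method("KAS")$slope_to_Ea(-12000)  # Ea in J/mol
#' @export
iso_method <- function(name) {
  name <- toupper(name)
  if (name == "FRD") name <- "FRIEDMAN"
  name <- match.arg(name, c("KAS", "FWO", "STARINK", "FRIEDMAN"))
  def <- switch(name,
    KAS = list(
      ordinate = function(beta, T, rate = NULL) log(beta / T^2),
      slope_to_Ea = function(slope) -slope * R_GAS),
    FWO = list(
      ordinate = function(beta, T, rate = NULL) log(beta) + 0 * T,
      slope_to_Ea = function(slope) -slope * R_GAS / 1.052),
    STARINK = list(
      ordinate = function(beta, T, rate = NULL) log(beta / T^1.92),
      slope_to_Ea = function(slope) -slope * R_GAS / 1.0037),
    FRIEDMAN = list(
      ordinate = function(beta, T, rate) log(beta * rate),
      slope_to_Ea = function(slope) -slope * R_GAS))
  structure(c(list(name = name), def), class = "iso_method")
}

#' Fit an activation-energy profile by an isoconversional method
#'
#' For every conversion level in the table, regresses the method's ordinate
#' on 1/T across heating rates by unweighted ordinary least squares, and
#' converts the slope to an activation energy. Cells that are `NA` (outside
#' a curve's span) are dropped per conversion; a level with fewer than 3
#' usable points is skipped with a warning.
#'
#' @param method an [iso_method()] or its name.
#' @param table an `iso_table` of temperatures from
#'   [temperatures_at_conversions()].
#' @param rates an `iso_table` of rates from [rates_at_conversions()];
#'   required by Friedman, ignored otherwise.
#' @return an object of class `ea_profile`: `method`, data frame `fits`
#'   with columns `alpha`, `slope`, `intercept`, `Ea` (J/mol), `r2`,
#'   `n_points`, and `mean_Ea` (J/mol).
#' @export
fit_isoconversional <- function(method, table, rates = NULL) {
  if (is.character(method)) method <- iso_method(method)
  stopifnot(inherits(method, "iso_method"), inherits(table, "iso_table"))
  betas <- table$betas
  if (length(unique(betas)) < 3L) {
    stop("need at least 3 distinct heating rates", call. = FALSE)
  }
  if (length(unique(betas)) == 1L) {
    stop("all heating rates identical: singular design", call. = FALSE)
  }
  if (method$name == "FRIEDMAN") {
    if (is.null(rates) || !inherits(rates, "iso_table")) {
      stop("Friedman requires the rate table", call. = FALSE)
    }
    stopifnot(identical(rates$alpha_grid, table$alpha_grid))
  }
  rows <- vector("list", length(table$alpha_grid))
  n_skipped <- 0L
  for (i in seq_along(table$alpha_grid)) {
    Tv <- table$T[i, ]
    rv <- if (method$name == "FRIEDMAN") rates$T[i, ] else rep(NA_real_,
                                                               length(Tv))
    ok <- is.finite(Tv) & (method$name != "FRIEDMAN" | (is.finite(rv) & rv > 0))
    if (sum(ok) < 3L) {
      n_skipped <- n_skipped + 1L
      next
    }
    y <- method$ordinate(betas[ok], Tv[ok], rv[ok])
    fit <- .ols(1 / Tv[ok], y)
    rows[[i]] <- data.frame(
      alpha = table$alpha_grid[i], slope = fit$slope,
      intercept = fit$intercept, Ea = method$slope_to_Ea(fit$slope),
      r2 = fit$r2, n_points = sum(ok))
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d conversion level(s) skipped (< 3 usable points)",
                    n_skipped), call. = FALSE)
  }
  fits <- do.call(rbind, rows)
  if (is.null(fits) || nrow(fits) == 0L) {
    stop("no conversion level had enough points to fit", call. = FALSE)
  }
  ea_profile(method$name, fits$alpha, fits$Ea,
             slope = fits$slope, intercept = fits$intercept,
             r2 = fits$r2, n_points = fits$n_points)
}

# simple linear regression, closed form
.ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) stop("singular design: identical abscissae", call. = FALSE)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - yb)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r2 = max(0, min(1, r2)))
}

#' Construct an activation-energy profile
#'
#' Bundles per-conversion activation energies (with optional regression
#' diagnostics) for one isoconversional method. Use this directly to wrap
#' published per-conversion values for summarising.
#'
#' @param method method name.
#' @param alpha conversion levels.
#' @param Ea activation energies, J mol^-1.
#' @param slope,intercept,r2,n_points optional per-fit diagnostics.
#' @return an `ea_profile`.
#' @export
ea_profile <- function(method, alpha, Ea, slope = NA_real_,
                       intercept = NA_real_, r2 = NA_real_,
                       n_points = NA_integer_) {
  stopifnot(length(alpha) == length(Ea))
  fits <- data.frame(alpha = alpha, slope = slope, intercept = intercept,
                     Ea = Ea, r2 = r2, n_points = n_points)
  structure(list(method = toupper(method), fits = fits, mean_Ea = mean(Ea)),
            class = "ea_profile")
}

#' @export
print.ea_profile <- function(x, ...) {
  cat(sprintf("<ea_profile> %s: %d conversions, mean Ea = %.3f kJ/mol\n",
              x$method, nrow(x$fits), x$mean_Ea / 1000))
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' Summarise an activation-energy profile
#'
#' Reports the arithmetic mean over the fitted conversion levels together
#' with the range, mirroring the "overall model average" convention of
#' model-free kinetic studies. Also accepts a bare numeric vector (e.g. a
#' published per-conversion column).
#'
#' @param profile an `ea_profile`, or a numeric vector of per-conversion
#'   values.
#' @return a list with `mean`, `min`, `max` (same units as the input) and,
#'   for profiles, the per-conversion `table`.
#' @export
summarize_profile <- function(profile) {
  if (is.numeric(profile)) {
    if (length(profile) == 0L) stop("empty profile", call. = FALSE)
    return(list(mean = mean(profile), min = min(profile),
                max = max(profile)))
  }
  stopifnot(inherits(profile, "ea_profile"))
  if (nrow(profile$fits) == 0L) stop("empty profile", call. = FALSE)
  list(mean = profile$mean_Ea, min = min(profile$fits$Ea),
       max = max(profile$fits$Ea), table = profile$fits)
}

#' Write isoconversional results to CSV
#'
#' Columns: `method,alpha,Ea_kJ_mol,A_per_min,r2,n_points`. `A_per_min` is
#' filled when a per-conversion frequency-factor vector is supplied.
#'
#' @param profiles list of `ea_profile` objects.
#' @param path output file.
#' @param A optional list (parallel to `profiles`) of per-conversion A
#'   values, min^-1.
#' @export
write_ea_profiles <- function(profiles, path, A = NULL) {
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(method = p$method, alpha = p$fits$alpha,
               Ea_kJ_mol = p$fits$Ea / 1000,
               A_per_min = if (is.null(A)) NA_real_ else A[[i]],
               r2 = p$fits$r2, n_points = p$fits$n_points)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
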