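#' Compute the conversion curve of a thermogram
#'
#' Applies the conversion definition alpha = (w0 - wt) / (w0 - wf) over the
#' analysis window, then
#' * enforces a non-decreasing alpha by isotonic clipping (running maximum)
#'   of noise-induced inversions, with the largest clipped magnitude recorded
#'   in the `clip` attribute, and
#' * estimates the rate d(alpha)/dT by local-polynomial (order-2
#'   Savitzky-Golay) smoothed differentiation.
#'
#' @param tg a `thermogram`.
#' @param w0,wf reference masses, mg. `NULL` (default) takes the mass at the
#'   window start / end.
#' @param window optional `c(T_lo, T_hi)` temperature bounds, K; `NULL` uses
#'   the full record.
#' @param smooth_window odd Savitzky-Golay window length in points
#'   (default 11); `0` or `1` disables smoothing and uses plain central
#'   differences.
#' @return a `conversion_curve` restricted to the window.
#' @export
compute_conversion <- function(tg, w0 = NULL, wf = NULL, window = NULL,
                               smooth_window = 11L) {
  stopifnot(inherits(tg, "thermogram"))
  Tv <- tg$temperature
  m <- tg$mass
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    if (window[1] < min(Tv) || window[2] > max(Tv)) {
      stop("window outside the data's temperature range", call. = FALSE)
    }
    keep <- Tv >= window[1] & Tv <= window[2]
    Tv <- Tv[keep]
    m <- m[keep]
  }
  if (is.null(w0)) w0 <- m[1]
  if (is.null(wf)) wf <- m[length(m)]
  if (w0 <= wf) stop("require w0 > wf", call. = FALSE)
  alpha <- (w0 - m) / (w0 - wf)
  alpha <- pmin(pmax(alpha, 0), 1)
  mono <- cummax(alpha)
  clip <- max(mono - alpha)
  alpha <- mono
  rate <- .sg_derivative(Tv, alpha, smooth_window)
  out <- new_conversion_curve(Tv, alpha, rate, tg$beta)
  attr(out, "clip") <- clip
  out
}

# Savitzky-Golay order-2 first derivative on an (approximately) uniform grid
.sg_derivative <- function(Tv, y, window) {
  h <- mean(diff(Tv))
  if (diff(range(diff(Tv))) > 0.05 * h) {
    warning("temperature grid is not uniform; derivative uses the mean step",
            call. = FALSE)
  }
  window <- as.integer(window)
  if (window <= 1L) {
    return(c(diff(y[1:2]) / diff(Tv[1:2]),
             (y[-(1:2)] - y[seq_len(length(y) - 2)]) /
               (Tv[-(1:2)] - Tv[seq_len(length(Tv) - 2)]),
             diff(y[(length(y) - 1):length(y)]) / h))
  }
  if (window %% 2L == 0L) stop("smooth_window must be odd", call. = FALSE)
  if (window > length(y)) stop("smooth_window exceeds data length",
                               call. = FALSE)
  as.numeric(signal::sgolayfilt(y, p = 2, n = window, m = 1, ts = h))
}

#' Locate the DTG peak of a conversion curve
#'
#' The peak temperature Tp is the temperature of the global maximum of
#' d(alpha)/dT; ties are broken towards the lowest temperature. A maximum
#' sitting on the first or last sample indicates there is no interior peak
#' and raises an error.
#'
#' @param curve a `conversion_curve` with its rate present.
#' @return an object of class `peak_info`: `Tp` (K), `peak_rate` (K^-1),
#'   `beta` (K min^-1).
#' @export
find_peak <- function(curve) {
  stopifnot(inherits(curve, "conversion_curve"))
  r <- curve$rate
  if (is.null(r) || all(!is.finite(r))) stop("rate missing", call. = FALSE)
  i <- which.max(r)  # which.max takes the first (lowest-T) maximum
  if (i == 1L || i == length(r)) {
    stop("rate maximum lies on the window boundary; no interior DTG peak",
         call. = FALSE)
  }
  structure(list(Tp = curve$temperature[i], peak_rate = r[i],
                 beta = curve$beta),
            class = "peak_info")
}

#' @export
print.peak_info <- function(x, ...) {
  cat(sprintf("<peak_info> Tp = %.2f K at beta = %g K/min (rate %.3g /K)\n",
              x$Tp, x$beta, x$peak_rate))
  invisible(x)
}

#' Iso-conversional temperature table
#'
#' Interpolates, for each requested conversion level, the temperature at
#' which each heating-rate run reaches it, using shape-preserving monotone
#' piecewise-cubic interpolation of the (alpha, T) relation. Conversions
#' outside a curve's span yield `NA` cells with a warning.
#'
#' @param curves list of `conversion_curve` objects at >= 3 distinct heating
#'   rates.
#' @param alpha_grid ascending conversions in (0, 1); default 0.10 to 0.80
#'   by 0.05.
#' @return an object of class `iso_table`: `alpha_grid`, matrix `T`
#'   (rows = alpha, columns = heating rates, K) and `betas`.
#' @export
temperatures_at_conversions <- function(curves,
                                        alpha_grid = seq(0.10, 0.80, 0.05)) {
  .iso_interp(curves, alpha_grid, what = "temperature")
}

#' Iso-conversional rate table
#'
#' As [temperatures_at_conversions()], but linearly interpolating the rate
#' d(alpha)/dT at each conversion level; needed by the Friedman method.
#'
#' @inheritParams temperatures_at_conversions
#' @return an `iso_table` whose matrix (named `T` for structural
#'   compatibility) holds d(alpha)/dT values in K^-1.
#' @export
rates_at_conversions <- function(curves,
                                 alpha_grid = seq(0.10, 0.80, 0.05)) {
  .iso_interp(curves, alpha_grid, what = "rate")
}

.iso_interp <- function(curves, alpha_grid, what = c("temperature", "rate")) {
  what <- match.arg(what)
  stopifnot(is.list(curves),
            all(vapply(curves, inherits, TRUE, "conversion_curve")))
  betas <- vapply(curves, `[[`, numeric(1), "beta")
  if (length(unique(betas)) < 3L) {
    stop("need at least 3 distinct heating rates", call. = FALSE)
  }
  stopifnot(is.numeric(alpha_grid), all(diff(alpha_grid) > 0),
            all(alpha_grid > 0), all(alpha_grid < 1))
  M <- matrix(NA_real_, nrow = length(alpha_grid), ncol = length(curves),
              dimnames = list(format(alpha_grid), format(betas)))
  n_missing <- 0L
  for (j in seq_along(curves)) {
    cv <- curves[[j]]
    inc <- c(TRUE, diff(cv$alpha) > 0)  # strictly increasing support
    a <- cv$alpha[inc]
    span <- alpha_grid >= min(a) & alpha_grid <= max(a)
    n_missing <- n_missing + sum(!span)
    if (!any(span)) next
    if (what == "temperature") {
      fun <- stats::splinefun(a, cv$temperature[inc], method = "monoH.FC")
      M[span, j] <- fun(alpha_grid[span])
    } else {
      M[span, j] <- stats::approx(a, cv$rate[inc],
                                  xout = alpha_grid[span])$y
    }
  }
  if (n_missing > 0L) {
    warning(sprintf("%d conversion cell(s) outside curve span set to NA",
                    n_missing), call. = FALSE)
  }
  structure(list(alpha_grid = alpha_grid, T = M, betas = betas),
            class = "iso_table")
}

#' @export
print.iso_table <- function(x, ...) {
  cat(sprintf("<iso_table> %d conversions x %d heating rates (beta: %s)\n",
              length(x$alpha_grid), length(x$betas),
              paste(x$betas, collapse = ", ")))
  print(utils::head(x$T))
  invisible(x)
}

#' Detect the main decomposition stage of a thermogram
#'
#' Returns the temperature bounds of the contiguous region around the DTG
#' maximum where the smoothed mass-loss rate exceeds `frac` of its maximum.
#' Useful as an analysis window so that slow tails do not dominate the
#' w0/wf normalisation.
#'
#' @param tg a `thermogram`.
#' @param frac threshold as a fraction of the peak rate (default 0.05).
#' @param smooth_window passed to the derivative smoother.
#' @return `c(T_lo, T_hi)` in K.
#' @export
main_stage_window <- function(tg, frac = 0.05, smooth_window = 11L) {
  stopifnot(inherits(tg, "thermogram"))
  dm <- -.sg_derivative(tg$temperature, tg$mass, smooth_window)
  i_pk <- which.max(dm)
  thr <- frac * dm[i_pk]
  lo <- i_pk
  while (lo > 1L && dm[lo - 1L] > thr) lo <- lo - 1L
  hi <- i_pk
  while (hi < length(dm) && dm[hi + 1L] > thr) hi <- hi + 1L
  c(tg$temperature[lo], tg$temperature[hi])
}

#' Read and write thermogram CSV files
#'
#' The on-disk dialect is a headered CSV with columns
#' `time_min,temperature_K,mass_mg` (one file per heating rate). The reader
#' tolerates Celsius input via `units = "C"`, converting to kelvin
#' internally (the column may then be named `temperature_C`).
#'
#' @param path file path.
#' @param beta heating rate of the run, K min^-1 (stored, not inferred).
#' @param units `"K"` (default) or `"C"` for the temperature column.
#' @param label sample label for the metadata.
#' @return `read_thermogram()` returns a `thermogram`;
#'   `write_thermogram()` invisibly returns `path`.
#' @export
read_thermogram <- function(path, beta, units = c("K", "C"),
                            label = basename(path)) {
  units <- match.arg(units)
  df <- utils::read.csv(path, check.names = FALSE)
  tcol <- intersect(c("temperature_K", "temperature_C", "temperature"),
                    names(df))[1]
  if (is.na(tcol) || !all(c("time_min", "mass_mg") %in% names(df))) {
    stop("expected columns time_min, temperature_K (or _C), mass_mg",
         call. = FALSE)
  }
  Tv <- df[[tcol]]
  if (units == "C") Tv <- Tv + 273.15
  new_thermogram(df$time_min, Tv, df$mass_mg, beta,
                 meta = list(label = label))
}

#' @rdname read_thermogram
#' @param tg a `thermogram` to write.
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  utils::write.csv(
    data.frame(time_min = tg$time, temperature_K = tg$temperature,
               mass_mg = tg$mass),
    path, row.names = FALSE)
  invisible(path)
}
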