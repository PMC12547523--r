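test_that("conversion arithmetic follows (w0 - wt)/(w0 - wf)", {
  Tv <- seq(400, 600, length.out = 51)
  mass <- seq(10, 2, length.out = 51)
  tg <- thermokin:::new_thermogram((Tv - 400) / 10, Tv, mass, beta = 10)
  cv <- compute_conversion(tg, w0 = 10, wf = 2, smooth_window = 0)
  expect_equal(cv$alpha[1], 0)
  expect_equal(cv$alpha[51], 1)
  expect_equal(cv$alpha[match(6, mass)], 0.5)   # wt = 6 between 10 and 2
  expect_error(compute_conversion(tg, w0 = 2, wf = 10), "w0 > wf")
  expect_error(compute_conversion(tg, window = c(100, 700)), "window")
})

test_that("noiseless processing recovers the generating conversion to 1e-10", {
  for (i in c(1L, 4L)) {
    cv0 <- sim_curves()[[i]]
    got <- processed_curves()[[i]]
    expect_lt(max(abs(got$alpha - cv0$alpha)), 1e-10)
  }
})

test_that("isotonic clipping repairs noise inversions and logs magnitude", {
  cv <- noisy_processed_curves()[[1]]
  expect_true(all(diff(cv$alpha) >= 0))
  expect_true(all(cv$alpha >= 0 & cv$alpha <= 1))
  expect_gt(attr(cv, "clip"), 0)
})

test_that("find_peak locates the DTG maximum", {
  # analytic oracle for the default scenario
  pk <- find_peak(processed_curves()[[1]])
  Tp_oracle <- predict_peak_temperature(default_triplet(), beta = 10)
  expect_lt(abs(pk$Tp - Tp_oracle), 0.5)

  # symmetric triangular rate: apex returned
  Tv <- seq(500, 600, 1)
  rate <- 1 - abs(Tv - 550) / 50
  tri <- thermokin:::new_conversion_curve(Tv, cumsum(rate) / sum(rate),
                                          rate, 10)
  expect_equal(find_peak(tri)$Tp, 550)

  # peak temperature increases with heating rate
  Tps <- vapply(processed_curves(), function(cv) find_peak(cv)$Tp,
                numeric(1))
  expect_true(all(diff(Tps) > 0))

  # boundary maximum is an error
  mono <- thermokin:::new_conversion_curve(Tv, seq(0, 1, length.out = 101),
                                           seq_len(101) / 101, 10)
  expect_error(find_peak(mono), "boundary")
})

test_that("smoothing does not shift the noiseless peak by more than one step", {
  tg <- sim_thermograms()[[1]]
  raw <- compute_conversion(tg, smooth_window = 0)
  smo <- compute_conversion(tg, smooth_window = 11)
  expect_lte(abs(find_peak(raw)$Tp - find_peak(smo)$Tp),
             mean(diff(tg$temperature)) + 1e-9)
})

test_that("iso-conversional temperatures match a dense-grid inversion", {
  grid <- seq(0.1, 0.8, 0.05)
  tab <- temperatures_at_conversions(processed_curves(), grid)
  expect_equal(dim(tab$T), c(length(grid), 4L))
  expect_identical(tab$betas, default_betas)
  # each column strictly increasing in alpha, rows increasing in beta
  expect_true(all(apply(tab$T, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(tab$T, 1, function(row) all(diff(row) > 0))))

  tr <- default_triplet()
  for (j in 1:4) {
    fine <- suppressWarnings(simulate_conversion(
      tr, heating_program(default_betas[j], 450, 800, step = 0.02)))
    inc <- c(TRUE, diff(fine$alpha) > 0)
    T_oracle <- stats::approx(fine$alpha[inc], fine$temperature[inc],
                              xout = grid)$y
    expect_lt(max(abs(tab$T[, j] - T_oracle)), 0.05)
  }
})

test_that("exact grid points are returned unchanged by interpolation", {
  cv <- processed_curves()[[1]]
  i <- which.min(abs(cv$alpha - 0.4))
  a_exact <- cv$alpha[i]
  tab <- temperatures_at_conversions(processed_curves(),
                                     c(0.2, a_exact, 0.8))
  expect_equal(tab$T[2, 1], cv$temperature[i], tolerance = 1e-12)
})

test_that("out-of-span conversions give NA cells with a warning", {
  curves <- processed_curves()
  # truncate the first curve below alpha = 0.4
  cv <- curves[[1]]
  keep <- cv$alpha < 0.4
  curves[[1]] <- thermokin:::new_conversion_curve(
    cv$temperature[keep], cv$alpha[keep], cv$rate[keep], cv$beta)
  expect_warning(tab <- temperatures_at_conversions(curves, c(0.2, 0.5)),
                 "outside")
  expect_true(is.na(tab$T[2, 1]))
  expect_false(anyNA(tab$T[, 2:4]))
  expect_error(temperatures_at_conversions(curves[1:2]), "3 distinct")
})

test_that("interpolated rates track the analytic rate law", {
  # noiseless data: raw central differences, no smoothing bias
  grid <- seq(0.1, 0.8, 0.05)
  raw <- lapply(sim_thermograms(), compute_conversion, smooth_window = 0)
  rts <- rates_at_conversions(raw, grid)
  tab <- temperatures_at_conversions(raw, grid)
  tr <- default_triplet()
  rhs <- (tr$A / rep(default_betas, each = length(grid))) *
    (1 - grid) * exp(-tr$Ea / (8.314462618 * tab$T))
  expect_lt(max(abs(rts$T / rhs - 1)), 0.001)
})

test_that("linear interpolation of rates is exact on locally linear data", {
  Tv <- seq(500, 600, 1)
  alpha <- seq(0.05, 0.95, length.out = 101)
  rate <- 0.001 + 0.00002 * (alpha - 0.5)   # linear in alpha
  mk <- function(b) thermokin:::new_conversion_curve(Tv, alpha, rate, b)
  rts <- rates_at_conversions(list(mk(10), mk(20), mk(30)),
                              c(0.3125, 0.5, 0.71))
  expected <- 0.001 + 0.00002 * (c(0.3125, 0.5, 0.71) - 0.5)
  for (j in 1:3) expect_equal(rts$T[, j], expected, tolerance = 1e-12,
                              ignore_attr = TRUE)
})

test_that("noisy rates stay within 5% at mid-conversions after smoothing", {
  grid <- seq(0.3, 0.7, 0.05)
  curves <- noisy_processed_curves(sd = 0.002, smooth_window = 15L)
  rts <- rates_at_conversions(curves, grid)
  tab <- temperatures_at_conversions(curves, grid)
  tr <- default_triplet()
  rhs <- (tr$A / rep(default_betas, each = length(grid))) *
    (1 - grid) * exp(-tr$Ea / (8.314462618 * tab$T))
  expect_lt(max(abs(rts$T / rhs - 1)), 0.05)
})

test_that("main decomposition stage bounds bracket the DTG peak", {
  tg <- sim_thermograms()[[1]]
  win <- main_stage_window(tg)
  Tp <- predict_peak_temperature(default_triplet(), 10)
  expect_lt(win[1], Tp)
  expect_gt(win[2], Tp)
  expect_gt(win[1], 450)
})

test_that("thermogram CSV round-trips, including Celsius input", {
  tg <- sim_thermograms()[[2]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermogram(tg, path)
  back <- read_thermogram(path, beta = 20)
  expect_equal(back$temperature, tg$temperature)
  expect_equal(back$mass, tg$mass)

  # Celsius dialect
  df <- utils::read.csv(path)
  df$temperature_K <- df$temperature_K - 273.15
  names(df)[names(df) == "temperature_K"] <- "temperature_C"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  back2 <- read_thermogram(path2, beta = 20, units = "C")
  expect_equal(back2$temperature, tg$temperature, tolerance = 1e-10)
})
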