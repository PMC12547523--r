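make_iso_table <- function(T, betas, alpha_grid) {
  structure(list(alpha_grid = alpha_grid,
                 T = matrix(T, nrow = length(alpha_grid),
                            byrow = TRUE),
                 betas = betas),
            class = "iso_table")
}

test_that("exactly collinear KAS data return the generating Ea and r2 = 1", {
  R <- 8.314462618
  Ea <- 100e3
  betas <- c(10, 20, 30, 40)
  Tv <- seq(550, 610, 20)
  # construct betas so that ln(beta/T^2) = c - (Ea/R)(1/T) exactly
  c0 <- -5
  betas_exact <- exp(c0 - (Ea / R) / Tv) * Tv^2
  tab <- make_iso_table(Tv, betas_exact, 0.5)
  p <- fit_isoconversional("KAS", tab)
  expect_equal(p$fits$Ea, Ea, tolerance = 1e-12)
  expect_equal(p$fits$r2, 1, tolerance = 1e-12)
  expect_equal(p$fits$intercept, c0, tolerance = 1e-10)
})

test_that("per-conversion fits equal the closed-form regression oracle", {
  tab <- temperatures_at_conversions(processed_curves())
  rts <- rates_at_conversions(processed_curves())
  for (m in c("KAS", "FWO", "STARINK", "FRIEDMAN")) {
    meth <- iso_method(m)
    p <- fit_isoconversional(meth, tab, rates = rts)
    for (i in seq_along(tab$alpha_grid)) {
      y <- meth$ordinate(tab$betas, tab$T[i, ], rts$T[i, ])
      o <- oracle_ols(1 / tab$T[i, ], y)
      expect_equal(p$fits$slope[i], o$slope, tolerance = 1e-10)
      expect_equal(p$fits$intercept[i], o$intercept, tolerance = 1e-10)
      expect_equal(p$fits$Ea[i], meth$slope_to_Ea(o$slope),
                   tolerance = 1e-10)
      expect_equal(p$fits$r2[i], o$r2, tolerance = 1e-10)
    }
  }
})

test_that("the four methods recover the simulation truth within method bias", {
  tab <- temperatures_at_conversions(processed_curves())
  rts <- rates_at_conversions(processed_curves())
  rel_err <- function(m) {
    abs(fit_isoconversional(m, tab, rates = rts)$mean_Ea / 105e3 - 1)
  }
  expect_lt(rel_err("FRIEDMAN"), 0.01)
  expect_lt(rel_err("KAS"), 0.02)
  expect_lt(rel_err("STARINK"), 0.02)
  # FWO carries the Doyle-approximation bias, ~3.5% at Ea/RT ~ 20-24
  expect_lt(rel_err("FWO"), 0.04)

  # method agreement on noiseless single-step data
  means <- vapply(c("KAS", "FWO", "STARINK", "FRIEDMAN"), function(m) {
    fit_isoconversional(m, tab, rates = rts)$mean_Ea
  }, numeric(1))
  expect_lt(diff(range(means)) / mean(means), 0.04)
})

test_that("KAS and Starink are near-identical on any input", {
  tab <- temperatures_at_conversions(processed_curves())
  kas <- fit_isoconversional("KAS", tab)
  sta <- fit_isoconversional("STARINK", tab)
  expect_lt(max(abs(kas$fits$Ea / sta$fits$Ea - 1)), 0.005)
})

test_that("Ea is invariant to rescaling all masses", {
  tgs <- sim_thermograms()
  scaled <- lapply(tgs, function(tg) {
    tg$mass <- tg$mass * 3.7
    tg$meta$w0 <- NULL
    tg
  })
  cv1 <- lapply(tgs, compute_conversion)
  cv2 <- lapply(scaled, compute_conversion)
  p1 <- fit_isoconversional("KAS", temperatures_at_conversions(cv1))
  p2 <- fit_isoconversional("KAS", temperatures_at_conversions(cv2))
  expect_equal(p1$fits$Ea, p2$fits$Ea, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  tab2 <- make_iso_table(c(550, 560, 555, 565), c(10, 20), c(0.3, 0.5))
  expect_error(fit_isoconversional("KAS", tab2), "3 distinct")
  expect_error(fit_isoconversional("FRIEDMAN",
                                   temperatures_at_conversions(
                                     processed_curves())),
               "rate")
})

test_that("conversion levels with too few usable points are skipped", {
  tab <- temperatures_at_conversions(processed_curves(), seq(0.2, 0.6, 0.2))
  tab$T[1, c(1, 2)] <- NA
  expect_warning(p <- fit_isoconversional("KAS", tab), "skipped")
  expect_equal(nrow(p$fits), 2L)
  expect_equal(p$fits$alpha, c(0.4, 0.6))
})

test_that("profile summaries reproduce published per-conversion averages", {
  t1 <- utils::read.csv(table1_path())
  expected <- c(KAS = 101.468, FWO = 105.809, FRIEDMAN = 111.147,
                STARINK = 101.486)
  for (m in names(expected)) {
    col <- t1$Ea_kJ_mol[t1$method == m]
    expect_equal(summarize_profile(col)$mean, expected[[m]],
                 tolerance = 5e-4)
    p <- ea_profile(m, t1$alpha[t1$method == m], col * 1000)
    s <- summarize_profile(p)
    expect_equal(s$mean / 1000, expected[[m]], tolerance = 5e-4)
    expect_equal(s$min, min(col) * 1000)
    expect_equal(s$max, max(col) * 1000)
  }
  # single fit: the mean is that value
  expect_equal(summarize_profile(ea_profile("KAS", 0.5, 99e3))$mean, 99e3)
  expect_error(summarize_profile(numeric(0)), "empty")
})

test_that("results writer emits the documented CSV dialect", {
  tab <- temperatures_at_conversions(processed_curves())
  p <- fit_isoconversional("KAS", tab)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ea_profiles(list(p), path)
  out <- utils::read.csv(path)
  expect_named(out, c("method", "alpha", "Ea_kJ_mol", "A_per_min", "r2",
                      "n_points"))
  expect_equal(out$Ea_kJ_mol, p$fits$Ea / 1000)
})
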