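# Shared fixtures, memoized: simulation is cheap but not free, and several
# files probe the same default scenario (F1, Ea = 105 kJ/mol, A = 1e9 /min,
# beta in {10, 20, 30, 40} K/min over 450-800 K).

.fixtures <- new.env(parent = emptyenv())

default_triplet <- function() kinetic_triplet(Ea = 105e3, A = 1e9, model = "F1")

default_betas <- c(10, 20, 30, 40)

sim_curves <- function() {
  if (is.null(.fixtures$curves)) {
    tr <- default_triplet()
    .fixtures$curves <- lapply(default_betas, function(b) {
      suppressWarnings(
        simulate_conversion(tr, heating_program(b, 450, 800, 0.5)))
    })
  }
  .fixtures$curves
}

sim_thermograms <- function() {
  if (is.null(.fixtures$tgs)) {
    .fixtures$tgs <- lapply(sim_curves(), conversion_to_thermogram,
                            w0 = 10, wf = 1)
  }
  .fixtures$tgs
}

processed_curves <- function() {
  if (is.null(.fixtures$proc)) {
    .fixtures$proc <- lapply(sim_thermograms(), compute_conversion)
  }
  .fixtures$proc
}

noisy_processed_curves <- function(sd = 0.002, smooth_window = 15L) {
  key <- sprintf("noisy_%g_%d", sd, smooth_window)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- lapply(seq_along(sim_thermograms()), function(i) {
      tg <- add_noise(sim_thermograms()[[i]], noise_spec(sd, seed = 100 + i))
      compute_conversion(tg, smooth_window = smooth_window)
    })
  }
  .fixtures[[key]]
}

# closed-form simple linear regression, kept deliberately separate from the
# package's fitting path
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# fixed-step classical RK4 integration of the first-order rate law,
# independent of the deSolve-based path
rk4_alpha_f1 <- function(Ea, A, beta, T0, T1, h = 0.01, probes) {
  R <- 8.314462618
  rhs <- function(T, a) (A / beta) * max(1 - a, 0) * exp(-Ea / (R * T))
  n <- ceiling((T1 - T0) / h)
  a <- 0
  out <- numeric(length(probes))
  j <- 1L
  Tcur <- T0
  for (i in seq_len(n)) {
    while (j <= length(probes) && probes[j] <= Tcur + 1e-9) {
      out[j] <- a
      j <- j + 1L
    }
    k1 <- rhs(Tcur, a)
    k2 <- rhs(Tcur + h / 2, a + h * k1 / 2)
    k3 <- rhs(Tcur + h / 2, a + h * k2 / 2)
    k4 <- rhs(Tcur + h, a + h * k3)
    a <- min(a + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6, 1)
    Tcur <- Tcur + h
  }
  while (j <= length(probes)) {
    out[j] <- a
    j <- j + 1L
  }
  out
}

table1_path <- function() {
  system.file("extdata", "metformin_isoconversional.csv",
              package = "thermokin")
}

table2_weighings <- function(liquid_g = 4.66, char_g = 0.36) {
  # one apparatus weighing pattern realising the published product masses
  data.frame(
    component = c("condenser", "elbow_joint", "adopter_joint", "flask",
                  "round_bottom_flask"),
    before_g = c(250.00, 48.20, 36.50, 95.00, 310.00),
    after_g = c(250.00 + 0.6 * liquid_g, 48.20 + 0.2 * liquid_g,
                36.50 + 0.1 * liquid_g, 95.00 + 0.1 * liquid_g,
                310.00 + char_g))
}
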