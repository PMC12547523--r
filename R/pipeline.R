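#' Build and validate a pipeline configuration
#'
#' A configuration drives [run_pipeline()] end to end. Inputs are either a
#' synthetic scenario (kinetic triplet + heating programs, simulated
#' in-package) or a list of thermogram CSV files with their heating rates.
#' The validated configuration is serialised into the output directory so
#' a run is fully reconstructible from it plus the seed.
#'
#' @param scenario synthetic scenario: list with `Ea` (J/mol), `A` (min^-1),
#'   `model`, `w0`, `wf` (mg), `T_start`, `T_end`, `step` (K), `betas`
#'   (K/min), and optional `mass_noise_sd`, `drift`. Mutually exclusive
#'   with `files`.
#' @param files list of `list(path =, beta =)` thermogram CSVs.
#' @param units temperature units of input files, `"K"` or `"C"`.
#' @param alpha_grid conversion levels for the isoconversional analysis.
#' @param methods isoconversional methods to fit.
#' @param smooth_window Savitzky-Golay window (odd, points).
#' @param Tm policy for the entropy reference temperature
#'   (`"lowest_beta_peak"` or a number, K).
#' @param ann `NULL` to skip the surrogate, or a list with `n_points` per
#'   curve and any [ann_spec()] arguments.
#' @param yields `NULL`, or a list with `weighings` (data frame or CSV
#'   path) and `W_feed` (g).
#' @param out_dir output directory for tables and the manifest; `NULL`
#'   keeps everything in memory.
#' @param seed integer seed for every stochastic element.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, files = NULL,
                            units = c("K", "C"),
                            alpha_grid = seq(0.10, 0.80, 0.05),
                            methods = c("KAS", "FWO", "STARINK", "FRIEDMAN"),
                            smooth_window = 11L,
                            Tm = "lowest_beta_peak",
                            ann = NULL, yields = NULL,
                            out_dir = NULL, seed = 1L) {
  units <- match.arg(units)
  if (is.null(scenario) == is.null(files)) {
    stop("supply exactly one of `scenario` or `files`", call. = FALSE)
  }
  if (!is.null(scenario)) {
    need <- c("Ea", "A", "w0", "wf", "T_start", "T_end", "betas")
    miss <- setdiff(need, names(scenario))
    if (length(miss)) {
      stop("scenario missing fields: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    scenario$model <- if (is.null(scenario$model)) "F1" else scenario$model
    scenario$step <- if (is.null(scenario$step)) 0.5 else scenario$step
    scenario$mass_noise_sd <- if (is.null(scenario$mass_noise_sd)) 0 else
      scenario$mass_noise_sd
    scenario$drift <- if (is.null(scenario$drift)) 0 else scenario$drift
  }
  methods <- vapply(methods, function(m) iso_method(m)$name, character(1))
  structure(list(scenario = scenario, files = files, units = units,
                 alpha_grid = alpha_grid, methods = unname(methods),
                 smooth_window = as.integer(smooth_window), Tm = Tm,
                 ann = ann, yields = yields, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full kinetic-analysis pipeline
#'
#' Stages: acquire thermograms (simulate or read), convert to conversion /
#' DTG curves, locate peaks, build the iso-conversional temperature and
#' rate tables, fit the requested activation-energy profiles, run the
#' Kissinger regression and per-conversion thermodynamics, and optionally
#' the product-yield balance and the ANN surrogate. Deterministic given the
#' configuration and seed. If `out_dir` is set, every table is written as
#' CSV together with the serialised configuration and an input manifest
#' (MD5 hashes); on a stage failure the outputs written so far are kept
#' next to a `FAILED` marker naming the stage.
#'
#' @param config a `pipeline_config`.
#' @return a result bundle: `thermograms`, `curves`, `peaks`, `iso_T`,
#'   `iso_rate`, `profiles`, `kissinger`, `thermo`, `yields`, `ann`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(log = character())
  note <- function(...) {
    out$log <<- c(out$log, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$out_dir)) {
        writeLines(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   file.path(config$out_dir, "FAILED"))
      }
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- config
    cfg$yields$weighings <- NULL  # data frames do not serialise to YAML well
    yaml::write_yaml(unclass(cfg), file.path(config$out_dir, "config.yaml"))
  }

  out$thermograms <- stage("input", {
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      triplet <- kinetic_triplet(sc$Ea, sc$A, sc$model)
      lapply(seq_along(sc$betas), function(i) {
        pr <- heating_program(sc$betas[i], sc$T_start, sc$T_end, sc$step)
        tg <- conversion_to_thermogram(simulate_conversion(triplet, pr),
                                       w0 = sc$w0, wf = sc$wf)
        add_noise(tg, noise_spec(sc$mass_noise_sd, sc$drift,
                                 seed = config$seed + i))
      })
    } else {
      lapply(config$files, function(f) {
        read_thermogram(f$path, beta = f$beta, units = config$units)
      })
    }
  })
  note("input: %d thermograms", length(out$thermograms))

  out$curves <- stage("conversion", lapply(out$thermograms, function(tg) {
    compute_conversion(tg, smooth_window = config$smooth_window)
  }))
  out$peaks <- stage("peaks", lapply(out$curves, find_peak))
  note("peaks at %s K",
       paste(sprintf("%.1f", vapply(out$peaks, `[[`, numeric(1), "Tp")),
             collapse = ", "))

  out$iso_T <- stage("iso_table",
                     temperatures_at_conversions(out$curves,
                                                 config$alpha_grid))
  out$iso_rate <- stage("iso_table",
                        rates_at_conversions(out$curves, config$alpha_grid))

  out$profiles <- stage("isoconversional", {
    ps <- lapply(config$methods, function(m) {
      fit_isoconversional(m, out$iso_T, rates = out$iso_rate)
    })
    names(ps) <- config$methods
    ps
  })
  note("mean Ea (kJ/mol): %s",
       paste(sprintf("%s %.1f", names(out$profiles),
                     vapply(out$profiles, `[[`, numeric(1),
                            "mean_Ea") / 1000),
             collapse = ", "))

  out$kissinger <- stage("kissinger", kissinger_regression(out$peaks))
  out$thermo <- stage("thermo", {
    tt <- lapply(out$profiles, thermo_table, table = out$iso_T,
                 peaks = out$peaks, Tm = config$Tm)
    do.call(rbind, tt)
  })

  if (!is.null(config$yields)) {
    out$yields <- stage("yields", {
      w <- config$yields$weighings
      if (is.character(w)) w <- read_weighings(w)
      compute_yields(w, config$yields$W_feed)
    })
  }
  if (!is.null(config$ann)) {
    out$ann <- stage("ann", {
      a <- config$ann
      np <- if (is.null(a$n_points)) 210L else a$n_points
      ds <- build_ann_dataset(out$curves, n_points = np)
      sp_args <- a[setdiff(names(a), "n_points")]
      if (is.null(sp_args$seed)) sp_args$seed <- config$seed
      train_ann(ds, do.call(ann_spec, sp_args))
    })
    note("ann: r_test = %.4f, mse_test = %.3g",
         out$ann$metrics$r_test, out$ann$metrics$mse_test)
  }

  if (!is.null(config$out_dir)) {
    stage("write", .write_bundle(out, config))
  }
  class(out) <- "pipeline_result"
  out
}

.write_bundle <- function(out, config) {
  dir <- config$out_dir
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  for (i in seq_along(out$thermograms)) {
    write_thermogram(out$thermograms[[i]],
                     file.path(dir, sprintf("thermogram_beta%g.csv",
                                            out$thermograms[[i]]$beta)))
  }
  iso <- data.frame(alpha = out$iso_T$alpha_grid, out$iso_T$T,
                    check.names = FALSE)
  names(iso)[-1] <- paste0("T_beta", format(out$iso_T$betas))
  w(iso, "iso_temperatures.csv")
  write_ea_profiles(out$profiles, file.path(dir, "ea_profiles.csv"))
  w(out$thermo, "thermo.csv")
  w(data.frame(Ea_J_mol = out$kissinger$Ea, A_per_min = out$kissinger$A,
               r2 = out$kissinger$r2), "kissinger.csv")
  if (!is.null(out$yields)) {
    y <- out$yields
    w(data.frame(product = c("liquid", "char", "gas"),
                 mass_g = c(y$W_liquid, y$W_char, y$W_gas),
                 yield_wt_pct = c(y$pct_liquid, y$pct_char, y$pct_gas)),
      "yields.csv")
  }
  if (!is.null(out$ann)) {
    write_ann_model(out$ann$model, file.path(dir, "ann_model.json"))
    w(data.frame(metric = c("mse_train", "mse_val", "mse_test",
                            "r_train", "r_val", "r_test", "best_epoch"),
                 value = unlist(out$ann$metrics[c(
                   "mse_train", "mse_val", "mse_test",
                   "r_train", "r_val", "r_test", "best_epoch")])),
      "ann_metrics.csv")
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)))
  w(manifest, "manifest.csv")
  writeLines(out$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
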