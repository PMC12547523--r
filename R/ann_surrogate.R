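#' Specification for the mass-loss ANN surrogate
#'
#' A small feed-forward network with one hidden layer of logistic (sigmoid)
#' units and a linear output maps (temperature, heating rate) to fractional
#' mass loss. Training minimises mean squared error with an L2 weight
#' penalty; the penalty weight lambda is selected on the validation split
#' from `lambda_grid`. Training proceeds in warm-started optimisation
#' segments ("epochs") of `iters_per_epoch` BFGS iterations each, with the
#' validation MSE tracked per epoch; the reported model is the epoch/lambda
#' pair with the lowest validation MSE.
#'
#' @param hidden hidden-layer width(s); only a single hidden layer is
#'   supported (default 4 neurons).
#' @param split fractions for train/test/validation (default 0.60 / 0.20 /
#'   0.20; must sum to 1).
#' @param max_epochs maximum number of optimisation segments (default 25).
#' @param iters_per_epoch BFGS iterations per segment (default 200; long
#'   segments let the quasi-Newton step converge, short ones give a finer
#'   early-stopping grid).
#' @param lambda_grid candidate L2 penalty weights.
#' @param seed integer seed controlling the split assignment and weight
#'   initialisation; fixed seed gives identical results end to end.
#' @return an object of class `ann_spec`.
#' @export
ann_spec <- function(hidden = 4L, split = c(0.60, 0.20, 0.20),
                     max_epochs = 25L, iters_per_epoch = 200L,
                     lambda_grid = c(1e-4, 1e-3, 1e-2), seed = 1L) {
  if (length(hidden) != 1L) {
    stop("only one hidden layer is supported; supply a single width",
         call. = FALSE)
  }
  stopifnot(hidden >= 1L, length(split) == 3L, all(split > 0),
            max_epochs >= 1L, iters_per_epoch >= 1L,
            all(lambda_grid >= 0))
  if (abs(sum(split) - 1) > 1e-8) stop("split must sum to 1", call. = FALSE)
  structure(list(hidden = as.integer(hidden), split = split,
                 max_epochs = as.integer(max_epochs),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 lambda_grid = lambda_grid, seed = as.integer(seed)),
            class = "ann_spec")
}

#' Build a supervised (temperature, heating rate) -> mass-loss dataset
#'
#' Samples each conversion curve on an even temperature grid over the
#' curves' common temperature window and interpolates the fractional mass
#' loss there. Features are z-score standardised with the scalers stored
#' for later prediction; the target stays on its natural \[0, 1\] scale.
#'
#' @param curves list of `conversion_curve` objects.
#' @param n_points grid points per curve (default 210, so four curves give
#'   840 rows).
#' @param n_weights reference network size used for the underdetermination
#'   check (default 17, a 2-4-1 network); fewer than `10 * n_weights` total
#'   rows triggers a warning.
#' @return an object of class `ann_dataset`: data frame `data` with raw
#'   `T`, `beta`, `y` and standardised `T_s`, `beta_s`; `scalers` with the
#'   feature means and standard deviations; `T_range`.
#' @export
build_ann_dataset <- function(curves, n_points = 210L, n_weights = 17L) {
  stopifnot(all(vapply(curves, inherits, TRUE, "conversion_curve")),
            n_points >= 2L)
  lo <- max(vapply(curves, function(cv) min(cv$temperature), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$temperature), numeric(1)))
  if (hi <= lo) stop("curves share no common temperature window",
                     call. = FALSE)
  grid <- seq(lo, hi, length.out = n_points)
  rows <- lapply(curves, function(cv) {
    data.frame(T = grid, beta = cv$beta,
               y = stats::approx(cv$temperature, cv$alpha, xout = grid)$y)
  })
  df <- do.call(rbind, rows)
  df$y <- pmin(pmax(df$y, 0), 1)
  if (nrow(df) < 10L * n_weights) {
    warning(sprintf(
      "only %d rows for ~%d weights: network may be underdetermined",
      nrow(df), n_weights), call. = FALSE)
  }
  sc <- list(
    T = c(mean = mean(df$T), sd = max(stats::sd(df$T), 1e-12)),
    beta = c(mean = mean(df$beta), sd = {
      s <- stats::sd(df$beta); if (!is.finite(s) || s == 0) 1 else s
    }))
  df$T_s <- (df$T - sc$T["mean"]) / sc$T["sd"]
  df$beta_s <- (df$beta - sc$beta["mean"]) / sc$beta["sd"]
  structure(list(data = df, scalers = sc, T_range = c(lo, hi)),
            class = "ann_dataset")
}

#' Train the mass-loss surrogate network
#'
#' Rows are assigned at random (under the spec seed) to train/test/
#' validation splits in the spec's proportions (exact up to one row of
#' rounding). For every lambda in the grid the network is trained from a
#' seeded uniform initialisation in warm-started segments, recording the
#' validation MSE after each; the weights from the overall best segment are
#' kept. Metrics use predictions clamped to \[0, 1\], as served by
#' [predict_ann()].
#'
#' @param dataset an `ann_dataset`.
#' @param spec an [ann_spec()].
#' @return list with `model` (class `ann_model`) and `metrics` (class
#'   `ann_metrics`: `mse_train`, `mse_val`, `mse_test`, `r_train`, `r_val`,
#'   `r_test`, `best_epoch`, `lambda`, `converged`).
#' @export
train_ann <- function(dataset, spec = ann_spec()) {
  stopifnot(inherits(dataset, "ann_dataset"), inherits(spec, "ann_spec"))
  df <- dataset$data
  n <- nrow(df)
  set.seed(spec$seed)
  perm <- sample.int(n)
  n_train <- round(spec$split[1] * n)
  n_test <- round(spec$split[2] * n)
  idx <- list(train = perm[seq_len(n_train)],
              test = perm[n_train + seq_len(n_test)],
              val = perm[(n_train + n_test + 1):n])
  X <- as.matrix(df[, c("T_s", "beta_s")])
  y <- df$y
  nw <- (ncol(X) + 1L) * spec$hidden + (spec$hidden + 1L)

  mse <- function(fit, i) mean((pmin(pmax(
    as.numeric(stats::predict(fit, X[i, , drop = FALSE])), 0), 1) - y[i])^2)

  best <- list(val = Inf, fit = NULL, epoch = NA_integer_,
               lambda = NA_real_, converged = FALSE)
  for (lam in spec$lambda_grid) {
    set.seed(spec$seed)
    wts <- stats::runif(nw, -0.5, 0.5)
    prev_val <- Inf
    for (epoch in seq_len(spec$max_epochs)) {
      fit <- nnet::nnet(X[idx$train, ], y[idx$train], size = spec$hidden,
                        Wts = wts, decay = lam, linout = TRUE,
                        maxit = spec$iters_per_epoch, trace = FALSE)
      wts <- fit$wts
      v <- mse(fit, idx$val)
      if (v < best$val) {
        best <- list(val = v, fit = fit, epoch = epoch, lambda = lam,
                     converged = TRUE)
      }
      if (is.finite(prev_val) && abs(prev_val - v) < 1e-14) break
      prev_val <- v
    }
  }
  fit <- best$fit
  model <- structure(
    list(fit = fit, hidden = spec$hidden, scalers = dataset$scalers,
         T_range = dataset$T_range, spec = spec, lambda = best$lambda),
    class = "ann_model")
  pred_r <- function(i) {
    p <- pmin(pmax(as.numeric(stats::predict(fit, X[i, , drop = FALSE])),
                   0), 1)
    if (stats::sd(p) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(p, y[i])
  }
  metrics <- structure(
    list(mse_train = mse(fit, idx$train), mse_val = best$val,
         mse_test = mse(fit, idx$test),
         r_train = pred_r(idx$train), r_val = pred_r(idx$val),
         r_test = pred_r(idx$test),
         best_epoch = best$epoch, lambda = best$lambda,
         converged = best$converged, n = n, split_sizes = lengths(idx)),
    class = "ann_metrics")
  list(model = model, metrics = metrics)
}

#' @export
print.ann_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<ann_metrics> mse train/val/test = %.3g / %.3g / %.3g; ",
    "r = %.4f / %.4f / %.4f; best epoch %d (lambda %.1g)\n"),
    x$mse_train, x$mse_val, x$mse_test, x$r_train, x$r_val, x$r_test,
    x$best_epoch, x$lambda))
  invisible(x)
}

#' Predict fractional mass loss from the trained surrogate
#'
#' Standardises the query with the stored scalers, evaluates the network
#' and clamps the output to \[0, 1\]. Queries outside the training
#' temperature range trigger an extrapolation warning. Predicted curves are
#' not constrained to be monotone in temperature.
#'
#' @param model an `ann_model` from [train_ann()].
#' @param T temperatures, in the same units the training curves used.
#' @param beta heating rates, K min^-1 (recycled to the length of `T`).
#' @return predicted mass-loss fractions in \[0, 1\].
#' @export
predict_ann <- function(model, T, beta) {
  stopifnot(inherits(model, "ann_model"))
  if (any(T < model$T_range[1] - 1e-9 | T > model$T_range[2] + 1e-9)) {
    warning("query temperature outside the training range: extrapolating",
            call. = FALSE)
  }
  sc <- model$scalers
  X <- cbind(T_s = (T - sc$T["mean"]) / sc$T["sd"],
             beta_s = (beta - sc$beta["mean"]) / sc$beta["sd"])
  pmin(pmax(as.numeric(stats::predict(model$fit, X)), 0), 1)
}

#' Serialise / restore the surrogate as a flat JSON artifact
#'
#' Writes the weights, architecture, scalers and training range to a plain
#' JSON file, and rebuilds a functioning `ann_model` from it.
#'
#' @param model an `ann_model`.
#' @param path output JSON path.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(hidden = model$hidden, wts = model$fit$wts,
              scalers = lapply(model$scalers, as.list),
              T_range = model$T_range, lambda = model$lambda)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nw <- length(obj$wts)
  # rebuild an nnet skeleton carrying the stored weights
  set.seed(0)
  dummyX <- matrix(stats::runif(10 * 2), ncol = 2,
                   dimnames = list(NULL, c("T_s", "beta_s")))
  fit <- nnet::nnet(dummyX, stats::runif(10), size = obj$hidden,
                    linout = TRUE, maxit = 1, trace = FALSE)
  stopifnot(length(fit$wts) == nw)
  fit$wts <- as.numeric(obj$wts)
  sc <- lapply(obj$scalers, function(s) unlist(s))
  structure(list(fit = fit, hidden = obj$hidden, scalers = sc,
                 T_range = as.numeric(obj$T_range), spec = NULL,
                 lambda = obj$lambda),
            class = "ann_model")
}
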