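#' Three-phase pyrolysis product yields from component weighings
#'
#' Computes the liquid, char and gas masses and weight-percent yields from
#' before/after weighings of the apparatus components:
#' * liquid mass = sum of (after - before) over the condenser, elbow joint,
#'   adopter joint and flask;
#' * char mass = (after - before) of the round-bottom flask (the reactor);
#' * gas mass = feed - (liquid + char), always by difference;
#' * yields in wt% of the feed, with the gas percentage by difference so
#'   that the three percentages close to exactly 100.
#'
#' @param weighings data frame with columns `component` (one of
#'   `"condenser"`, `"elbow_joint"`, `"adopter_joint"`, `"flask"`,
#'   `"round_bottom_flask"`), `before_g`, `after_g`.
#' @param W_feed feed mass, g (> 0).
#' @return an object of class `yield_set`: masses `W_feed`, `W_liquid`,
#'   `W_char`, `W_gas` (g) and percentages `pct_liquid`, `pct_char`,
#'   `pct_gas`.
#' @examples
#' w <- data.frame(
#'   component = c("condenser", "elbow_joint", "adopter_joint", "flask",
#'                 "round_bottom_flask"),
#'   before_g = c(100, 50, 40, 80, 120),
#'   after_g  = c(103, 50.8, 40.5, 80.36, 120.36))
#' compute_yields(w, W_feed = 10)
#' @export
compute_yields <- function(weighings, W_feed) {
  stopifnot(is.data.frame(weighings),
            all(c("component", "before_g", "after_g") %in% names(weighings)))
  if (!is.numeric(W_feed) || W_feed <= 0) {
    stop("W_feed must be positive", call. = FALSE)
  }
  liquid_parts <- c("condenser", "elbow_joint", "adopter_joint", "flask")
  comp <- as.character(weighings$component)
  unknown <- setdiff(comp, c(liquid_parts, "round_bottom_flask"))
  if (length(unknown)) {
    stop("unknown component(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!all(liquid_parts %in% comp) || !"round_bottom_flask" %in% comp) {
    stop("all liquid-train components and the round_bottom_flask required",
         call. = FALSE)
  }
  if (any(weighings$before_g < 0) || any(weighings$after_g < 0)) {
    stop("weighings must be non-negative", call. = FALSE)
  }
  dw <- weighings$after_g - weighings$before_g
  W_liquid <- sum(dw[comp %in% liquid_parts])
  W_char <- sum(dw[comp == "round_bottom_flask"])
  if (W_liquid < 0) {
    bad <- comp[comp %in% liquid_parts & dw < 0]
    stop("negative liquid mass; check weighings for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (W_char < 0) {
    stop("negative char mass; check weighings for: round_bottom_flask",
         call. = FALSE)
  }
  if (W_liquid + W_char > W_feed) {
    stop(sprintf(
      "mass-balance violation: liquid + char = %.4g g exceeds feed %.4g g",
      W_liquid + W_char, W_feed), call. = FALSE)
  }
  yield_set(W_liquid, W_char, W_feed)
}

#' Assemble a yield set from product masses
#'
#' Applies the mass-balance relations directly when the liquid and char
#' masses are already known: gas by difference in mass and in percentage.
#'
#' @param W_liquid,W_char product masses, g.
#' @param W_feed feed mass, g.
#' @return a `yield_set`.
#' @export
yield_set <- function(W_liquid, W_char, W_feed) {
  if (W_liquid < 0 || W_char < 0 || W_feed <= 0) {
    stop("masses must be non-negative and feed positive", call. = FALSE)
  }
  if (W_liquid + W_char > W_feed) {
    stop("mass-balance violation: liquid + char exceeds feed", call. = FALSE)
  }
  W_gas <- W_feed - (W_liquid + W_char)
  pct_liquid <- W_liquid / W_feed * 100
  pct_char <- W_char / W_feed * 100
  pct_gas <- 100 - (pct_liquid + pct_char)
  structure(list(W_feed = W_feed, W_liquid = W_liquid, W_char = W_char,
                 W_gas = W_gas, pct_liquid = pct_liquid,
                 pct_char = pct_char, pct_gas = pct_gas),
            class = "yield_set")
}

#' @export
print.yield_set <- function(x, ...) {
  cat(sprintf(paste0(
    "<yield_set> feed %.3g g: liquid %.3g g (%.1f wt%%), ",
    "char %.3g g (%.1f wt%%), gas %.3g g (%.1f wt%%)\n"),
    x$W_feed, x$W_liquid, x$pct_liquid, x$W_char, x$pct_char,
    x$W_gas, x$pct_gas))
  invisible(x)
}

#' Summarise replicate yield sets
#'
#' Mean and sample standard deviation of the masses and percentages across
#' replicate runs (pyrolysis experiments are typically run in triplicate).
#'
#' @param sets list of `yield_set` objects.
#' @return data frame with one row per product (`liquid`, `char`, `gas`)
#'   and columns `mass_mean_g`, `mass_sd_g`, `pct_mean`, `pct_sd`.
#' @export
summarize_yields <- function(sets) {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, TRUE, "yield_set")))
  grab <- function(f) vapply(sets, `[[`, numeric(1), f)
  prods <- list(liquid = c("W_liquid", "pct_liquid"),
                char = c("W_char", "pct_char"),
                gas = c("W_gas", "pct_gas"))
  do.call(rbind, lapply(names(prods), function(p) {
    m <- grab(prods[[p]][1]); pc <- grab(prods[[p]][2])
    data.frame(product = p, mass_mean_g = mean(m),
               mass_sd_g = if (length(m) > 1) stats::sd(m) else NA_real_,
               pct_mean = mean(pc),
               pct_sd = if (length(pc) > 1) stats::sd(pc) else NA_real_)
  }))
}

#' Read component weighings from CSV
#'
#' Expected columns: `component,before_g,after_g`.
#'
#' @param path file path.
#' @return a data frame suitable for [compute_yields()].
#' @export
read_weighings <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("component", "before_g", "after_g") %in% names(df)))
  df
}
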