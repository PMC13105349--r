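#' Censused survival series for one culture replicate
#'
#' Container for raw aliquot counts from one replicate culture: one row of
#' `counts` per census day, one column per aliquot, together with the
#' counting geometry needed to scale counts back to whole-container
#' abundance.
#'
#' @param replicate Replicate identifier.
#' @param treatment Treatment label (e.g. `"light"` or `"dark"`).
#' @param days Census times in days (strictly increasing), relative to a
#'   stated origin — conventionally hatching.
#' @param counts Integer matrix of aliquot counts, `length(days)` rows.
#' @param aliquot_ml,container_ml Counting geometry (mL).
#' @return An object of class `survival_series`.
#' @export
survival_series <- function(replicate, treatment, days, counts,
                            aliquot_ml, container_ml) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(days), all(counts >= 0),
            !is.unsorted(days, strictly = TRUE),
            aliquot_ml > 0, container_ml > 0)
  structure(list(replicate = replicate, treatment = treatment,
                 days = days, counts = counts,
                 aliquot_ml = aliquot_ml, container_ml = container_ml),
            class = "survival_series")
}

#' @export
print.survival_series <- function(x, ...) {
  cat(sprintf("Survival series: replicate %s (%s), %d censuses, %d aliquots\n",
              x$replicate, x$treatment, length(x$days), ncol(x$counts)))
  print(counts_to_abundance(x))
  invisible(x)
}

#' Scale aliquot counts to whole-container abundance
#'
#' Abundance at each census is the mean aliquot count times the
#' container-to-aliquot volume ratio.
#'
#' @param series A [survival_series()].
#' @return Data frame with columns `day` and `abundance`.
#' @export
#' @examples
#' s <- survival_series(1, "light", 0:2, matrix(c(2, 2, 2, 1, 1, 1), 3, 2),
#'                      aliquot_ml = 1, container_ml = 100)
#' counts_to_abundance(s)
counts_to_abundance <- function(series) {
  stopifnot(inherits(series, "survival_series"))
  if (ncol(series$counts) == 0) stop("no aliquot counts at any census")
  data.frame(day = series$days,
             abundance = rowMeans(series$counts) *
               series$container_ml / series$aliquot_ml)
}

#' Fit the exponential survival model to census counts
#'
#' Estimates the instantaneous mortality rate \eqn{M} of the model
#' \eqn{N_t = N_0 e^{-Mt}} by ordinary least squares of \eqn{\ln N_t} on
#' \eqn{t}. \eqn{M} is minus the slope; the intercept estimates
#' \eqn{\ln N_0} at the time origin. Censuses with zero abundance cannot
#' enter a log fit and are dropped with a warning.
#'
#' With `scope = "pooled"` (default) all replicates contribute points to one
#' regression; with `scope = "replicate"` each replicate is fitted separately
#' and \eqn{M} is the mean of the per-replicate slopes, with its standard
#' error taken across replicates.
#'
#' @param series A [survival_series()] or a list of them (e.g. from
#'   [simulate_survival()]).
#' @param scope `"pooled"` or `"replicate"`.
#' @param t0 Optional time-origin offset in days, subtracted from census
#'   times before fitting (default 0: times are already relative to the
#'   desired origin).
#' @return An object of class `mortality_fit` with components `m` (day^-1),
#'   `ln_n0`, `se_m`, `r_squared`, `n` (census points used), `scope`,
#'   `treatment`, and (for replicate scope) `per_replicate`, a data frame of
#'   per-replicate slopes.
#' @seealso [pld_last_survivor()], [survival_ratio()]
#' @export
#' @examples
#' sims <- simulate_survival(survival_sim_spec(m = 0.165, seed = 11))
#' fit <- fit_mortality(sims)
#' summary(fit)
fit_mortality <- function(series, scope = c("pooled", "replicate"), t0 = 0) {
  scope <- match.arg(scope)
  if (inherits(series, "survival_series")) series <- list(series)
  stopifnot(length(series) >= 1,
            all(vapply(series, inherits, TRUE, "survival_series")))
  tab <- do.call(rbind, lapply(series, function(s) {
    ab <- counts_to_abundance(s)
    data.frame(replicate = s$replicate, day = ab$day - t0,
               abundance = ab$abundance)
  }))
  nz <- tab$abundance > 0
  if (any(!nz)) {
    warning(sum(!nz), " zero-abundance census(es) dropped from the log fit")
    tab <- tab[nz, , drop = FALSE]
  }
  if (nrow(tab) < 2) stop("fewer than 2 usable (positive-abundance) censuses")

  treatment <- unique(vapply(series, `[[`, "", "treatment"))
  if (scope == "pooled") {
    fit <- stats::lm(log(abundance) ~ day, data = tab)
    sm <- summary(fit)
    out <- list(m = -unname(stats::coef(fit)[2]),
                ln_n0 = unname(stats::coef(fit)[1]),
                se_m = sm$coefficients[2, 2],
                r_squared = sm$r.squared,
                n = nrow(tab), scope = scope, treatment = treatment,
                t0 = t0, lm_fit = fit, data = tab)
  } else {
    reps <- split(tab, tab$replicate)
    per <- do.call(rbind, lapply(reps, function(d) {
      if (nrow(d) < 2) return(NULL)
      f <- stats::lm(log(abundance) ~ day, data = d)
      data.frame(replicate = d$replicate[1],
                 m = -unname(stats::coef(f)[2]),
                 ln_n0 = unname(stats::coef(f)[1]),
                 r_squared = summary(f)$r.squared)
    }))
    if (is.null(per) || nrow(per) < 1)
      stop("no replicate had 2 or more usable censuses")
    out <- list(m = mean(per$m), ln_n0 = mean(per$ln_n0),
                se_m = if (nrow(per) > 1)
                  stats::sd(per$m) / sqrt(nrow(per)) else NA_real_,
                r_squared = mean(per$r_squared),
                n = nrow(tab), scope = scope, treatment = treatment,
                t0 = t0, per_replicate = per, data = tab)
  }
  class(out) <- "mortality_fit"
  out
}

#' @export
print.mortality_fit <- function(x, digits = 4, ...) {
  cat("Exponential survival model  N_t = N0 * exp(-M t)\n")
  if (length(x$treatment))
    cat("  treatment:", paste(x$treatment, collapse = ", "), "\n")
  cat(sprintf("  M     = %.*g day^-1  (SE %.*g)\n", digits, x$m, digits,
              x$se_m))
  cat(sprintf("  ln N0 = %.*g  (N0 ~ %.*g)\n", digits, x$ln_n0, digits,
              exp(x$ln_n0)))
  cat(sprintf("  fit: %s, %d census points, R^2 = %.3f\n",
              x$scope, x$n, x$r_squared))
  invisible(x)
}

#' @export
summary.mortality_fit <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$per_replicate)) {
    cat("Per-replicate slopes:\n")
    print(object$per_replicate, row.names = FALSE)
  } else if (!is.null(object$lm_fit)) {
    cat("\nUnderlying log-linear regression:\n")
    print(summary(object$lm_fit)$coefficients)
  }
  invisible(object)
}

#' @export
coef.mortality_fit <- function(object, ...) {
  c(m = object$m, ln_n0 = object$ln_n0)
}

#' Predicted abundance under a fitted survival model
#'
#' @param object A `mortality_fit`.
#' @param newdata Optional data frame with a `day` column, or a numeric
#'   vector of days; defaults to the fitted census days.
#' @param ... Unused.
#' @return Predicted abundance \eqn{\hat N_0 e^{-\hat M t}} at each day.
#' @export
predict.mortality_fit <- function(object, newdata = NULL, ...) {
  days <- if (is.null(newdata)) object$data$day
          else if (is.data.frame(newdata)) newdata$day else newdata
  exp(object$ln_n0 - object$m * days)
}

#' @export
residuals.mortality_fit <- function(object, ...) {
  log(object$data$abundance) - (object$ln_n0 - object$m * object$data$day)
}

#' @export
plot.mortality_fit <- function(x, ...) {
  graphics::plot(x$data$day, log(x$data$abundance),
                 xlab = "days", ylab = "ln abundance", ...)
  graphics::abline(a = x$ln_n0, b = -x$m, lty = 2)
  invisible(x)
}

#' Parametric resampling from a fitted survival model
#'
#' Draws new Poisson aliquot-count experiments whose latent decay follows the
#' fitted \eqn{M} and \eqn{N_0}.
#'
#' @param object A `mortality_fit`.
#' @param nsim Number of simulated replicate sets.
#' @param seed Integer seed.
#' @param days Census days (default the fitted days).
#' @param container_ml,aliquot_ml,n_aliquots Counting geometry.
#' @param ... Unused.
#' @return A list of `nsim` lists of [survival_series()].
#' @export
simulate.mortality_fit <- function(object, nsim = 1, seed = 1L,
                                   days = NULL, container_ml = 100,
                                   aliquot_ml = 1, n_aliquots = 3, ...) {
  if (is.null(days)) days <- sort(unique(object$data$day))
  lapply(seq_len(nsim), function(i) {
    simulate_survival(survival_sim_spec(
      n0 = exp(object$ln_n0), m = max(object$m, 0), days = days,
      container_ml = container_ml, aliquot_ml = aliquot_ml,
      n_aliquots = n_aliquots, n_replicates = 1,
      treatment = paste(object$treatment, collapse = "+"),
      seed = as.integer(seed) + i - 1L))[[1]]
  })
}

#' Estimate fecundity from serial-dilution counts
#'
#' Back-calculates the clutch egg number from counts of small aliquots of a
#' serially diluted spawn: \eqn{N_0 =} mean count / aliquot volume x product
#' of dilution factors x total volume.
#'
#' @param counts Integer vector of aliquot counts (or a data frame with a
#'   `count` column as returned by [simulate_dilution_counts()]).
#' @param aliquot_ml Counted aliquot volume (mL).
#' @param dilution_factors Serial dilution factors applied before counting.
#' @param total_ml Total standardized volume of the spawn (mL).
#' @return An object of class `fecundity_estimate`: list with `n0`, `cv`
#'   (coefficient of variation across aliquots), `total_ml`,
#'   `dilution_factors`.
#' @export
#' @examples
#' estimate_fecundity(c(10, 10, 10), aliquot_ml = 0.5,
#'                    dilution_factors = c(100, 100), total_ml = 100)
estimate_fecundity <- function(counts, aliquot_ml, dilution_factors,
                               total_ml) {
  if (is.data.frame(counts)) counts <- counts$count
  stopifnot(length(counts) >= 1, all(counts >= 0), aliquot_ml > 0,
            total_ml > 0, length(dilution_factors) >= 1)
  n0 <- mean(counts) / aliquot_ml * prod(dilution_factors) * total_ml
  cv <- if (length(counts) > 1 && mean(counts) > 0)
    stats::sd(counts) / mean(counts) else NA_real_
  structure(list(n0 = n0, cv = cv, total_ml = total_ml,
                 dilution_factors = dilution_factors,
                 aliquot_ml = aliquot_ml, counts = counts),
            class = "fecundity_estimate")
}

#' @export
print.fecundity_estimate <- function(x, ...) {
  cat(sprintf("Fecundity estimate: N0 = %.4g eggs (CV %.2f, %d aliquots)\n",
              x$n0, x$cv, length(x$counts)))
  invisible(x)
}

#' Clutch-exhaustion pelagic larval duration
#'
#' The time until the last larva of a clutch survives under exponential
#' mortality: solving \eqn{N_0 e^{-Mt} = 1} gives
#' \eqn{t^* = \ln(N_0) / M}. This operationalizes the maximum pelagic larval
#' duration of a clutch of `n0` eggs dying at rate `m`.
#'
#' @param n0 Fecundity (eggs), at least 1.
#' @param m Instantaneous mortality rate (day^-1), strictly positive.
#' @return Duration in days.
#' @export
#' @examples
#' pld_last_survivor(2e7, 0.093)  # light-reared larvae
#' pld_last_survivor(2e7, 0.165)  # dark-reared larvae
pld_last_survivor <- function(n0, m) {
  stopifnot(all(n0 >= 1))
  if (any(m <= 0)) stop("duration undefined for non-positive mortality rate")
  log(n0) / m
}

#' Ratio of surviving fractions under two mortality rates
#'
#' Under the exponential model the fraction of a clutch alive at time `t` is
#' \eqn{e^{-Mt}}, so scenario a's survivorship exceeds scenario b's by the
#' factor \eqn{e^{(M_b - M_a) t}}.
#'
#' @param m_a,m_b Mortality rates (day^-1) of the two scenarios.
#' @param t Time since the shared origin (days, non-negative).
#' @return The survivorship ratio (scenario a relative to scenario b).
#' @export
#' @examples
#' survival_ratio(0.093, 0.165, 5)  # ~1.4x higher survivorship in light
survival_ratio <- function(m_a, m_b, t) {
  stopifnot(all(t >= 0))
  exp((m_b - m_a) * t)
}

#' Ratio of pelagic larval durations between scenarios
#'
#' Longer duration over shorter. With a shared fecundity
#' \eqn{t^* = \ln(N_0)/M}, so this equals the inverse ratio of the mortality
#' rates.
#'
#' @param pld_a,pld_b Durations in days (both positive).
#' @return Ratio `>= 1`.
#' @export
#' @examples
#' duration_ratio(181, 102)  # ~1.8x
duration_ratio <- function(pld_a, pld_b) {
  stopifnot(pld_a > 0, pld_b > 0)
  max(pld_a, pld_b) / min(pld_a, pld_b)
}

#' Scenario durations table
#'
#' Convenience constructor pairing per-scenario mortality rates with a shared
#' fecundity, returning the implied last-survivor durations.
#'
#' @param m Named numeric vector of mortality rates (day^-1); names are
#'   scenario labels.
#' @param n0 Shared fecundity (eggs).
#' @return Data frame with columns `scenario`, `m`, `pld_days`, `ln_n0`.
#' @export
#' @examples
#' scenario_durations(c(light = 0.093, dark = 0.165), n0 = 2e7)
scenario_durations <- function(m, n0) {
  stopifnot(!is.null(names(m)), all(m > 0), n0 >= 1)
  data.frame(scenario = names(m), m = unname(m),
             pld_days = log(n0) / unname(m), ln_n0 = log(n0))
}
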