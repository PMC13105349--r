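# Mortality estimation, fecundity, pelagic larval duration, model ratios.

test_that("aliquot counts scale to container abundance", {
  s <- survival_series(1, "light", 0, matrix(c(2, 2, 2), 1, 3),
                       aliquot_ml = 1, container_ml = 100)
  expect_equal(counts_to_abundance(s)$abundance, 200)
  s2 <- survival_series(1, "light", 0, matrix(c(1, 2, 3), 1, 3),
                        aliquot_ml = 1, container_ml = 1000)
  expect_equal(counts_to_abundance(s2)$abundance, 2000)
  s3 <- survival_series(1, "dark", 0:1, matrix(0, 2, 3),
                        aliquot_ml = 1, container_ml = 100)
  expect_equal(counts_to_abundance(s3)$abundance, c(0, 0))
})

test_that("noise-free exponential decay is recovered exactly", {
  days <- 0:5
  ab <- 200 * exp(-0.1 * days)
  s <- survival_series(1, "light", days, matrix(ab / 100, 6, 1),
                       aliquot_ml = 1, container_ml = 100)
  fit <- suppressWarnings(fit_mortality(s))  # lm warns on a perfect fit
  expect_equal(fit$m, 0.1, tolerance = 1e-10)
  expect_equal(exp(fit$ln_n0), 200, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)
  # constant abundance -> zero mortality
  sc <- survival_series(1, "light", days, matrix(2, 6, 1), 1, 100)
  expect_equal(suppressWarnings(fit_mortality(sc))$m, 0, tolerance = 1e-12)
})

test_that("pooled fit recovers the simulated rate and matches an independent OLS", {
  sims <- simulate_survival(survival_sim_spec(
    n0 = 2000, m = 0.165, days = 0:5, container_ml = 100, aliquot_ml = 1,
    n_aliquots = 3, n_replicates = 10, seed = 11))
  fit <- fit_mortality(sims, scope = "pooled")
  expect_lt(abs(fit$m - 0.165), 0.02)
  # independent oracle: normal-equations slope on the same (t, ln N) table
  tab <- do.call(rbind, lapply(sims, function(s) {
    data.frame(t = s$days, y = log(rowMeans(s$counts) * 100))
  }))
  tab <- tab[is.finite(tab$y), ]
  slope <- sum((tab$t - mean(tab$t)) * (tab$y - mean(tab$y))) /
    sum((tab$t - mean(tab$t))^2)
  expect_equal(fit$m, -slope, tolerance = 1e-10)
  # replicate scope averages per-replicate slopes
  fr <- fit_mortality(sims, scope = "replicate")
  expect_equal(fr$m, mean(fr$per_replicate$m), tolerance = 1e-12)
  expect_equal(nrow(fr$per_replicate), 10)
})

test_that("zero-abundance censuses are dropped with a warning", {
  s <- survival_series(1, "dark", 0:3, matrix(c(4, 2, 0, 1), 4, 1), 1, 100)
  expect_warning(fit <- fit_mortality(s), "zero-abundance")
  expect_equal(fit$n, 3)
  s_all0 <- survival_series(1, "dark", 0:2, matrix(0, 3, 1), 1, 100)
  expect_error(suppressWarnings(fit_mortality(s_all0)))
  s_one <- survival_series(1, "dark", 0:1, matrix(c(2, 0), 2, 1), 1, 100)
  expect_error(suppressWarnings(fit_mortality(s_one)), "fewer than 2")
})

test_that("mortality_fit methods are coherent", {
  sims <- simulate_survival(survival_sim_spec(seed = 2))
  fit <- fit_mortality(sims)
  expect_named(coef(fit), c("m", "ln_n0"))
  expect_equal(predict(fit, 0), exp(fit$ln_n0))
  expect_equal(length(residuals(fit)), fit$n)
  expect_output(print(fit), "instantaneous|M ")
  sim <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "survival_series")
})

test_that("fecundity back-calculation follows the dilution arithmetic", {
  est <- estimate_fecundity(c(10, 10, 10), aliquot_ml = 0.5,
                            dilution_factors = c(100, 100), total_ml = 100)
  expect_equal(est$n0, 2e7)
  expect_equal(estimate_fecundity(c(9, 10, 11), 0.5, c(100, 100), 100)$n0,
               2e7)
  expect_equal(estimate_fecundity(c(0, 0, 0), 0.5, c(100, 100), 100)$n0, 0)
})

test_that("last-survivor duration solves N0 exp(-Mt) = 1", {
  # the two printed rates and a shared fecundity give 181 vs 102 days
  expect_equal(pld_last_survivor(exp(0.093 * 181), 0.165), 102, tolerance = 0.002)
  expect_equal(pld_last_survivor(1, 0.1), 0)
  expect_equal(pld_last_survivor(exp(10), 0.1), 100)
  expect_error(pld_last_survivor(100, 0))
  expect_error(pld_last_survivor(0.5, 0.1))
})

test_that("last-survivor duration is monotone in fecundity and mortality", {
  n0 <- exp(seq(1, 20, length.out = 25))
  expect_true(all(diff(pld_last_survivor(n0, 0.12)) > 0))
  ms <- seq(0.01, 0.5, length.out = 25)
  expect_true(all(diff(pld_last_survivor(2e7, ms)) < 0))
})

test_that("scenario durations from the printed rates imply one fecundity", {
  # ln N0 implied by (0.093, 181) and (0.165, 102) agree within 0.5%
  ln_a <- 0.093 * 181
  ln_b <- 0.165 * 102
  expect_lt(abs(ln_a - ln_b) / ln_a, 0.005)
  expect_equal(exp(ln_a), 2.0e7, tolerance = 0.05)
  sd <- scenario_durations(c(light = 0.093, dark = 0.165), n0 = exp(ln_a))
  expect_equal(sd$pld_days[sd$scenario == "light"], 181, tolerance = 1e-10)
  expect_equal(sd$pld_days[sd$scenario == "dark"], 102, tolerance = 0.002)
})

test_that("model survival and duration ratios reproduce the headline factors", {
  expect_equal(round(survival_ratio(0.093, 0.165, 5), 1), 1.4)
  expect_equal(survival_ratio(0.1, 0.1, 7), 1)
  expect_equal(survival_ratio(0, 0.2, 3), exp(0.6))
  # reciprocity for fuzzed inputs
  set.seed(8)
  for (i in 1:20) {
    ma <- runif(1, 0, 0.5); mb <- runif(1, 0, 0.5); t <- runif(1, 0, 200)
    expect_equal(survival_ratio(ma, mb, t) * survival_ratio(mb, ma, t), 1,
                 tolerance = 1e-12)
  }
  expect_equal(round(duration_ratio(181, 102), 1), 1.8)
  expect_equal(duration_ratio(0.165 / 0.093 * 100, 100), 181 / 102,
               tolerance = 0.01)  # rate ratio equals duration ratio
  expect_equal(duration_ratio(50, 50), 1)
  expect_error(duration_ratio(0, 10))
})
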