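#' Specify a simulated survival experiment
#'
#' Describes a larval culture census experiment: a latent cohort decaying as
#' \eqn{N_t = N_0 e^{-Mt}} in a stirred container, censused on stated days by
#' withdrawing small aliquots and counting them. The default geometry mirrors
#' a common sea-urchin protocol: 2 embryos/mL in 1 L at hatching, cultures
#' concentrated to 100 mL for counting, triplicate 1 mL aliquots, daily
#' censuses for six days.
#'
#' @param n0 True initial abundance (individuals) at the time origin.
#' @param m True instantaneous mortality rate (day^-1).
#' @param days Census times in days post-hatching (strictly increasing,
#'   non-negative).
#' @param container_ml Container volume at counting time (mL).
#' @param aliquot_ml Aliquot volume (mL).
#' @param n_aliquots Aliquots counted per census.
#' @param n_replicates Number of replicate cultures.
#' @param treatment Label attached to the series (e.g. `"light"`, `"dark"`).
#' @param seed Integer seed for the Poisson subsampling.
#' @return An object of class `survival_sim_spec`.
#' @seealso [simulate_survival()]
#' @export
survival_sim_spec <- function(n0 = 2000, m = 0.1, days = 0:5,
                              container_ml = 100, aliquot_ml = 1,
                              n_aliquots = 3, n_replicates = 10,
                              treatment = "light", seed = 1L) {
  stopifnot(n0 > 0, m >= 0, all(days >= 0), !is.unsorted(days, strictly = TRUE),
            container_ml > 0, aliquot_ml > 0, aliquot_ml <= container_ml,
            n_aliquots >= 1, n_replicates >= 1)
  structure(list(n0 = n0, m = m, days = days, container_ml = container_ml,
                 aliquot_ml = aliquot_ml, n_aliquots = as.integer(n_aliquots),
                 n_replicates = as.integer(n_replicates),
                 treatment = treatment, seed = as.integer(seed)),
            class = "survival_sim_spec")
}

#' Simulate census counts from exponentially decaying cultures
#'
#' The latent abundance in each replicate container follows
#' \eqn{N_t = N_0 e^{-Mt}}. A well-mixed aliquot of volume \eqn{v} from a
#' container of volume \eqn{V} holds on average \eqn{N_t v / V} individuals,
#' and the observed count is drawn Poisson with that mean — the natural noise
#' model for counting a small subvolume of a mixed suspension.
#'
#' @param spec A [survival_sim_spec()].
#' @return A list of [survival_series()] objects, one per replicate.
#' @export
#' @examples
#' sims <- simulate_survival(survival_sim_spec(n0 = 2000, m = 0.165, seed = 7))
#' sims[[1]]
simulate_survival <- function(spec) {
  stopifnot(inherits(spec, "survival_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  ratio <- spec$aliquot_ml / spec$container_ml
  lapply(seq_len(spec$n_replicates), function(r) {
    mean_n <- spec$n0 * exp(-spec$m * spec$days) * ratio
    counts <- matrix(stats::rpois(length(spec$days) * spec$n_aliquots,
                                  rep(mean_n, each = spec$n_aliquots)),
                     nrow = length(spec$days), byrow = TRUE)
    survival_series(replicate = r, treatment = spec$treatment,
                    days = spec$days, counts = counts,
                    aliquot_ml = spec$aliquot_ml,
                    container_ml = spec$container_ml)
  })
}

#' Simulate a serial-dilution fecundity count
#'
#' Emulates estimating a clutch's egg number by standardizing the spawn to a
#' total volume, serially diluting a subsample, and counting small aliquots
#' of the final dilution. Counts are Poisson with mean
#' \eqn{N_0 / V_{tot} / \prod d_i \times v_{aliquot}}.
#'
#' @param n0 True number of eggs in the clutch.
#' @param total_ml Total standardized volume (mL).
#' @param dilution_factors Numeric vector of serial dilution factors, each
#'   greater than 1 (e.g. `c(100, 100)` for two 1:100 dilutions).
#' @param aliquot_ml Counted aliquot volume (mL).
#' @param n_aliquots Number of aliquots counted.
#' @param seed Integer seed.
#' @return A data frame with columns `aliquot_index` and `count`, with the
#'   simulation geometry in attributes.
#' @export
#' @examples
#' simulate_dilution_counts(2e7, total_ml = 100,
#'                          dilution_factors = c(100, 100),
#'                          aliquot_ml = 0.5, n_aliquots = 3, seed = 1)
simulate_dilution_counts <- function(n0, total_ml, dilution_factors,
                                     aliquot_ml, n_aliquots = 3, seed = 1L) {
  stopifnot(n0 >= 0, total_ml > 0, aliquot_ml > 0, n_aliquots >= 1,
            all(dilution_factors > 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  mu <- n0 / total_ml / prod(dilution_factors) * aliquot_ml
  out <- data.frame(aliquot_index = seq_len(n_aliquots),
                    count = stats::rpois(n_aliquots, mu))
  attr(out, "total_ml") <- total_ml
  attr(out, "dilution_factors") <- dilution_factors
  attr(out, "aliquot_ml") <- aliquot_ml
  out
}

# Save/restore the global RNG state so seeded simulators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
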