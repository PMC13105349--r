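#' Define a dispersal scenario
#'
#' A scenario is a pelagic-duration hypothesis: a label, a particle lifetime
#' (the clutch-exhaustion pelagic larval duration), and the minimum
#' competency age below which settlement is not allowed.
#'
#' @param label Scenario label, e.g. `"light"` or `"dark"`.
#' @param lifetime Particle lifetime in days.
#' @param min_age Minimum competency age in days (default 25).
#' @return An object of class `dispersal_scenario`.
#' @export
#' @examples
#' dispersal_scenario("light", 181)
#' dispersal_scenario("dark", 102)
dispersal_scenario <- function(label, lifetime, min_age = 25) {
  stopifnot(lifetime > min_age)
  structure(list(label = label, lifetime = lifetime, min_age = min_age),
            class = "dispersal_scenario")
}

#' Run a paired two-scenario dispersal experiment
#'
#' Advects one set of particles (shared schedule, field, and seed) and
#' evaluates settlement under each scenario's lifetime and competency age.
#' Because the particles are passive and the random draws are independent of
#' lifetime, the scenarios see identical trajectories and every difference
#' in the metrics is attributable to pelagic duration alone — the paired
#' design behind comparing the scenarios cohort by cohort.
#'
#' @param scenarios List of [dispersal_scenario()] objects.
#' @param field A `gridded_field`.
#' @param schedule A [release_schedule()].
#' @param mask A [shelf_mask()] of settleable habitat.
#' @param dt,output_interval,seed Passed to [run_release()].
#' @return A list of class `scenario_run`: `metrics` (per-cohort
#'   [cohort_metrics()] rows for all scenarios), `records` (settlement
#'   records), and `trajectories`.
#' @export
run_scenarios <- function(scenarios, field, schedule, mask,
                          dt = 1 / 12, output_interval = 1, seed = 1L) {
  stopifnot(length(scenarios) >= 1,
            all(vapply(scenarios, inherits, TRUE, "dispersal_scenario")))
  max_life <- max(vapply(scenarios, `[[`, 0, "lifetime"))
  traj <- run_release(schedule, field, lifetime = max_life, dt = dt,
                      output_interval = output_interval, seed = seed)
  rel <- table(traj$meta$cohort)
  rel <- stats::setNames(as.integer(rel), names(rel))
  records <- do.call(rbind, lapply(scenarios, function(sc)
    detect_settlement(traj, mask, min_age = sc$min_age,
                      lifetime = sc$lifetime, scenario = sc$label)))
  metrics <- do.call(rbind, lapply(scenarios, function(sc) {
    r <- records[records$scenario == sc$label, , drop = FALSE]
    m <- cohort_metrics(r, rel, mask)
    m$scenario <- sc$label
    m
  }))
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, records = records, trajectories = traj),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat("Paired scenario run\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Paired comparison of a dispersal metric between two scenarios
#'
#' Pairs the per-cohort values of one metric across two scenarios, applies a
#' natural-log transform (dispersal metrics are right-skewed and
#' ratio-scaled), and tests the paired differences with a two-tailed paired
#' t test: \eqn{t = \bar d / (s_d / \sqrt{n})} on \eqn{n - 1} degrees of
#' freedom. The scenario effect is reported as the ratio of back-transformed
#' means, \eqn{\exp(\bar d)}. Cohorts with a non-positive value in either
#' scenario cannot be log-transformed and are dropped with a flag; if the
#' paired differences have zero variance the t statistic is undefined and
#' flagged (for identical scenarios the ratio is exactly 1).
#'
#' @param metrics Metrics table from [run_scenarios()] (or equivalent) with
#'   columns `cohort`, `scenario`, and the metric.
#' @param metric Column to compare, e.g. `"mean_displacement_km"`,
#'   `"settled_area_km2"`, `"n_settled"`.
#' @param scenario_order Optional length-2 character vector giving numerator
#'   and denominator scenario.
#' @return An object of class `scenario_comparison`: the paired table,
#'   `ratio` (numerator/denominator of back-transformed means), `t_stat`,
#'   `df`, `p_value`, `transform`, and flags.
#' @export
compare_paired <- function(metrics, metric = "mean_displacement_km",
                           scenario_order = NULL) {
  stopifnot(metric %in% names(metrics))
  scen <- if (is.null(scenario_order)) unique(metrics$scenario)
          else scenario_order
  if (length(scen) != 2) stop("exactly two scenarios are required")
  a <- metrics[metrics$scenario == scen[1], c("cohort", metric)]
  b <- metrics[metrics$scenario == scen[2], c("cohort", metric)]
  tab <- merge(a, b, by = "cohort", suffixes = c("_a", "_b"))
  if (nrow(tab) < 2) stop("need at least 2 paired cohorts")
  if (!setequal(a$cohort, b$cohort)) stop("mismatched cohort sets")
  va <- tab[[paste0(metric, "_a")]]
  vb <- tab[[paste0(metric, "_b")]]
  usable <- va > 0 & vb > 0
  dropped <- sum(!usable)
  va <- va[usable]; vb <- vb[usable]
  if (length(va) < 2) stop("fewer than 2 cohorts with positive metric values")
  d <- log(va) - log(vb)
  zero_var <- isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0
  if (zero_var) {
    t_stat <- if (all(d == 0)) 0 else NA_real_
    p_value <- if (all(d == 0)) 1 else NA_real_
  } else {
    tt <- stats::t.test(log(va), log(vb), paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_value <- tt$p.value
  }
  structure(list(metric = metric, scenarios = scen, table = tab,
                 n_pairs = length(d), ratio = exp(mean(d)),
                 t_stat = t_stat, df = length(d) - 1L, p_value = p_value,
                 transform = "ln", zero_variance = zero_var,
                 dropped_nonpositive = dropped),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison of %s (%s vs %s), ln-transformed\n",
              x$metric, x$scenarios[1], x$scenarios[2]))
  cat(sprintf("  ratio = %.3g, t(%d) = %.3g, two-tailed p = %.3g\n",
              x$ratio, x$df, x$t_stat, x$p_value))
  if (x$zero_variance)
    cat("  note: paired differences have zero variance\n")
  if (x$dropped_nonpositive > 0)
    cat("  note:", x$dropped_nonpositive,
        "cohort pair(s) dropped (non-positive metric)\n")
  invisible(x)
}

#' Multi-generation range expansion
#'
#' Iterates dispersal generation by generation: generation 0 releases from
#' the origin cells; each later generation releases from the previous
#' generation's settlement cells, with the particle budget apportioned by
#' multinomial draws weighted by per-cell settled abundance. Iteration stops
#' at the first generation whose settlements intersect the target region, at
#' a generation with zero settlements (not reached), or at
#' `max_generations`.
#'
#' @param field A `gridded_field`.
#' @param mask A [shelf_mask()] of settleable habitat (settlement target of
#'   every generation).
#' @param origin A `shelf_mask` (or logical matrix on the field grid) of
#'   generation-0 release cells.
#' @param target A `shelf_mask` (or logical matrix) defining the range-edge
#'   region to reach.
#' @param scenario A [dispersal_scenario()].
#' @param n_particles Particle budget per generation.
#' @param max_generations Iteration cap.
#' @param dt,output_interval Integrator settings for [run_release()].
#' @param seed Integer seed; generation g uses `seed + g` so runs are
#'   reproducible end to end.
#' @return An object of class `generation_run`: list with `generations` (a
#'   list of per-generation records: release cells, settlement cells and
#'   counts, reached flag), `reached`, `n_generations`, and the scenario.
#' @export
iterate_generations <- function(field, mask, origin, target, scenario,
                                n_particles = 1000, max_generations = 10,
                                dt = 1 / 12, output_interval = 1,
                                seed = 1L) {
  stopifnot(inherits(scenario, "dispersal_scenario"), n_particles >= 1,
            max_generations >= 1)
  om <- if (inherits(origin, "shelf_mask")) origin$mask else origin
  tm <- if (inherits(target, "shelf_mask")) target$mask else target
  cells <- which(om & mask$mask, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("origin has no settleable cells")
  weights <- rep(1, nrow(cells))
  dx <- field$lon[2] - field$lon[1]

  gens <- list()
  reached <- FALSE
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (g in seq_len(max_generations)) {
    set.seed(as.integer(seed) + g)
    draw <- as.vector(stats::rmultinom(1, n_particles, weights))
    use <- draw > 0
    sites <- data.frame(lon = field$lon[cells[use, 1]],
                        lat = field$lat[cells[use, 2]],
                        n = draw[use])
    sched <- release_schedule(sites, n_per_event = n_particles,
                              n_events = 1, jitter_deg = dx / 2)
    traj <- run_release(sched, field, lifetime = scenario$lifetime, dt = dt,
                        output_interval = output_interval,
                        seed = as.integer(seed) + g)
    rec <- detect_settlement(traj, mask, min_age = scenario$min_age,
                             lifetime = scenario$lifetime,
                             scenario = scenario$label)
    settled_cells <- if (nrow(rec)) {
      agg <- stats::aggregate(list(n = rec$id),
                              by = list(i = rec$cell_i, j = rec$cell_j),
                              FUN = length)
      agg
    } else data.frame(i = integer(), j = integer(), n = integer())
    hit_target <- nrow(rec) > 0 &&
      any(tm[as.matrix(settled_cells[, c("i", "j")])])
    gens[[g]] <- list(generation = g, release_cells = cells[use, , drop = FALSE],
                      n_released = n_particles,
                      settlement = settled_cells,
                      n_settled = nrow(rec), reached = hit_target)
    if (hit_target) { reached <- TRUE; break }
    if (nrow(settled_cells) == 0) break
    cells <- as.matrix(settled_cells[, c("i", "j")])
    colnames(cells) <- c("row", "col")
    weights <- settled_cells$n
  }
  structure(list(generations = gens, reached = reached,
                 n_generations = length(gens), scenario = scenario,
                 seed = as.integer(seed)),
            class = "generation_run")
}

#' @export
print.generation_run <- function(x, ...) {
  cat(sprintf("Generation run (%s, lifetime %g d): %d generation(s), %s\n",
              x$scenario$label, x$scenario$lifetime, x$n_generations,
              if (x$reached) "target reached" else "target not reached"))
  for (g in x$generations)
    cat(sprintf("  gen %d: %d released, %d settled in %d cell(s)%s\n",
                g$generation, g$n_released, g$n_settled,
                nrow(g$settlement), if (g$reached) " [target]" else ""))
  invisible(x)
}

#' Evenly seed particles along a shelf span
#'
#' Builds a single-event release schedule whose particles are evenly
#' apportioned (deterministic largest-remainder rule) across the shelf cells
#' whose latitude falls in `lat_span` — the design used to seed a coastline
#' segment uniformly.
#'
#' @param mask A [shelf_mask()].
#' @param lat_span Length-2 latitude bounds (degrees).
#' @param n_particles Total particle budget.
#' @param ... Passed to [release_schedule()] (e.g. `jitter_deg`,
#'   `depth_range`).
#' @return A [release_schedule()] with one site per shelf cell and per-site
#'   weights `n`.
#' @export
seed_line_release <- function(mask, lat_span, n_particles, ...) {
  stopifnot(inherits(mask, "shelf_mask"), length(lat_span) == 2)
  lat_span <- sort(lat_span)
  cells <- which(mask$mask, arr.ind = TRUE)
  lat <- mask$lat[cells[, 2]]
  keep <- lat >= lat_span[1] & lat <= lat_span[2]
  if (!any(keep)) stop("no shelf cells intersect the latitude span")
  cells <- cells[keep, , drop = FALSE]
  counts <- apportion(n_particles, rep(1, nrow(cells)))
  use <- counts > 0
  sites <- data.frame(lon = mask$lon[cells[use, 1]],
                      lat = mask$lat[cells[use, 2]],
                      n = counts[use])
  release_schedule(sites, n_per_event = n_particles, n_events = 1, ...)
}
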