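#' Validate and normalize a run configuration
#'
#' Reads a YAML (or JSON) configuration for a dispersal experiment, fills
#' defaults, checks units and consistency, and computes a content hash so
#' every output artifact can be traced to the exact configuration that
#' produced it. Defaulted parameters are reported via `message()` — no
#' silent defaults.
#'
#' Required keys: `scenarios` (a list, each with `label` and `lifetime` in
#' days) and `seed`. Optional keys with defaults: `dt` (0.0833 day, i.e.
#' 2 h), `output_interval` (1 day), `min_age` (25 days), `out_dir` (`"."`).
#' Any `field`, `mask`, or `survival` file paths must exist.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return An object of class `run_config`: the normalized list plus
#'   `config_hash`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  required <- c("scenarios", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "))
  defaults <- list(dt = 1 / 12, output_interval = 1, min_age = 25,
                   out_dir = ".")
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
      message("config: '", k, "' defaulted to ", format(defaults[[k]]))
    }
  }
  stopifnot(config$dt > 0, config$output_interval > 0, config$min_age >= 0)
  for (sc in config$scenarios) {
    if (is.null(sc$label) || is.null(sc$lifetime))
      stop("every scenario needs 'label' and 'lifetime'")
    if (sc$lifetime <= config$min_age)
      stop("scenario '", sc$label, "': lifetime (", sc$lifetime,
           " d) must exceed the minimum competency age (", config$min_age,
           " d)")
  }
  for (k in c("field", "mask", "survival")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop("config file reference does not exist: ", config[[k]])
  }
  config$seed <- as.integer(config$seed)
  config$config_hash <- config_hash(config)
  structure(config, class = "run_config")
}

#' Content hash of a configuration
#'
#' FNV-1a 32-bit hash of the canonical YAML serialization (keys sorted,
#' hash field excluded). Identical configurations always hash identically.
#'
#' @param config A list or `run_config`.
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  config$config_hash <- NULL
  config <- config[order(names(config))]
  txt <- yaml::as.yaml(config)
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) h <- .fnv_mix(h, b)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# FNV-1a update: (h XOR byte) * 16777619 mod 2^32, in doubles (exact: all
# intermediates < 2^53).
.fnv_mix <- function(h, b) {
  hx <- h
  # xor via 16-bit halves to stay in integer range
  lo <- bitwXor(as.integer(hx %% 65536), as.integer(b))
  hi <- as.integer(hx %/% 65536)
  x <- hi * 65536 + lo
  p <- 16777619
  lo2 <- (x %% 65536) * p
  hi2 <- ((x %/% 65536) * p) %% 65536
  (hi2 * 65536 + lo2) %% 4294967296
}

#' Summarize run outputs into a report
#'
#' Collects the headline quantities of a completed experiment — scenario
#' pelagic durations and their ratio, per-cohort metrics, paired
#' comparisons, and provenance (seed, config hash) — into a deterministic,
#' machine-readable structure, optionally written as JSON. Zero-settlement
#' cohorts are flagged.
#'
#' @param durations Data frame from [scenario_durations()] (or `NULL`).
#' @param metrics Per-cohort metrics table (or `NULL`).
#' @param comparisons List of [compare_paired()] results (or `NULL`).
#' @param config A `run_config` (or `NULL`).
#' @param path Optional JSON output path.
#' @return A list of class `run_report`; written to `path` if given.
#' @export
report <- function(durations = NULL, metrics = NULL, comparisons = NULL,
                   config = NULL, path = NULL) {
  rep <- list()
  if (!is.null(durations)) {
    rep$pld_days <- stats::setNames(as.list(durations$pld_days),
                                    durations$scenario)
    if (nrow(durations) == 2)
      rep$duration_ratio <- duration_ratio(durations$pld_days[1],
                                           durations$pld_days[2])
  }
  if (!is.null(metrics)) {
    rep$metrics <- metrics
    empty <- metrics[metrics$n_settled == 0, , drop = FALSE]
    if (nrow(empty))
      rep$zero_settlement_cohorts <-
        paste(empty$scenario, empty$cohort, sep = ":")
  }
  if (!is.null(comparisons)) {
    rep$comparisons <- lapply(comparisons, function(cmp) list(
      metric = cmp$metric, ratio = cmp$ratio, t_stat = cmp$t_stat,
      df = cmp$df, p_value = cmp$p_value, transform = cmp$transform))
  }
  if (!is.null(config)) {
    rep$seed <- config$seed
    rep$config_hash <- config$config_hash
  }
  class(rep) <- "run_report"
  if (!is.null(path))
    jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  rep
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report\n")
  if (!is.null(x$pld_days)) {
    for (s in names(x$pld_days))
      cat(sprintf("  PLD[%s] = %.1f d\n", s, x$pld_days[[s]]))
    if (!is.null(x$duration_ratio))
      cat(sprintf("  duration ratio = %.2f\n", x$duration_ratio))
  }
  if (!is.null(x$comparisons))
    for (cmp in x$comparisons)
      cat(sprintf("  %s: ratio %.3g (t = %.3g, p = %.3g)\n",
                  cmp$metric, cmp$ratio, cmp$t_stat, cmp$p_value))
  if (!is.null(x$zero_settlement_cohorts))
    cat("  zero-settlement cohorts:",
        paste(x$zero_settlement_cohorts, collapse = ", "), "\n")
  if (!is.null(x$config_hash))
    cat(sprintf("  seed %d, config %s\n", x$seed, x$config_hash))
  invisible(x)
}
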