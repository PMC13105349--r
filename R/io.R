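#' Write / read a gridded field as JSON
#'
#' Plain-text, lossless (full double precision) serialization of a
#' `gridded_field`: axes, velocity arrays, bathymetry, land mask, and
#' provenance.
#'
#' @param field A `gridded_field`.
#' @param path Output file path.
#' @return `write_field_json` returns `path` invisibly; `read_field_json`
#'   returns the reconstructed `gridded_field`.
#' @export
write_field_json <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  obj <- unclass(field)
  obj$dim <- dim(field$u)
  obj$u <- as.vector(field$u)
  obj$v <- as.vector(field$v)
  obj$depth <- as.vector(field$depth)
  obj$land <- as.vector(field$land)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_field_json
#' @export
read_field_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dim
  null2na <- function(x) { x[vapply(x, is.null, TRUE)] <- NA; x }
  num <- function(x) as.numeric(unlist(null2na(as.list(x))))
  field <- list(
    lon = as.numeric(obj$lon), lat = as.numeric(obj$lat),
    time = as.numeric(obj$time),
    u = array(num(obj$u), d), v = array(num(obj$v), d),
    depth = matrix(num(obj$depth), d[1], d[2]),
    land = matrix(as.logical(unlist(obj$land)), d[1], d[2]),
    recipe = obj$recipe, params = obj$params, coast_lon = obj$coast_lon,
    shelf_width_km = obj$shelf_width_km, lat_ref = obj$lat_ref,
    seed = obj$seed)
  class(field) <- "gridded_field"
  field
}

#' Write / read survival census tables as CSV
#'
#' Long-format schema with one row per counted aliquot: `replicate`,
#' `treatment`, `day`, `aliquot_index`, `count`, `aliquot_ml`,
#' `container_ml`.
#'
#' @param series A [survival_series()] or list of them.
#' @param path CSV file path.
#' @return `write_survival_csv` returns `path` invisibly;
#'   `read_survival_csv` returns a list of `survival_series`.
#' @export
write_survival_csv <- function(series, path) {
  if (inherits(series, "survival_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(replicate = s$replicate, treatment = s$treatment,
               day = rep(s$days, each = ncol(s$counts)),
               aliquot_index = rep(seq_len(ncol(s$counts)),
                                   length(s$days)),
               count = as.vector(t(s$counts)),
               aliquot_ml = s$aliquot_ml, container_ml = s$container_ml)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$replicate), function(r) {
    days <- sort(unique(r$day))
    counts <- t(vapply(days, function(dy)
      r$count[r$day == dy][order(r$aliquot_index[r$day == dy])],
      numeric(sum(r$day == days[1]))))
    survival_series(replicate = r$replicate[1], treatment = r$treatment[1],
                    days = days, counts = counts,
                    aliquot_ml = r$aliquot_ml[1],
                    container_ml = r$container_ml[1])
  })
}

#' Write / read a trajectory set as CSV
#'
#' Long format (`id`, `release_time`, `cohort`, `site`, `depth`, `age`,
#' `lon`, `lat`) with the run provenance (lifetime, dt, output interval,
#' seed, grid axes) stored as a JSON header comment on the first line.
#'
#' @param traj A `trajectory_set`.
#' @param path CSV file path.
#' @return `write_trajectories_csv` returns `path` invisibly;
#'   `read_trajectories_csv` returns the reconstructed `trajectory_set`.
#' @export
write_trajectories_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  hdr <- jsonlite::toJSON(list(lifetime = traj$lifetime, dt = traj$dt,
                               output_interval = traj$output_interval,
                               seed = traj$seed, age = traj$age,
                               grid = traj$grid,
                               field_recipe = traj$field_recipe,
                               meta = traj$meta),
                          auto_unbox = TRUE, digits = NA)
  n_samp <- length(traj$age)
  rows <- data.frame(id = rep(traj$meta$id, n_samp),
                     age = rep(traj$age, each = nrow(traj$meta)),
                     lon = as.vector(traj$lon), lat = as.vector(traj$lat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  stopifnot(startsWith(hdr, "# "))
  prov <- jsonlite::fromJSON(substring(hdr, 3))
  rows <- utils::read.csv(path, comment.char = "#")
  meta <- as.data.frame(prov$meta)
  n_samp <- length(prov$age)
  structure(list(lon = matrix(rows$lon, nrow(meta), n_samp),
                 lat = matrix(rows$lat, nrow(meta), n_samp),
                 age = as.numeric(prov$age), meta = meta,
                 lifetime = prov$lifetime, dt = prov$dt,
                 output_interval = prov$output_interval,
                 seed = prov$seed,
                 grid = list(lon = as.numeric(prov$grid$lon),
                             lat = as.numeric(prov$grid$lat)),
                 field_recipe = prov$field_recipe),
            class = "trajectory_set")
}

#' Write a mortality fit (or any summary list) as JSON
#'
#' @param x A `mortality_fit`, `scenario_comparison`, or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  if (inherits(x, "mortality_fit"))
    x <- list(m = x$m, ln_n0 = x$ln_n0, se_m = x$se_m,
              r_squared = x$r_squared, n = x$n, scope = x$scope,
              treatment = x$treatment)
  if (inherits(x, "scenario_comparison"))
    x <- list(metric = x$metric, scenarios = x$scenarios,
              n_pairs = x$n_pairs, ratio = x$ratio, t_stat = x$t_stat,
              df = x$df, p_value = x$p_value, transform = x$transform)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
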