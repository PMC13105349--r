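#' Build a shelf (settleable habitat) mask
#'
#' Marks the grid cells of a field that lie on the continental shelf —
#' ocean cells shallower than the isobath threshold — optionally restricted
#' to a named rectangular region. The 500 m isobath is the conventional
#' shelf-edge delimiter for settleable habitat.
#'
#' @param field A `gridded_field`.
#' @param region Optional list with `lon` and `lat` length-2 bounds
#'   restricting the mask.
#' @param name Region name carried in outputs.
#' @param isobath_m Shelf-edge depth threshold in metres (default 500).
#' @return An object of class `shelf_mask`: logical matrix `mask` aligned to
#'   the field grid, the grid axes, per-cell areas (km^2), and the region
#'   name.
#' @export
shelf_mask <- function(field, region = NULL, name = "shelf",
                       isobath_m = 500) {
  stopifnot(inherits(field, "gridded_field"), isobath_m > 0)
  mask <- !field$land & !is.na(field$depth) & field$depth < isobath_m
  if (!is.null(region)) {
    inlon <- field$lon >= region$lon[1] & field$lon <= region$lon[2]
    inlat <- field$lat >= region$lat[1] & field$lat <= region$lat[2]
    mask <- mask & outer(inlon, inlat)
  }
  structure(list(mask = mask, lon = field$lon, lat = field$lat,
                 cell_area = cell_area_km2(field), name = name,
                 isobath_m = isobath_m),
            class = "shelf_mask")
}

#' Rectangular region mask on a field grid
#'
#' A plain geographic region (all ocean cells in a box), for first-arrival
#' queries against islands or target areas rather than settleable shelf.
#'
#' @inheritParams shelf_mask
#' @return A `shelf_mask`-classed object whose cells are the ocean cells of
#'   the box (no isobath restriction).
#' @export
region_mask <- function(field, region, name = "region") {
  stopifnot(inherits(field, "gridded_field"))
  inlon <- field$lon >= region$lon[1] & field$lon <= region$lon[2]
  inlat <- field$lat >= region$lat[1] & field$lat <= region$lat[2]
  mask <- !field$land & outer(inlon, inlat)
  structure(list(mask = mask, lon = field$lon, lat = field$lat,
                 cell_area = cell_area_km2(field), name = name,
                 isobath_m = Inf),
            class = "shelf_mask")
}

#' @export
print.shelf_mask <- function(x, ...) {
  cat(sprintf("Mask '%s': %d cells (isobath %g m), area %.0f km^2\n",
              x$name, sum(x$mask), x$isobath_m,
              sum(x$cell_area[x$mask])))
  invisible(x)
}

.check_grid_match <- function(traj, mask) {
  if (!isTRUE(all.equal(traj$grid$lon, mask$lon)) ||
      !isTRUE(all.equal(traj$grid$lat, mask$lat)))
    stop("trajectory set and mask are on different grids")
}

#' Detect settlement on a shelf mask
#'
#' A particle settles at its first trajectory sample over a masked cell with
#' age strictly greater than `min_age` (the minimum competency age; contacts
#' at or before it are ignored) and at most `lifetime`. Settlement is
#' terminal: later shelf contacts of a settled particle are not recorded.
#' Applying a `lifetime` shorter than the integrated trajectory length
#' evaluates the same trajectories under a shorter pelagic duration —
#' passive particles make this exactly equivalent to a shorter run, which is
#' what makes scenario comparisons paired.
#'
#' @param traj A `trajectory_set`.
#' @param mask A [shelf_mask()] on the same grid.
#' @param min_age Minimum competency age in days (default 25); settlement
#'   requires age > `min_age`.
#' @param lifetime Maximum age considered (defaults to the trajectory
#'   lifetime).
#' @param scenario Label attached to the records.
#' @return Data frame of settlement records: `id`, `settle_age`,
#'   `settle_lon`, `settle_lat`, `cell_i`, `cell_j`, `displacement_km`
#'   (great-circle, release to settlement), `cohort`, `scenario`.
#' @export
detect_settlement <- function(traj, mask, min_age = 25,
                              lifetime = traj$lifetime,
                              scenario = "scenario") {
  stopifnot(inherits(traj, "trajectory_set"), inherits(mask, "shelf_mask"),
            lifetime > min_age)
  .check_grid_match(traj, mask)
  eligible <- which(traj$age > min_age & traj$age <= lifetime)
  np <- nrow(traj$meta)
  nx <- length(mask$lon); ny <- length(mask$lat)
  dx <- mask$lon[2] - mask$lon[1]; dy <- mask$lat[2] - mask$lat[1]
  settle_col <- rep(NA_integer_, np)
  settle_i <- rep(NA_integer_, np); settle_j <- rep(NA_integer_, np)
  for (col in eligible) {           # columns are in increasing-age order
    open <- is.na(settle_col)
    if (!any(open)) break
    lon <- traj$lon[, col]; lat <- traj$lat[, col]
    i <- as.integer(round((lon - mask$lon[1]) / dx)) + 1L
    j <- as.integer(round((lat - mask$lat[1]) / dy)) + 1L
    ok <- !is.na(i) & i >= 1L & i <= nx & j >= 1L & j <= ny
    hit <- ok & mask$mask[cbind(pmax(i, 1L), pmax(j, 1L))]
    hit[is.na(hit)] <- FALSE
    newly <- which(hit & open)
    settle_col[newly] <- col
    settle_i[newly] <- i[newly]; settle_j[newly] <- j[newly]
  }
  p <- which(!is.na(settle_col))
  out <- data.frame(
    id = traj$meta$id[p],
    settle_age = traj$age[settle_col[p]],
    settle_lon = traj$lon[cbind(p, settle_col[p])],
    settle_lat = traj$lat[cbind(p, settle_col[p])],
    cell_i = settle_i[p], cell_j = settle_j[p],
    displacement_km = if (length(p))
      gc_distance_km(traj$meta$lon0[p], traj$meta$lat0[p],
                     traj$lon[cbind(p, settle_col[p])],
                     traj$lat[cbind(p, settle_col[p])]) else numeric(),
    cohort = traj$meta$cohort[p],
    scenario = if (length(p)) scenario else character())
  rownames(out) <- NULL
  out
}

#' Per-cohort settlement metrics
#'
#' Summarises settlement records into the three dispersal metrics compared
#' between scenarios: settled abundance, mean great-circle displacement from
#' release to settlement, and settled area (distinct occupied mask cells
#' times cell area).
#'
#' @param records Settlement records from [detect_settlement()].
#' @param released_per_cohort Named vector (or data frame with columns
#'   `cohort`, `n_released`) of particles released per cohort.
#' @param mask The [shelf_mask()] used for detection (provides cell areas).
#' @return Data frame with one row per cohort (and scenario): `cohort`,
#'   `scenario`, `n_settled`, `mean_displacement_km`, `settled_area_km2`,
#'   `n_released`, and `empty` flag for zero-settlement cohorts.
#' @export
cohort_metrics <- function(records, released_per_cohort, mask) {
  stopifnot(inherits(mask, "shelf_mask"))
  if (is.data.frame(released_per_cohort)) {
    rel <- stats::setNames(released_per_cohort$n_released,
                           released_per_cohort$cohort)
  } else rel <- released_per_cohort
  scen <- if (nrow(records)) unique(records$scenario) else "scenario"
  out <- lapply(scen, function(sc) {
    rs <- records[records$scenario == sc, , drop = FALSE]
    do.call(rbind, lapply(names(rel), function(co) {
      r <- rs[rs$cohort == as.numeric(co), , drop = FALSE]
      if (nrow(r) == 0) {
        data.frame(cohort = as.numeric(co), scenario = sc, n_settled = 0L,
                   mean_displacement_km = 0, settled_area_km2 = 0,
                   n_released = unname(rel[co]), empty = TRUE)
      } else {
        cells <- unique(r[, c("cell_i", "cell_j")])
        data.frame(cohort = as.numeric(co), scenario = sc,
                   n_settled = nrow(r),
                   mean_displacement_km = mean(r$displacement_km),
                   settled_area_km2 =
                     sum(mask$cell_area[as.matrix(cells)]),
                   n_released = unname(rel[co]), empty = FALSE)
      }
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Day of first arrival in a region
#'
#' The minimum particle age at which any trajectory sample falls inside the
#' region mask; `Inf` if the region is never visited.
#'
#' @param traj A `trajectory_set`.
#' @param mask A [region_mask()] or [shelf_mask()] on the same grid.
#' @param min_age Ignore samples at or before this age (default 0).
#' @return First-arrival age in days, or `Inf`.
#' @export
first_arrival <- function(traj, mask, min_age = 0) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(mask, "shelf_mask"))
  .check_grid_match(traj, mask)
  nx <- length(mask$lon); ny <- length(mask$lat)
  dx <- mask$lon[2] - mask$lon[1]; dy <- mask$lat[2] - mask$lat[1]
  for (col in which(traj$age > min_age)) {
    lon <- traj$lon[, col]; lat <- traj$lat[, col]
    i <- as.integer(round((lon - mask$lon[1]) / dx)) + 1L
    j <- as.integer(round((lat - mask$lat[1]) / dy)) + 1L
    ok <- !is.na(i) & i >= 1L & i <= nx & j >= 1L & j <= ny
    hit <- ok & mask$mask[cbind(pmax(i, 1L), pmax(j, 1L))]
    if (any(hit, na.rm = TRUE)) return(traj$age[col])
  }
  Inf
}

#' Arrival time as a multiple of the pelagic larval duration
#'
#' How many lifetimes a passive particle needs to reach a region: the
#' first-arrival day divided by the clutch-exhaustion pelagic larval
#' duration, reported to one decimal. Values above 1 mean a single
#' generation cannot make the crossing.
#'
#' @param arrival_day First-detection day.
#' @param pld Pelagic larval duration in days (positive).
#' @return Ratio rounded to one decimal.
#' @export
#' @examples
#' arrival_ratio(366, 181)  # Azores-type crossing: 2 lifetimes
arrival_ratio <- function(arrival_day, pld) {
  stopifnot(pld > 0)
  round(arrival_day / pld, 1)
}
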