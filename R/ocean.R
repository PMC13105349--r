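#' Specify a synthetic ocean
#'
#' Describes the domain, grid, time sampling, flow recipe, and coastline/shelf
#' geometry of an idealized ocean. Flow recipes are built from stream
#' functions in a local tangent plane anchored at the domain's reference
#' latitude, so every recipe is divergence-free by construction and has
#' closed-form trajectories that serve as oracles for the advection kernel.
#'
#' Available recipes:
#' \describe{
#'   \item{`uniform`}{constant flow; params `u0`, `v0` (m/s).}
#'   \item{`solid_body`}{rotation about `center = c(lon, lat)` with angular
#'     speed `omega` (radians/day). The zonal component carries a
#'     cos(lat)/cos(lat_ref) factor so trajectories are exact circles in
#'     tangent-plane coordinates.}
#'   \item{`double_gyre`}{the classic two-gyre benchmark stream function on
#'     the domain rectangle; params `A` (velocity scale, m/s), `eps`
#'     (gyre-boundary oscillation amplitude), `period` (days).}
#'   \item{`coastal_jet_with_eddies`}{an alongshore (southward for
#'     `v_jet > 0`) Gaussian jet whose axis meanders on- and off-shelf, an
#'     optional ocean-crossing zonal current, and an optional propagating
#'     eddy field; see parameter list below.}
#' }
#'
#' Jet parameters (km unless noted): `v_jet` peak speed m/s (positive =
#' southward), `jet_offset_km` distance of the mean jet axis offshore of the
#' coast, `jet_width_km`, `meander_amp_km`, `meander_wavelength_km`,
#' `meander_speed_kmday` phase propagation, `u_cross` westward crossing
#' current peak m/s, `cross_lat` its centre latitude, `cross_width_km`,
#' `eddy_speed` m/s, `eddy_wavelength_km`, `eddy_period_days`.
#'
#' @param lon,lat Numeric length-2 domain bounds in degrees.
#' @param dx,dy Grid spacing in degrees.
#' @param days Time span of the field in days.
#' @param interval Field snapshot interval in days (default 1, mirroring
#'   daily-mean model output).
#' @param recipe One of `"uniform"`, `"solid_body"`, `"double_gyre"`,
#'   `"coastal_jet_with_eddies"`.
#' @param params Named list of recipe parameters (see Details).
#' @param coast_lon Longitude of a meridional coastline; cells east of it are
#'   land. `NULL` for an all-ocean domain.
#' @param shelf_width_km Width of the continental shelf strip (depth < 500 m)
#'   seaward of the coastline.
#' @param deep_depth Open-ocean depth in metres (default 4000).
#' @param seed Integer seed recorded with the field (used only by recipes
#'   with randomized phases).
#' @return An object of class `ocean_spec`.
#' @seealso [make_ocean()]
#' @export
ocean_spec <- function(lon = c(-30, -10), lat = c(10, 30), dx = 0.5, dy = 0.5,
                       days = 30, interval = 1,
                       recipe = c("uniform", "solid_body", "double_gyre",
                                  "coastal_jet_with_eddies"),
                       params = list(), coast_lon = NULL,
                       shelf_width_km = 100, deep_depth = 4000, seed = 1L) {
  recipe <- match.arg(recipe)
  stopifnot(length(lon) == 2, length(lat) == 2, lon[1] < lon[2],
            lat[1] < lat[2], dx > 0, dy > 0, days >= 0, interval > 0,
            shelf_width_km > 0, deep_depth >= 500)
  defaults <- switch(recipe,
    uniform = list(u0 = 0.1, v0 = 0),
    solid_body = list(omega = 2 * pi / 30,
                      center = c(mean(lon), mean(lat))),
    double_gyre = list(A = 0.1, eps = 0.1, period = 10),
    coastal_jet_with_eddies = list(
      v_jet = 0.3, jet_offset_km = 60, jet_width_km = 80,
      meander_amp_km = 80, meander_wavelength_km = 400,
      meander_speed_kmday = 0, u_cross = 0, cross_lat = mean(lat),
      cross_width_km = 150, eddy_speed = 0, eddy_wavelength_km = 300,
      eddy_period_days = 30))
  params <- utils::modifyList(defaults, params)
  structure(list(lon = lon, lat = lat, dx = dx, dy = dy, days = days,
                 interval = interval, recipe = recipe, params = params,
                 coast_lon = coast_lon, shelf_width_km = shelf_width_km,
                 deep_depth = deep_depth, seed = as.integer(seed)),
            class = "ocean_spec")
}

# Tangent-plane coordinates (metres) about the spec's reference point.
.tangent_xy <- function(lon, lat, lon_ref, lat_ref) {
  list(x = (lon - lon_ref) * .M_PER_DEG * cos(lat_ref * pi / 180),
       y = (lat - lat_ref) * .M_PER_DEG)
}

# Closed-form velocity (m/s) for a recipe; returns function(lon, lat, t)
# vectorized over positions with scalar t.
.recipe_velocity <- function(spec) {
  p <- spec$params
  lon_ref <- mean(spec$lon)
  lat_ref <- mean(spec$lat)
  cos_ref <- cos(lat_ref * pi / 180)
  switch(spec$recipe,
    uniform = function(lon, lat, t) {
      n <- length(lon)
      list(u = rep(p$u0, n), v = rep(p$v0, n))
    },
    solid_body = function(lon, lat, t) {
      # exact circles in the tangent plane anchored at the rotation centre:
      # the cos(lat)/cos(lat_c) factor on u compensates the spherical metric
      xy <- .tangent_xy(lon, lat, p$center[1], p$center[2])
      om <- p$omega / .SEC_PER_DAY          # rad/s
      cos_c <- cos(p$center[2] * pi / 180)
      list(u = -om * xy$y * cos(lat * pi / 180) / cos_c,
           v = om * xy$x)
    },
    double_gyre = function(lon, lat, t) {
      Lx <- diff(spec$lon) * .M_PER_DEG * cos_ref
      Ly <- diff(spec$lat) * .M_PER_DEG
      X <- 2 * (lon - spec$lon[1]) / diff(spec$lon)   # [0, 2]
      Y <- (lat - spec$lat[1]) / diff(spec$lat)       # [0, 1]
      a <- p$eps * sin(2 * pi * t / p$period)
      b <- 1 - 2 * a
      f <- a * X^2 + b * X
      fx <- 2 * a * X + b
      A_psi <- p$A * Ly / pi                          # m^2/s
      list(u = -pi * A_psi / Ly * sin(pi * f) * cos(pi * Y),
           v = pi * A_psi * (2 / Lx) * cos(pi * f) * fx * sin(pi * Y))
    },
    coastal_jet_with_eddies = function(lon, lat, t) {
      coast_lon <- if (is.null(spec$coast_lon)) spec$lon[2] else spec$coast_lon
      xy <- .tangent_xy(lon, lat, coast_lon, lat_ref)
      x <- xy$x; y <- xy$y
      km <- 1000
      w <- p$jet_width_km * km
      k <- 2 * pi / (p$meander_wavelength_km * km)
      phase <- k * (y - p$meander_speed_kmday * km * t)
      xj <- -p$jet_offset_km * km + p$meander_amp_km * km * sin(phase)
      s <- (x - xj) / w
      g <- exp(-s^2)
      u <- -p$v_jet * g * p$meander_amp_km * km * k * cos(phase)
      v <- -p$v_jet * g
      if (p$u_cross != 0) {
        yb <- (p$cross_lat - lat_ref) * .M_PER_DEG
        u <- u - p$u_cross * exp(-((y - yb) / (p$cross_width_km * km))^2)
      }
      if (p$eddy_speed != 0) {
        ke <- 2 * pi / (p$eddy_wavelength_km * km)
        sig <- 2 * pi / p$eddy_period_days * t
        amp <- p$eddy_speed
        u <- u - amp * sin(ke * x) * cos(ke * y - sig)
        v <- v + amp * cos(ke * x) * sin(ke * y - sig)
      }
      list(u = u, v = v)
    })
}

#' Synthesize a gridded ocean velocity field
#'
#' Samples the analytic flow recipe of an [ocean_spec()] at the grid nodes and
#' snapshot times, and derives the land mask, bathymetry, and shelf strip from
#' the coastline geometry. Velocities are undefined (`NA`) on land nodes.
#' Bathymetry shoals linearly from the 500 m isobath at the shelf edge to the
#' coast, so the shelf strip is exactly the set of ocean cells with depth
#' below 500 m.
#'
#' @param spec An [ocean_spec()].
#' @return An object of class `gridded_field`: a list with strictly
#'   increasing axes `lon`, `lat`, `time`, velocity arrays `u`, `v`
#'   (lon x lat x time, m/s), `depth` (m, positive down, `NA` on land),
#'   logical `land` matrix, and provenance (`recipe`, `params`, `seed`).
#' @export
#' @examples
#' f <- make_ocean(ocean_spec(recipe = "uniform", days = 5))
#' f
make_ocean <- function(spec) {
  stopifnot(inherits(spec, "ocean_spec"))
  lon <- seq(spec$lon[1], spec$lon[2], by = spec$dx)
  lat <- seq(spec$lat[1], spec$lat[2], by = spec$dy)
  if (length(lon) < 2 || length(lat) < 2)
    stop("degenerate grid: need at least 2 nodes per axis")
  time <- seq(0, spec$days, by = spec$interval)
  lat_ref <- mean(spec$lat)

  # land mask and bathymetry from the meridional coastline
  land <- matrix(FALSE, length(lon), length(lat))
  if (!is.null(spec$coast_lon)) {
    land <- matrix(lon > spec$coast_lon, length(lon), length(lat))
    dist_km <- outer(lon, lat, function(lo, la)
      (spec$coast_lon - lo) * .M_PER_DEG * cos(lat_ref * pi / 180) / 1000)
    depth <- ifelse(dist_km < spec$shelf_width_km,
                    pmax(1, 500 * dist_km / spec$shelf_width_km),
                    pmin(spec$deep_depth,
                         500 + (dist_km - spec$shelf_width_km) * 20))
    depth[land] <- NA_real_
  } else {
    depth <- matrix(spec$deep_depth, length(lon), length(lat))
  }

  vel <- .recipe_velocity(spec)
  grid <- expand.grid(lon = lon, lat = lat)
  u <- array(NA_real_, c(length(lon), length(lat), length(time)))
  v <- u
  for (k in seq_along(time)) {
    uv <- vel(grid$lon, grid$lat, time[k])
    uk <- matrix(uv$u, length(lon), length(lat))
    vk <- matrix(uv$v, length(lon), length(lat))
    uk[land] <- NA_real_
    vk[land] <- NA_real_
    u[, , k] <- uk
    v[, , k] <- vk
  }

  structure(list(lon = lon, lat = lat, time = time, u = u, v = v,
                 depth = depth, land = land, recipe = spec$recipe,
                 params = spec$params, coast_lon = spec$coast_lon,
                 shelf_width_km = spec$shelf_width_km,
                 lat_ref = lat_ref, seed = spec$seed),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat("Gridded ocean field (", x$recipe, ")\n", sep = "")
  cat(sprintf("  lon: [%g, %g] x %d  lat: [%g, %g] x %d\n",
              min(x$lon), max(x$lon), length(x$lon),
              min(x$lat), max(x$lat), length(x$lat)))
  cat(sprintf("  time: %g..%g days, %d snapshots\n",
              min(x$time), max(x$time), length(x$time)))
  cat(sprintf("  land cells: %d / %d\n", sum(x$land), length(x$land)))
  invisible(x)
}

#' Cell areas of a gridded field
#'
#' Area of each grid cell in km^2, using the spherical metric
#' \eqn{R^2 \cos\phi \, d\lambda \, d\phi}.
#'
#' @param field A `gridded_field`.
#' @return Matrix (lon x lat) of areas in km^2.
#' @export
cell_area_km2 <- function(field) {
  dx <- diff(field$lon[1:2])
  dy <- diff(field$lat[1:2])
  a <- (dx * .M_PER_DEG / 1000) * (dy * .M_PER_DEG / 1000)
  outer(rep(a, length(field$lon)), cos(field$lat * pi / 180))
}
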