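# Shared fixtures: small analytic fields and hand-built trajectory sets.

uniform_field <- function(u0 = 0.1, v0 = 0, days = 10, dx = 0.5,
                          lon = c(-30, -10), lat = c(10, 30),
                          coast_lon = NULL, shelf_width_km = 100) {
  make_ocean(ocean_spec(lon = lon, lat = lat, dx = dx, dy = dx, days = days,
                        recipe = "uniform", params = list(u0 = u0, v0 = v0),
                        coast_lon = coast_lon,
                        shelf_width_km = shelf_width_km))
}

solid_field <- function(omega = 2 * pi / 30, center = c(-20, 20),
                        dx = 0.25, days = 40) {
  make_ocean(ocean_spec(lon = c(-25, -15), lat = c(15, 25), dx = dx, dy = dx,
                        days = days, recipe = "solid_body",
                        params = list(omega = omega, center = center)))
}

# Meandering southward coastal jet against an eastern coastline; the meander
# swings streamlines on and off the shelf, so settlement ages spread widely.
jet_field <- function(v_jet = 0.4, meander_amp_km = 150,
                      meander_wavelength_km = 600, days = 1) {
  make_ocean(ocean_spec(
    lon = c(-30, -14), lat = c(0, 30), dx = 0.5, dy = 0.5, days = days,
    recipe = "coastal_jet_with_eddies",
    params = list(v_jet = v_jet, jet_offset_km = 120, jet_width_km = 100,
                  meander_amp_km = meander_amp_km,
                  meander_wavelength_km = meander_wavelength_km),
    coast_lon = -15, shelf_width_km = 120))
}

# Hand-built trajectory set on a given field grid: positions is a list of
# per-particle matrices (n_samples x 2, columns lon/lat) sharing `ages`.
manual_traj <- function(field, positions, ages, lifetime = max(ages),
                        cohort = 0) {
  np <- length(positions)
  lon <- t(vapply(positions, function(p) p[, 1], numeric(length(ages))))
  lat <- t(vapply(positions, function(p) p[, 2], numeric(length(ages))))
  if (length(ages) == 1) { lon <- matrix(lon, np, 1); lat <- matrix(lat, np, 1) }
  meta <- data.frame(id = seq_len(np),
                     release_time = 0, cohort = cohort, site = 1,
                     depth = 15,
                     lon0 = lon[, 1], lat0 = lat[, 1],
                     stranded_steps = 0L, status = "expired")
  structure(list(lon = lon, lat = lat, age = ages, meta = meta,
                 lifetime = lifetime, dt = ages[2] - ages[1],
                 output_interval = if (length(ages) > 1) ages[2] - ages[1] else 1,
                 seed = 0L, grid = list(lon = field$lon, lat = field$lat),
                 field_recipe = field$recipe),
            class = "trajectory_set")
}

# Independent haversine implementation (oracle for distance assertions).
haversine_km_oracle <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to <- pi / 180
  dlat <- (lat2 - lat1) * to
  dlon <- (lon2 - lon1) * to
  a <- sin(dlat / 2)^2 + cos(lat1 * to) * cos(lat2 * to) * sin(dlon / 2)^2
  2 * r * asin(sqrt(a))
}
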