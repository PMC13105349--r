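#' Sample a gridded velocity field at arbitrary points
#'
#' Bilinear interpolation in longitude/latitude between the four surrounding
#' grid nodes, linear in time between the bracketing snapshots. Land nodes
#' (velocity `NA`) are excluded from the stencil and the remaining weights
#' renormalized, so near-coast queries use only ocean information. Queries
#' outside the domain, or whose four stencil nodes are all land, return `NA`.
#' Times outside the field's span are clamped to the nearest snapshot.
#'
#' @param field A `gridded_field` from [make_ocean()] or [read_field_json()].
#' @param lon,lat Query coordinates (degrees); vectorized.
#' @param t Query time (days); scalar.
#' @return List with numeric vectors `u` and `v` (m/s).
#' @export
sample_velocity <- function(field, lon, lat, t) {
  nx <- length(field$lon); ny <- length(field$lat)
  nt <- length(field$time)
  # time bracketing (clamped)
  tt <- min(max(t, field$time[1]), field$time[nt])
  kt <- findInterval(tt, field$time)
  if (kt >= nt) { kt <- nt; wt <- 0 } else {
    wt <- (tt - field$time[kt]) / (field$time[kt + 1] - field$time[kt])
  }
  u2 <- if (wt > 0) (1 - wt) * field$u[, , kt] + wt * field$u[, , kt + 1]
        else field$u[, , kt]
  v2 <- if (wt > 0) (1 - wt) * field$v[, , kt] + wt * field$v[, , kt + 1]
        else field$v[, , kt]

  n <- length(lon)
  inside <- lon >= field$lon[1] & lon <= field$lon[nx] &
            lat >= field$lat[1] & lat <= field$lat[ny] &
            !is.na(lon) & !is.na(lat)
  i <- pmin(pmax(findInterval(lon, field$lon), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(lat, field$lat), 1L), ny - 1L)
  wx <- (lon - field$lon[i]) / (field$lon[i + 1] - field$lon[i])
  wy <- (lat - field$lat[j]) / (field$lat[j + 1] - field$lat[j])

  idx <- function(ii, jj) (jj - 1L) * nx + ii
  c00 <- idx(i, j); c10 <- idx(i + 1L, j)
  c01 <- idx(i, j + 1L); c11 <- idx(i + 1L, j + 1L)
  W <- cbind((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy)
  U <- cbind(u2[c00], u2[c10], u2[c01], u2[c11])
  V <- cbind(v2[c00], v2[c10], v2[c01], v2[c11])
  W[is.na(U)] <- 0
  U[is.na(U)] <- 0
  V[is.na(V)] <- 0
  tot <- rowSums(W)
  ok <- inside & tot > 0
  u <- ifelse(ok, rowSums(W * U) / tot, NA_real_)
  v <- ifelse(ok, rowSums(W * V) / tot, NA_real_)
  list(u = u, v = v)
}

# Position tendency in degrees/day under the spherical metric; NA velocities
# (sampling failures) contribute zero motion.
.deriv_deg <- function(field, lon, lat, t) {
  uv <- sample_velocity(field, lon, lat, t)
  u <- ifelse(is.na(uv$u), 0, uv$u)
  v <- ifelse(is.na(uv$v), 0, uv$v)
  list(dlon = u * .SEC_PER_DAY / (.M_PER_DEG * cos(lat * pi / 180)),
       dlat = v * .SEC_PER_DAY / .M_PER_DEG)
}

#' One classical Runge--Kutta advection step
#'
#' Advances particle positions through the velocity field with the classical
#' four-stage Runge--Kutta scheme. Velocities (m/s) are converted to degrees
#' per day using the Earth radius, with the zonal term divided by
#' cos(latitude). The step proposes new positions only; land/domain handling
#' is a separate concern ([apply_boundary()]).
#'
#' @param field A `gridded_field`.
#' @param lon,lat Current positions (degrees); vectorized.
#' @param t Current time (days).
#' @param dt Step length (days).
#' @return List with proposed `lon` and `lat`.
#' @export
step_rk4 <- function(field, lon, lat, t, dt) {
  k1 <- .deriv_deg(field, lon, lat, t)
  k2 <- .deriv_deg(field, lon + dt / 2 * k1$dlon, lat + dt / 2 * k1$dlat,
                   t + dt / 2)
  k3 <- .deriv_deg(field, lon + dt / 2 * k2$dlon, lat + dt / 2 * k2$dlat,
                   t + dt / 2)
  k4 <- .deriv_deg(field, lon + dt * k3$dlon, lat + dt * k3$dlat, t + dt)
  list(lon = lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
       lat = lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat))
}

# Nearest-node cell indices for positions; NA when outside the domain.
.cell_index <- function(field, lon, lat) {
  dx <- field$lon[2] - field$lon[1]
  dy <- field$lat[2] - field$lat[1]
  i <- as.integer(round((lon - field$lon[1]) / dx)) + 1L
  j <- as.integer(round((lat - field$lat[1]) / dy)) + 1L
  bad <- i < 1L | i > length(field$lon) | j < 1L | j > length(field$lat)
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  list(i = i, j = j)
}

#' Anti-beaching boundary policy
#'
#' If a proposed position falls on a land cell or outside the domain, the
#' particle keeps its previous position for this step and is flagged as a
#' stranding candidate. Stranding never terminates a particle — settlement is
#' decided solely by the settlement rules.
#'
#' @param field A `gridded_field`.
#' @param lon,lat Proposed positions.
#' @param lon_prev,lat_prev Positions before the step.
#' @return List with accepted `lon`, `lat`, and logical `stranded` flags.
#' @export
apply_boundary <- function(field, lon, lat, lon_prev, lat_prev) {
  cidx <- .cell_index(field, lon, lat)
  on_land <- is.na(cidx$i) |
    field$land[cbind(pmax(cidx$i, 1L), pmax(cidx$j, 1L))]
  on_land[is.na(on_land)] <- TRUE
  list(lon = ifelse(on_land, lon_prev, lon),
       lat = ifelse(on_land, lat_prev, lat),
       stranded = on_land)
}

#' Define a particle release schedule
#'
#' Release sites with a per-event particle budget, repeated at a fixed
#' interval. The budget of each event is split across sites by a
#' deterministic largest-remainder rule (equal weights unless `sites` has an
#' `n` column of per-site weights). Particles are jittered uniformly within
#' `jitter_deg` of their site and assigned a uniform release depth, both
#' drawn from the run seed; depth is carried as metadata (advection is
#' single-layer).
#'
#' @param sites Data frame with columns `lon`, `lat` (degrees) and optional
#'   `n` (per-site weights).
#' @param n_per_event Particles released per event.
#' @param interval Days between release events (default 7, i.e. weekly).
#' @param n_events Number of release events.
#' @param start Time of the first event (days).
#' @param times Explicit release times; overrides `interval`/`n_events`.
#' @param depth_range Release depth range in metres (default 0--30).
#' @param jitter_deg Half-width of the uniform within-cell release jitter
#'   (degrees).
#' @param cohort_length Days per annual cohort (default 365); cohort year is
#'   `floor(release_time / cohort_length)`.
#' @return An object of class `release_schedule`.
#' @export
release_schedule <- function(sites, n_per_event = 100, interval = 7,
                             n_events = 1, start = 0, times = NULL,
                             depth_range = c(0, 30), jitter_deg = 0,
                             cohort_length = 365) {
  stopifnot(is.data.frame(sites), all(c("lon", "lat") %in% names(sites)),
            nrow(sites) >= 1, n_per_event >= 1, interval > 0,
            cohort_length > 0)
  if (is.null(times)) times <- start + interval * (seq_len(n_events) - 1)
  structure(list(sites = sites, n_per_event = as.integer(n_per_event),
                 times = times, depth_range = depth_range,
                 jitter_deg = jitter_deg, cohort_length = cohort_length),
            class = "release_schedule")
}

#' Largest-remainder apportionment
#'
#' Splits an integer budget across categories proportionally to weights,
#' assigning leftover units by decreasing fractional remainder with ties
#' broken by category order.
#'
#' @param n Integer budget.
#' @param weights Non-negative weights (at least one positive).
#' @return Integer vector summing to `n`.
#' @export
#' @examples
#' apportion(100, rep(1, 3))  # 34 33 33
apportion <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Advect a release schedule through a field
#'
#' Releases particles per the schedule and integrates each with
#' [step_rk4()] + [apply_boundary()] until its age exceeds `lifetime`.
#' Positions are sampled at `output_interval` (which must divide evenly into
#' steps of `dt`) from release (age 0) to age `lifetime`. The run is
#' bit-reproducible for identical (field, schedule, seed, dt), and the
#' random draws (jitter, depths) do not depend on `lifetime`, so runs that
#' differ only in lifetime are exactly paired.
#'
#' @param schedule A [release_schedule()].
#' @param field A `gridded_field`.
#' @param lifetime Maximum particle age in days.
#' @param dt Integration step (days); default 1/12 day (2 h).
#' @param output_interval Trajectory sampling interval (days).
#' @param seed Integer seed for release jitter and depths.
#' @return An object of class `trajectory_set`: positions `lon`, `lat`
#'   (particle x sample matrices), sample `age` vector, particle metadata
#'   data frame `meta` (release time, cohort, site, release position, depth,
#'   stranded step count), and run provenance.
#' @export
run_release <- function(schedule, field, lifetime, dt = 1 / 12,
                        output_interval = 1, seed = 1L) {
  stopifnot(inherits(schedule, "release_schedule"),
            inherits(field, "gridded_field"), lifetime >= 0, dt > 0)
  steps_per_out <- output_interval / dt
  if (abs(steps_per_out - round(steps_per_out)) > 1e-8)
    stop("output_interval must be an integer multiple of dt")
  steps_per_out <- as.integer(round(steps_per_out))
  n_samp <- as.integer(floor(lifetime / output_interval + 1e-9)) + 1L
  ages <- output_interval * (seq_len(n_samp) - 1)

  per_site <- apportion(schedule$n_per_event,
                        if ("n" %in% names(schedule$sites))
                          schedule$sites$n else rep(1, nrow(schedule$sites)))
  site_of <- rep(seq_len(nrow(schedule$sites)), per_site)
  n_event <- length(site_of)
  n_total <- n_event * length(schedule$times)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # draws are per-particle and independent of lifetime (paired design)
  jit_lon <- stats::runif(n_total, -schedule$jitter_deg, schedule$jitter_deg)
  jit_lat <- stats::runif(n_total, -schedule$jitter_deg, schedule$jitter_deg)
  depths <- stats::runif(n_total, schedule$depth_range[1],
                         schedule$depth_range[2])

  meta <- data.frame(
    id = seq_len(n_total),
    release_time = rep(schedule$times, each = n_event),
    cohort = floor(rep(schedule$times, each = n_event) /
                     schedule$cohort_length),
    site = rep(site_of, length(schedule$times)),
    depth = depths)
  # jittered positions are clamped into the grid so edge-cell releases stay
  # inside the interpolation domain
  meta$lon0 <- pmin(pmax(schedule$sites$lon[meta$site] + jit_lon,
                         field$lon[1]), field$lon[length(field$lon)])
  meta$lat0 <- pmin(pmax(schedule$sites$lat[meta$site] + jit_lat,
                         field$lat[1]), field$lat[length(field$lat)])

  cidx <- .cell_index(field, meta$lon0, meta$lat0)
  bad <- is.na(cidx$i) | field$land[cbind(cidx$i, cidx$j)]
  if (any(bad))
    stop("release site(s) on land or outside the domain: particle(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))

  LON <- matrix(NA_real_, n_total, n_samp)
  LAT <- matrix(NA_real_, n_total, n_samp)
  stranded_steps <- integer(n_total)

  n_steps <- as.integer(round(lifetime / dt + 1e-9))
  for (ev in seq_along(schedule$times)) {
    rows <- which(meta$release_time == schedule$times[ev])
    lon <- meta$lon0[rows]; lat <- meta$lat0[rows]
    LON[rows, 1] <- lon; LAT[rows, 1] <- lat
    t0 <- schedule$times[ev]
    if (n_steps > 0) for (s in seq_len(n_steps)) {
      prop <- step_rk4(field, lon, lat, t0 + (s - 1) * dt, dt)
      acc <- apply_boundary(field, prop$lon, prop$lat, lon, lat)
      lon <- acc$lon; lat <- acc$lat
      stranded_steps[rows] <- stranded_steps[rows] + acc$stranded
      if (s %% steps_per_out == 0L) {
        col <- s %/% steps_per_out + 1L
        if (col <= n_samp) { LON[rows, col] <- lon; LAT[rows, col] <- lat }
      }
    }
  }
  meta$stranded_steps <- stranded_steps
  meta$status <- if (n_total > 0) "expired" else character(0)

  structure(list(lon = LON, lat = LAT, age = ages, meta = meta,
                 lifetime = lifetime, dt = dt,
                 output_interval = output_interval, seed = as.integer(seed),
                 grid = list(lon = field$lon, lat = field$lat),
                 field_recipe = field$recipe),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "Trajectory set: %d particles, %d samples (every %g d to age %g d)\n",
    nrow(x$meta), length(x$age), x$output_interval, x$lifetime))
  cat(sprintf("  %d release events, cohorts %s; dt = %g d, seed = %d\n",
              length(unique(x$meta$release_time)),
              paste(sort(unique(x$meta$cohort)), collapse = ","),
              x$dt, x$seed))
  invisible(x)
}

#' Particle status census at a simulation time
#'
#' Classifies every particle of a run at clock time `t`: `pending` (not yet
#' released), `active` (drifting), or `expired` (age exceeded the lifetime).
#' Settlement is a post-processing concept and not counted here.
#'
#' @param traj A `trajectory_set`.
#' @param t Simulation time in days.
#' @return Named integer vector with counts `pending`, `active`, `expired`.
#' @export
particle_status <- function(traj, t) {
  age <- t - traj$meta$release_time
  c(pending = sum(age < 0),
    active = sum(age >= 0 & age <= traj$lifetime),
    expired = sum(age > traj$lifetime))
}
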