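# Velocity interpolation, RK4 stepping, boundary policy, release bookkeeping.

test_that("interpolation reproduces node values and hand-computed midpoints", {
  f <- uniform_field(u0 = 0.1, v0 = 0.05)
  uv <- sample_velocity(f, c(-20, -17.3), c(20, 12.8), 0.5)
  expect_equal(uv$u, c(0.1, 0.1))
  expect_equal(uv$v, c(0.05, 0.05))

  # two-node hand case: u = 0 and 0.2 at adjacent nodes -> 0.1 at midpoint
  g <- uniform_field(u0 = 0, dx = 1, lon = c(0, 2), lat = c(0, 2))
  g$u[] <- 0
  g$u[2, 1, ] <- 0.2
  expect_equal(sample_velocity(g, 0.5, 0, 0)$u, 0.1)
  expect_equal(sample_velocity(g, 1, 0, 0)$u, 0.2)  # interpolation identity
  expect_equal(sample_velocity(g, 0.25, 0, 0)$u, 0.05)
})

test_that("land nodes are excluded from the stencil with renormalization", {
  g <- uniform_field(u0 = 0.3, dx = 1, lon = c(0, 2), lat = c(0, 2))
  g$land[1, 1] <- TRUE
  g$u[1, 1, ] <- NA; g$v[1, 1, ] <- NA
  # query near the land corner: remaining three ocean nodes all hold 0.3
  expect_equal(sample_velocity(g, 0.25, 0.25, 0)$u, 0.3)
  # all-land stencil and out-of-domain queries return NA
  g$land[, ] <- TRUE; g$u[] <- NA; g$v[] <- NA
  expect_true(is.na(sample_velocity(g, 0.5, 0.5, 0)$u))
  f <- uniform_field()
  expect_true(is.na(sample_velocity(f, -50, 20, 0)$u))
})

test_that("constant-field RK4 is exact: 8.64 km east per day at 0.1 m/s", {
  f <- uniform_field(u0 = 0.1, v0 = 0)
  p <- step_rk4(f, -20, 20, 0, 1)
  expect_equal(p$lat, 20)
  expect_equal(gc_distance_km(-20, 20, p$lon, p$lat), 8.64, tolerance = 1e-6)
  # zero field: no motion
  f0 <- uniform_field(u0 = 0, v0 = 0)
  p0 <- step_rk4(f0, -20, 20, 0, 1)
  expect_equal(c(p0$lon, p0$lat), c(-20, 20))
})

test_that("solid-body rotation returns to start after one period", {
  f <- solid_field(omega = 2 * pi / 30, center = c(-20, 20))
  lon <- -20; lat <- 21  # radius: 1 degree of latitude
  dt <- 0.05
  for (i in seq_len(30 / dt)) {
    p <- step_rk4(f, lon, lat, (i - 1) * dt, dt)
    lon <- p$lon; lat <- p$lat
  }
  err <- sqrt((cos(20 * pi / 180) * (lon + 20))^2 + (lat - 21)^2)
  expect_lt(err, 1e-3)  # within 1e-3 of the rotation radius (1 deg)
})

test_that("boundary policy reverts to the previous position and flags", {
  f <- jet_field()
  land_lon <- -14.5  # east of the coastline
  b <- apply_boundary(f, land_lon, 15, -16, 15)
  expect_equal(b$lon, -16)
  expect_true(b$stranded)
  ok <- apply_boundary(f, -20, 15, -16, 15)
  expect_equal(ok$lon, -20)
  expect_false(ok$stranded)
  # pinned at the coast for several proposals: position never moves
  pos <- c(-16, 15)
  for (k in 1:5) {
    b <- apply_boundary(f, -14.2, 15, pos[1], pos[2])
    pos <- c(b$lon, b$lat)
  }
  expect_equal(pos, c(-16, 15))
})

test_that("release bookkeeping: sample counts, expiry, conservation", {
  f <- uniform_field(u0 = 0.05)
  sch <- release_schedule(data.frame(lon = -20, lat = 20), n_per_event = 10,
                          n_events = 1)
  tr <- run_release(sch, f, lifetime = 3, dt = 0.25,
                    output_interval = 0.25, seed = 1)
  expect_equal(length(tr$age), 13)
  expect_equal(nrow(tr$meta), 10)
  expect_true(all(is.finite(tr$lon)))

  # lifetime zero: expire at release with zero displacement
  tr0 <- run_release(sch, f, lifetime = 0, dt = 0.25,
                     output_interval = 0.25, seed = 1)
  expect_equal(length(tr0$age), 1)
  expect_equal(tr0$lon[, 1], tr0$meta$lon0)
  expect_equal(unname(particle_status(tr0, 1)["expired"]), 10L)

  # status census conserves the released total at all times
  sch2 <- release_schedule(data.frame(lon = -20, lat = 20), n_per_event = 5,
                           n_events = 3, interval = 2)
  tr2 <- run_release(sch2, f, lifetime = 3, dt = 0.5, output_interval = 1,
                     seed = 2)
  for (t in c(0, 1, 2.5, 4, 10))
    expect_equal(sum(particle_status(tr2, t)), 15)
  # doubling the per-event budget exactly doubles the released count
  sch3 <- release_schedule(data.frame(lon = -20, lat = 20), n_per_event = 10,
                           n_events = 3, interval = 2)
  tr3 <- run_release(sch3, f, lifetime = 3, dt = 0.5, output_interval = 1,
                     seed = 2)
  expect_equal(nrow(tr3$meta), 2 * nrow(tr2$meta))
})

test_that("uniform flow moves every particle by u * lifetime", {
  f <- uniform_field(u0 = 0.2, v0 = 0)
  sch <- release_schedule(data.frame(lon = c(-25, -22), lat = c(18, 22)),
                          n_per_event = 6, n_events = 2, interval = 3,
                          jitter_deg = 0.2)
  tr <- run_release(sch, f, lifetime = 10, dt = 0.25, output_interval = 1,
                    seed = 5)
  last <- ncol(tr$lon)
  d <- gc_distance_km(tr$meta$lon0, tr$meta$lat0, tr$lon[, last],
                      tr$lat[, last])
  expect_equal(d, rep(0.2 * 86.4 * 10, nrow(tr$meta)), tolerance = 1e-4)
})

test_that("runs are bit-identical under a fixed seed and reject land sites", {
  f <- jet_field()
  sch <- release_schedule(data.frame(lon = -16, lat = 28), n_per_event = 8,
                          n_events = 2, interval = 7, jitter_deg = 0.25)
  a <- run_release(sch, f, lifetime = 10, dt = 0.25, output_interval = 1,
                   seed = 42)
  b <- run_release(sch, f, lifetime = 10, dt = 0.25, output_interval = 1,
                   seed = 42)
  expect_identical(a, b)
  c1 <- run_release(sch, f, lifetime = 10, dt = 0.25, output_interval = 1,
                    seed = 43)
  expect_false(identical(a$lon, c1$lon))
  land_sch <- release_schedule(data.frame(lon = -14.2, lat = 15),
                               n_per_event = 2, n_events = 1)
  expect_error(run_release(land_sch, f, lifetime = 5, dt = 0.25,
                           output_interval = 1), "land")
  expect_error(run_release(sch, f, lifetime = 5, dt = 0.3,
                           output_interval = 1), "multiple")
})

test_that("active particles never sit on land after the boundary step", {
  f <- jet_field()
  sch <- release_schedule(data.frame(lon = -15.6, lat = 28), n_per_event = 20,
                          n_events = 1, jitter_deg = 0.25)
  tr <- run_release(sch, f, lifetime = 40, dt = 0.25, output_interval = 1,
                    seed = 9)
  dx <- f$lon[2] - f$lon[1]
  for (col in seq_along(tr$age)) {
    i <- round((tr$lon[, col] - f$lon[1]) / dx) + 1
    j <- round((tr$lat[, col] - f$lat[1]) / dx) + 1
    expect_true(all(!f$land[cbind(i, j)]))
  }
})

test_that("largest-remainder apportionment is deterministic and exact", {
  expect_equal(apportion(100, rep(1, 10)), rep(10L, 10))
  expect_equal(apportion(100, rep(1, 3)), c(34L, 33L, 33L))
  expect_equal(sum(apportion(17, c(5, 1, 1, 3))), 17L)
  expect_equal(apportion(5, c(0, 1, 0)), c(0L, 5L, 0L))
})
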