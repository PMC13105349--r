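# Paired scenario experiments, scenario statistics, generation stepping.

test_that("identical lifetimes give identical metrics (paired-design sanity)", {
  f <- jet_field()
  msk <- shelf_mask(f, region = list(lon = c(-30, -14), lat = c(0, 20)))
  sch <- release_schedule(data.frame(lon = -16, lat = 28), n_per_event = 20,
                          n_events = 4, interval = 7, jitter_deg = 0.25,
                          cohort_length = 14)
  run <- run_scenarios(list(dispersal_scenario("a", 60),
                            dispersal_scenario("b", 60)),
                       f, sch, msk, dt = 0.25, seed = 3)
  ma <- run$metrics[run$metrics$scenario == "a",
                    c("cohort", "n_settled", "mean_displacement_km",
                      "settled_area_km2")]
  mb <- run$metrics[run$metrics$scenario == "b",
                    c("cohort", "n_settled", "mean_displacement_km",
                      "settled_area_km2")]
  expect_equal(ma, mb, ignore_attr = TRUE)
})

test_that("tiny run metrics equal a direct recomputation from the records", {
  f <- jet_field()
  msk <- shelf_mask(f, region = list(lon = c(-30, -14), lat = c(0, 20)))
  sch <- release_schedule(data.frame(lon = -16, lat = 28), n_per_event = 30,
                          n_events = 1, jitter_deg = 0.25)
  run <- run_scenarios(list(dispersal_scenario("light", 100)),
                       f, sch, msk, dt = 0.25, seed = 4)
  rec <- run$records
  m <- run$metrics
  expect_equal(m$n_settled, nrow(rec))
  if (nrow(rec) > 0) {
    expect_equal(m$mean_displacement_km, mean(rec$displacement_km))
    cells <- unique(rec[, c("cell_i", "cell_j")])
    expect_equal(m$settled_area_km2, sum(msk$cell_area[as.matrix(cells)]))
  }
  expect_equal(m$n_released, 30L)
})

test_that("paired t on log metrics matches the closed-form computation", {
  # hand-worked 5-pair example
  a <- c(120, 95, 150, 80, 140)
  b <- c(100, 90, 100, 70, 100)
  metrics <- data.frame(cohort = rep(1:5, 2),
                        scenario = rep(c("light", "dark"), each = 5),
                        mean_displacement_km = c(a, b))
  cmp <- compare_paired(metrics, "mean_displacement_km",
                        scenario_order = c("light", "dark"))
  d <- log(a) - log(b)
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(cmp$t_stat, t_oracle, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(cmp$df, 4L)
  expect_equal(cmp$ratio, exp(mean(d)), tolerance = 1e-12)
})

test_that("degenerate paired comparisons are flagged", {
  m_same <- data.frame(cohort = rep(1:3, 2),
                       scenario = rep(c("x", "y"), each = 3),
                       n_settled = rep(c(5, 8, 13), 2))
  cmp <- compare_paired(m_same, "n_settled")
  expect_equal(cmp$t_stat, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$ratio, 1)
  expect_true(cmp$zero_variance)
  # constant non-zero log difference: sd = 0, t undefined but ratio defined
  m_const <- data.frame(cohort = rep(1:3, 2),
                        scenario = rep(c("x", "y"), each = 3),
                        n_settled = c(10, 20, 40, 5, 10, 20))
  cmp2 <- compare_paired(m_const, "n_settled")
  expect_true(cmp2$zero_variance)
  expect_true(is.na(cmp2$t_stat))
  expect_equal(cmp2$ratio, 2)
  expect_error(compare_paired(m_same[c(1, 4), ], "n_settled"), "2 paired")
})

test_that("generation stepping releases only from settled cells and stops at the target", {
  f <- jet_field()
  msk <- shelf_mask(f)
  origin <- shelf_mask(f, region = list(lon = c(-30, -14), lat = c(27, 30)),
                       name = "north")
  near_target <- shelf_mask(f, region = list(lon = c(-30, -14),
                                             lat = c(0, 26)),
                            name = "south-of-origin")
  sc <- dispersal_scenario("light", 60)
  gr <- iterate_generations(f, msk, origin, near_target, sc,
                            n_particles = 60, max_generations = 2,
                            dt = 0.25, seed = 5)
  # settlement south of 26N is reachable within one lifetime here
  expect_true(gr$reached)
  expect_equal(gr$n_generations, 1)
  # reproducibility
  gr2 <- iterate_generations(f, msk, origin, near_target, sc,
                             n_particles = 60, max_generations = 2,
                             dt = 0.25, seed = 5)
  expect_equal(gr$generations[[1]]$settlement, gr2$generations[[1]]$settlement)
})

test_that("a generation with no settlement terminates as not reached", {
  # uniform offshore (westward) flow: particles leave the shelf and never
  # return, so generation 1 settles nothing
  f <- uniform_field(u0 = -0.3, v0 = 0, dx = 0.5, lon = c(-30, -14),
                     lat = c(10, 20), coast_lon = -15, shelf_width_km = 120)
  msk <- shelf_mask(f)
  origin <- shelf_mask(f, region = list(lon = c(-16, -14), lat = c(14, 16)))
  target <- shelf_mask(f, region = list(lon = c(-16, -14), lat = c(10, 12)))
  gr <- iterate_generations(f, msk, origin, target,
                            dispersal_scenario("dark", 40),
                            n_particles = 30, max_generations = 3,
                            dt = 0.25, seed = 6)
  expect_false(gr$reached)
  expect_equal(gr$n_generations, 1)
  expect_equal(gr$generations[[1]]$n_settled, 0)
})

test_that("later generations release only from earlier settlement cells", {
  f <- jet_field()
  msk <- shelf_mask(f)
  origin <- shelf_mask(f, region = list(lon = c(-30, -14), lat = c(28, 30)))
  target <- shelf_mask(f, region = list(lon = c(-30, -14), lat = c(0, 2)))
  gr <- iterate_generations(f, msk, origin, target,
                            dispersal_scenario("light", 50),
                            n_particles = 50, max_generations = 3,
                            dt = 0.25, seed = 7)
  for (g in seq_len(gr$n_generations)[-1]) {
    prev <- gr$generations[[g - 1]]$settlement
    rel <- gr$generations[[g]]$release_cells
    prev_keys <- paste(prev$i, prev$j)
    expect_true(all(paste(rel[, 1], rel[, 2]) %in% prev_keys))
  }
})

test_that("line seeding apportions particles evenly across shelf cells", {
  f <- uniform_field(u0 = 0, dx = 0.5, lon = c(-20, -14), lat = c(10, 16),
                     coast_lon = -15, shelf_width_km = 60)
  msk <- shelf_mask(f)
  ncells <- sum(msk$mask[, f$lat >= 12 & f$lat <= 14])
  sch <- seed_line_release(msk, c(12, 14), n_particles = 10 * ncells)
  expect_equal(sum(sch$sites$n), 10 * ncells)
  expect_true(all(sch$sites$n == 10))
  # largest-remainder: 100 over 3 cells -> 34/33/33
  expect_equal(sort(apportion(100, rep(1, 3)), decreasing = TRUE),
               c(34L, 33L, 33L))
  expect_error(seed_line_release(msk, c(40, 45), 100), "no shelf cells")
})
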