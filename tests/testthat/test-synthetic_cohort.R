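test_that("lognormal calibration satisfies both constraints", {
  # fraction 1/2 pins the log-mean at log(limit), the lognormal median
  cal <- calibrate_lognormal(0.5, limit = 10, target_max = 80, n = 50)
  expect_equal(cal$meanlog, log(10), tolerance = 1e-10)

  # milk calibration: exceedance holds analytically to 1e-6, expected max hits
  cal <- calibrate_lognormal(134 / 181, limit = 1.7, target_max = 61.91,
                             n = 181)
  expect_equal(plnorm(1.7, cal$meanlog, cal$sdlog, lower.tail = FALSE),
               134 / 181, tolerance = 1e-6)
  expect_equal(expected_lognormal_max(cal$meanlog, cal$sdlog, 181), 61.91,
               tolerance = 1e-6)
  # and by forward Monte Carlo on the fitted parameters
  set.seed(99)
  x <- rlnorm(1e6, cal$meanlog, cal$sdlog)
  expect_equal(mean(x > 1.7), 134 / 181, tolerance = 3e-3)

  expect_error(calibrate_lognormal(0.99, 1.7, 1.7 * (1 + 1e-8), n = 181),
               class = "hg_calibration_error")
  expect_error(calibrate_lognormal(0.5, 10, target_max = 9, n = 10),
               class = "hg_calibration_error")
  expect_error(calibrate_lognormal(1.2, 10, 20, 10),
               class = "hg_calibration_error")
})

test_that("generator is deterministic for a fixed seed", {
  cfg <- generator_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  cfg2 <- generator_config(seed = 8)
  expect_false(identical(generate_cohort(cfg2)$records, a$records))
})

test_that("generated cohorts have the configured structure", {
  cfg <- generator_config(seed = 3)
  ds <- generate_cohort(cfg)
  counts <- matrix_counts(ds)
  expect_equal(counts[["breastmilk"]], 181L)
  expect_equal(counts[["blood"]], 70L)
  expect_equal(counts[["mother_urine"]], 224L)
  expect_equal(counts[["child_urine"]], 172L)
  expect_equal(counts[["food"]], 53L)
  df <- ds$records
  expect_true(all(df$value >= 0))
  # truncation bound respected per matrix
  for (m in c("breastmilk", "blood", "mother_urine", "child_urine"))
    expect_true(all(df$value[df$matrix == m] <=
                      cfg$marginals[[m]]$trunc_max))
  # every infant carries a linked mother who gave milk, and shares her GPS
  kids <- df[df$matrix == "child_urine", ]
  milk <- df[df$matrix == "breastmilk", ]
  expect_true(all(kids$linked_mother_id %in% milk$subject_id))
  i <- match(kids$linked_mother_id, milk$subject_id)
  expect_equal(kids$latitude, milk$latitude[i])
  # GPS inside the bounding box
  expect_true(all(df$latitude >= 24.3 & df$latitude <= 27.5))
  expect_true(all(df$longitude >= 83.3 & df$longitude <= 88.3))
})

test_that("copula dependence is controlled by rho", {
  # rho = 0: empirical log-scale correlation near 0 at n = 172
  cfg0 <- generator_config(seed = 11, rho_milk_child_urine = 0,
                           rho_milk_mother_urine = 0)
  ds <- generate_cohort(cfg0)
  p <- pair_series(ds, "child_urine")
  expect_lt(abs(cor(log(p$pairs$predictor), log(p$pairs$response))), 0.1)

  # positive rho raises the log-scale correlation accordingly
  cfg6 <- generator_config(seed = 11, rho_milk_child_urine = 0.6,
                           rho_milk_mother_urine = 0.6,
                           sizes = c(breastmilk = 5000, blood = 0,
                                     mother_urine = 5000, child_urine = 5000,
                                     food = 0))
  ds <- generate_cohort(cfg6)
  p <- pair_series(ds, "mother_urine")
  expect_equal(cor(log(p$pairs$predictor), log(p$pairs$response)), 0.6,
               tolerance = 0.05)
})

test_that("closed-form r-squared mapping agrees with simulation", {
  sx <- 1.1; sy <- 0.9
  rho <- rho_for_target_r2(0.108, sx, sy)
  set.seed(5)
  z1 <- rnorm(2e5)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(2e5)
  r2 <- cor(exp(1 + sx * z1), exp(2 + sy * z2))^2
  expect_equal(r2, 0.108, tolerance = 0.02)
  expect_error(rho_for_target_r2(0.9999, 0.1, 3),
               class = "hg_calibration_error")
})

test_that("food generator stays below the limit with a pinned maximum", {
  food <- generate_food_below_limit(53, max_target = 44.44, seed = 2)
  expect_equal(nrow(food), 53L)
  expect_equal(max(food$value), 44.44)
  expect_true(all(food$value < 100))
  expect_equal(sum(food$value == 44.44), 1L)
  one <- generate_food_below_limit(1, max_target = 44.44, seed = 2)
  expect_equal(one$value, 44.44)
  expect_error(generate_food_below_limit(53, max_target = 120),
               class = "hg_config_error")
})

test_that("non-detect probability produces zero-valued records", {
  cfg <- generator_config(seed = 4,
                          nondetect_prob = c(child_urine = 0.2))
  ds <- generate_cohort(cfg)
  x <- ds$records$value[ds$records$matrix == "child_urine"]
  expect_gt(sum(x == 0), 0)
  expect_lt(abs(mean(x == 0) - 0.2), 0.1)
})

test_that("generated margins are self-consistent with the configured law", {
  # KS test against the configured lognormal should fail to reject at
  # alpha = 0.01 in at least 95 of 100 seeded replicates
  cfg <- generator_config(seed = 1,
                          sizes = c(breastmilk = 181, blood = 0,
                                    mother_urine = 0, child_urine = 0,
                                    food = 0))
  marg <- cfg$marginals$breastmilk
  reject <- logical(100)
  for (i in 1:100) {
    cfg$seed <- i
    x <- generate_cohort(cfg)$records$value
    reject[i] <- suppressWarnings(
      ks.test(x, plnorm, marg$meanlog, marg$sdlog)$p.value) < 0.01
  }
  expect_gte(mean(!reject), 0.95)
})

test_that("empirical exceedance converges to the configured fraction", {
  cfg <- generator_config(seed = 21,
                          sizes = c(breastmilk = 1e5, blood = 0,
                                    mother_urine = 0, child_urine = 0,
                                    food = 0))
  x <- generate_cohort(cfg)$records$value
  expect_equal(mean(x > 1.7), 134 / 181, tolerance = 0.005 / (134 / 181))
})
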