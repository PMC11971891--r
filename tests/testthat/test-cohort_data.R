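test_that("CSV reading validates rows, drops blank values and reports them", {
  f <- write_csv_fixture(c(
    "subject_id,group,matrix,value",
    "M001,mother,breastmilk,1.2",
    "M002,mother,breastmilk,2.5",
    "M003,mother,blood,8.1"))
  ds <- read_cohort(f)
  expect_s3_class(ds, "hg_cohort")
  expect_equal(nrow(ds$records), 3L)
  expect_equal(ds$report$n_dropped, 0L)
  expect_equal(ds$records$unit, c("ug_per_L", "ug_per_L", "ug_per_L"))

  f <- write_csv_fixture(c(
    "subject_id,group,matrix,value",
    "M001,mother,breastmilk,1.2",
    "M002,mother,breastmilk,",
    "M003,mother,blood,8.1",
    "M004,mother,mother_urine,4.0",
    "M005,mother,mother_urine,"))
  ds <- read_cohort(f)
  expect_equal(nrow(ds$records), 3L)
  expect_equal(ds$report$n_dropped, 2L)
  expect_equal(ds$report$dropped_lines, c(3L, 6L))

  f <- write_csv_fixture(c("subject_id,group,matrix,value",
                           "M001,mother,breastmilk,-1.0"))
  expect_error(read_cohort(f), "negative.*line\\(s\\) 2",
               class = "hg_validation_error")

  f <- write_csv_fixture(c("subject_id,group,matrix,value",
                           "M001,mother,plasma,1.0"))
  expect_error(read_cohort(f), "plasma", class = "hg_validation_error")

  f <- write_csv_fixture(c("subject_id,matrix,value", "M001,breastmilk,1"))
  expect_error(read_cohort(f), "group", class = "hg_validation_error")
  expect_error(read_cohort(tempfile()), class = "hg_io_error")

  # schema mapping renames file columns to the canonical ones
  f <- write_csv_fixture(c("ID,group,matrix,conc", "M001,mother,blood,3.3"))
  ds <- read_cohort(f, schema = c(subject_id = "ID", value = "conc"))
  expect_equal(ds$records$value, 3.3)
})

test_that("cohort construction enforces the record invariants", {
  expect_error(as_cohort(rec("A", "breastmilk", -0.1)),
               class = "hg_validation_error")
  expect_error(as_cohort(rec(c("A", "A"), "blood", c(1, 2))),
               "duplicate", class = "hg_validation_error")
  expect_error(as_cohort(rec("A", "blood", 1, latitude = 95,
                             longitude = 80)),
               "latitude", class = "hg_validation_error")
  bad_unit <- rec("A", "food", 1)
  bad_unit$unit <- "ug_per_L"
  expect_error(as_cohort(bad_unit), "unit", class = "hg_validation_error")
})

test_that("exceedance classification is strict at the limit boundary", {
  ds <- milk_cohort(c(1.0, 1.7, 1.8))
  cls <- classify_exceedance(ds)
  expect_equal(cls$records$exceeds, c(FALSE, FALSE, TRUE))
  expect_equal(cls$summary$exceedance_percent, 33)
  expect_equal(cls$summary$exceedance_percent_exact, 100 / 3)
  # boundary semantics are config-overridable
  loose <- classify_exceedance(ds, strict = FALSE)
  expect_equal(loose$records$exceeds, c(FALSE, TRUE, TRUE))
  # a matrix with no registered limit is a configuration error
  expect_error(classify_exceedance(ds, default_limits()[0, ]),
               class = "hg_config_error")
})

test_that("limit registry defaults, overrides and YAML round", {
  lim <- default_limits()
  expect_equal(lim$limit[match(c("breastmilk", "blood", "mother_urine",
                                 "child_urine", "food"), lim$matrix)],
               c(1.7, 20, 10, 10, 100))
  expect_equal(default_limits(breastmilk = 2)$limit[
    default_limits()$matrix == "breastmilk"], 2)
  expect_error(default_limits(hair = 1), class = "hg_config_error")
  expect_error(default_limits(blood = -5), class = "hg_config_error")
  f <- tempfile(fileext = ".yml")
  writeLines("blood: 25.5", f)
  expect_equal(limits_from_yaml(f)$limit[default_limits()$matrix == "blood"],
               25.5)
})

test_that("matrix summaries: closed forms, zero handling, empty signal", {
  ds <- as_cohort(rec(c("A", "B"), "blood", c(2, 8)))
  s <- summarize_matrix(ds, "blood")
  expect_equal(s$mean, 5)
  expect_equal(s$geometric_mean, 4)
  expect_equal(s$max_value, 8)
  expect_equal(s$median, 5)

  s <- summarize_matrix(as_cohort(rec("A", "breastmilk", 61.91)),
                        "breastmilk")
  expect_equal(s$max_value, 61.91)
  expect_equal(s$mean, 61.91)

  ds <- as_cohort(rec(c("A", "B"), "mother_urine", c(0, 10)))
  s <- summarize_matrix(ds, "mother_urine")
  expect_equal(s$mean, 5)
  expect_equal(s$geometric_mean, 10)  # computed on positive values only
  expect_equal(s$n_zeros, 1L)

  s <- summarize_matrix(milk_cohort(1), "blood")
  expect_equal(s$n_total, 0L)
  expect_true(is.na(s$mean))
})

test_that("classification invariants: permutation, monotonicity, rounding", {
  for (seed in 1:5) {
    ds <- with(list(), {set.seed(seed); random_cohort(30)})
    cls <- classify_exceedance(ds)
    perm <- as_cohort(ds$records[sample(nrow(ds$records)), ])
    cls2 <- classify_exceedance(perm)
    expect_equal(cls$summary, cls2$summary)
    # raising a limit weakly decreases n_above
    x <- ds$records$value[ds$records$matrix == "breastmilk"]
    if (length(x)) {
      n_above <- sapply(c(0.5, 1.7, 5, 50), function(L)
        summarize_matrix(ds, "breastmilk",
                         default_limits(breastmilk = L))$n_above_limit)
      expect_true(all(diff(n_above) <= 0))
    }
    # exact percent is 100 * above / total
    s <- cls$summary
    expect_equal(s$exceedance_percent_exact,
                 100 * s$n_above_limit / s$n_total, tolerance = 1e-12)
    expect_equal(s$n_above_limit + s$n_below_limit, s$n_total)
  }
  # nearest-integer rounding, ties away from zero: 1 of 8 above = 12.5 -> 13
  ds <- milk_cohort(c(rep(1, 7), 2))
  expect_equal(classify_exceedance(ds)$summary$exceedance_percent, 13)
})

test_that("cohort CSV writing round-trips every field exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    ds <- random_cohort(25)
    f <- tempfile(fileext = ".csv")
    write_cohort(ds, f)
    back <- read_cohort(f)
    expect_identical(back$records, ds$records)
  }
  # GPS coordinates preserved beyond 6 decimal places
  ds <- as_cohort(rec("A", "blood", 1.5, latitude = 26.1234567,
                      longitude = 85.7654321))
  f <- tempfile(fileext = ".csv")
  write_cohort(ds, f)
  back <- read_cohort(f)
  expect_equal(back$records$latitude, 26.1234567, tolerance = 1e-12)
  expect_equal(back$records$longitude, 85.7654321, tolerance = 1e-12)
  # empty dataset: header-only file, read back as empty
  empty <- as_cohort(rec("A", "blood", 1)[0, ])
  f <- tempfile(fileext = ".csv")
  write_cohort(empty, f)
  expect_equal(nrow(read_cohort(f)$records), 0L)
})
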