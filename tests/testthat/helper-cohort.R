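# Fixture builders: small record frames constructed in code.

rec <- function(subject_id, matrix, value, group = NULL,
                latitude = NA_real_, longitude = NA_real_,
                linked_mother_id = NA_character_,
                linked_household_id = NA_character_) {
  if (is.null(group))
    group <- ifelse(matrix == "child_urine", "infant",
                    ifelse(matrix == "food", "household", "mother"))
  data.frame(subject_id = subject_id, group = group, matrix = matrix,
             value = value, unit = matrix_unit(matrix),
             latitude = latitude, longitude = longitude,
             linked_mother_id = linked_mother_id,
             linked_household_id = linked_household_id,
             stringsAsFactors = FALSE)
}

milk_cohort <- function(values, ids = sprintf("M%03d", seq_along(values))) {
  as_cohort(rec(ids, "breastmilk", values))
}

# random valid cohort for property-style tests (ambient RNG)
random_cohort <- function(n = 20) {
  m <- sample(c("breastmilk", "blood", "mother_urine", "food"), n,
              replace = TRUE)
  ids <- sprintf("S%03d_%s", seq_len(n), m)  # unique per matrix by design
  has_xy <- runif(n) < 0.5
  as_cohort(rec(ids, m, round(rlnorm(n, 1, 1), 4),
                latitude = ifelse(has_xy, runif(n, 24.3, 27.5), NA),
                longitude = ifelse(has_xy, runif(n, 83.3, 88.3), NA)))
}

write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
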