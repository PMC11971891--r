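# Deterministic Average Daily Dose (ADD) and Hazard Quotient (HQ)
# computation: ADD = C x IR x EF x ED / (BW x AT), HQ = ADD / RfD.
# Two exposure routes are modelled: the lactating mother ingesting
# mercury-contaminated wheat, and the breastfed infant ingesting the
# mother's milk. Breastmilk, blood and urine concentrations are otherwise
# biomarkers (classification and association stages), not intake routes.

# receptor -> the matrix whose concentration enters its ADD
HG_ROUTE <- c(adult_mother = "food", infant = "breastmilk")

#' Exposure parameter set for one receptor
#'
#' Default values are the standard deterministic point estimates for this
#' assessment: for the adult mother, wheat intake IR = 159.9 g/day,
#' EF = 350 days/year, ED = 30 years, BW = 71.7 kg, AT = 22365 days; for
#' the infant, milk intake IR = 0.741 L/day, EF = 182 days/year,
#' ED = 0.25 years, BW = 7.4 kg, AT = 45.5 days. RfD = 0.0003 mg/kg/day
#' for both. All must be strictly positive and the averaging time must
#' cover the exposure window (`AT >= EF * ED`).
#'
#' @param receptor `"adult_mother"` or `"infant"`.
#' @param ... Named overrides of `IR`, `EF`, `ED`, `BW`, `AT`, `RfD`.
#' @return A list of class `hg_exposure` with the parameters, their units
#'   and the receptor's intake matrix.
#' @export
#' @examples
#' exposure_parameters("adult_mother")
#' exposure_parameters("infant", BW = 8.0)
exposure_parameters <- function(receptor = c("adult_mother", "infant"), ...) {
  receptor <- match.arg(receptor)
  p <- if (receptor == "adult_mother") {
    list(IR = 159.9, IR_unit = "g_per_day", EF = 350, ED = 30,
         BW = 71.7, AT = 22365, RfD = 3e-4)
  } else {
    list(IR = 0.741, IR_unit = "L_per_day", EF = 182, ED = 0.25,
         BW = 7.4, AT = 45.5, RfD = 3e-4)
  }
  over <- list(...)
  bad <- setdiff(names(over), c("IR", "EF", "ED", "BW", "AT", "RfD"))
  if (length(bad))
    hg_error(paste0("unknown exposure parameter: ",
                    paste(bad, collapse = ", ")), "hg_config_error")
  p[names(over)] <- over
  num <- unlist(p[c("IR", "EF", "ED", "BW", "AT", "RfD")])
  if (any(!is.finite(num) | num <= 0))
    hg_error("exposure parameters must be strictly positive",
             "hg_config_error")
  if (p$AT < p$EF * p$ED)
    hg_error("averaging time AT must cover the exposure window EF * ED",
             "hg_config_error")
  structure(c(list(receptor = receptor, matrix = HG_ROUTE[[receptor]]), p),
            class = "hg_exposure")
}

#' Read exposure parameters for both receptors from YAML
#'
#' The file has top-level keys `adult_mother` and/or `infant`, each mapping
#' parameter names to values; omitted parameters keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list of `hg_exposure` objects, one per receptor.
#' @export
exposure_parameters_from_yaml <- function(path) {
  if (!file.exists(path))
    hg_error(paste0("parameter file not found: ", path), "hg_io_error")
  conf <- yaml::read_yaml(path)
  out <- list(adult_mother = exposure_parameters("adult_mother"),
              infant = exposure_parameters("infant"))
  for (r in intersect(names(conf), names(out)))
    out[[r]] <- do.call(exposure_parameters, c(list(receptor = r), conf[[r]]))
  out
}

#' Average Daily Dose from a concentration
#'
#' `ADD = C * IR * EF * ED / (BW * AT)` in mg/kg/day, with units made
#' consistent first: the concentration is converted from ug to mg (/1000)
#' and the adult food intake rate from g/day to kg/day (/1000); the infant
#' intake is volumetric (L/day) against a per-litre milk concentration, so
#' no further conversion applies. ADD is linear in C.
#'
#' @param C Concentration(s), ug/L for breastmilk or ug/kg for food;
#'   non-negative. Vectorised.
#' @param matrix `"food"` (adult route) or `"breastmilk"` (infant route);
#'   must match the receptor of `params`.
#' @param params An `hg_exposure` parameter set.
#' @return ADD in mg/kg/day, same length as `C`.
#' @export
#' @examples
#' compute_add(44.44, "food", exposure_parameters("adult_mother"))
compute_add <- function(C, matrix, params) {
  stopifnot(inherits(params, "hg_exposure"))
  if (!identical(matrix, params$matrix))
    hg_error(sprintf("matrix '%s' is not the intake route of receptor '%s'",
                     matrix, params$receptor), "hg_usage_error")
  if (any(C < 0, na.rm = TRUE))
    hg_error("concentration must be non-negative", "hg_validation_error")
  C_mg <- C / 1000                                     # ug -> mg
  IR <- if (params$IR_unit == "g_per_day") params$IR / 1000 else params$IR
  C_mg * IR * params$EF * params$ED / (params$BW * params$AT)
}

#' Hazard Quotient from an Average Daily Dose
#'
#' `HQ = ADD / RfD`; an HQ above 1 flags potential non-carcinogenic risk,
#' while HQ equal to or below 1 predicts no adverse effect (the boundary
#' itself does not flag).
#'
#' @param ADD Average daily dose(s), mg/kg/day. Vectorised.
#' @param RfD Oral reference dose, mg/kg/day, strictly positive.
#' @return HQ, dimensionless.
#' @export
compute_hq <- function(ADD, RfD = 3e-4) {
  if (!is.numeric(RfD) || length(RfD) != 1L || !is.finite(RfD) || RfD <= 0)
    hg_error("RfD must be a single positive number", "hg_config_error")
  ADD / RfD
}

#' Per-subject deterministic risk table
#'
#' One row per eligible subject and receptor: adult mothers are paired with
#' their household's food (wheat) concentration through
#' `linked_household_id`; infants use their linked mother's measured
#' breastmilk concentration. Subjects whose route concentration is missing
#' are skipped and counted.
#'
#' @param ds An `hg_cohort`.
#' @param params_by_receptor Named list with elements `adult_mother` and
#'   `infant`, each an `hg_exposure`.
#' @return A list with `results` (subject_id, receptor, matrix,
#'   concentration, unit, ADD, HQ, exceeds_hq_threshold) and `summary`
#'   (per receptor: n, n_skipped, ADD min/max/mean, HQ min/max/mean; a
#'   receptor with no eligible subject keeps `n = 0` and `NA` statistics).
#' @export
risk_table <- function(ds,
                       params_by_receptor = list(
                         adult_mother = exposure_parameters("adult_mother"),
                         infant = exposure_parameters("infant"))) {
  stopifnot(inherits(ds, "hg_cohort"))
  df <- ds$records
  food <- df[df$matrix == "food", ]
  milk <- df[df$matrix == "breastmilk", ]

  rows <- list(); skipped <- c(adult_mother = 0L, infant = 0L)

  # adult mothers: any subject with a mother-group record
  mothers <- unique(df[df$group == "mother", c("subject_id",
                                               "linked_household_id")])
  if (nrow(mothers)) {
    conc <- food$value[match(mothers$linked_household_id, food$subject_id)]
    keep <- !is.na(conc)
    skipped[["adult_mother"]] <- sum(!keep)
    if (any(keep)) {
      p <- params_by_receptor$adult_mother
      add <- compute_add(conc[keep], "food", p)
      hq <- compute_hq(add, p$RfD)
      rows$adult <- data.frame(subject_id = mothers$subject_id[keep],
                               receptor = "adult_mother", matrix = "food",
                               concentration = conc[keep],
                               unit = "ug_per_kg", ADD = add, HQ = hq,
                               exceeds_hq_threshold = hq > 1,
                               stringsAsFactors = FALSE)
    }
  }

  # infants: linked mother's milk
  infants <- df[df$group == "infant", ]
  infants <- unique(infants[, c("subject_id", "linked_mother_id")])
  if (nrow(infants)) {
    conc <- milk$value[match(infants$linked_mother_id, milk$subject_id)]
    keep <- !is.na(conc)
    skipped[["infant"]] <- sum(!keep)
    if (any(keep)) {
      p <- params_by_receptor$infant
      add <- compute_add(conc[keep], "breastmilk", p)
      hq <- compute_hq(add, p$RfD)
      rows$infant <- data.frame(subject_id = infants$subject_id[keep],
                                receptor = "infant", matrix = "breastmilk",
                                concentration = conc[keep],
                                unit = "ug_per_L", ADD = add, HQ = hq,
                                exceeds_hq_threshold = hq > 1,
                                stringsAsFactors = FALSE)
    }
  }

  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), receptor = character(),
               matrix = character(), concentration = numeric(),
               unit = character(), ADD = numeric(), HQ = numeric(),
               exceeds_hq_threshold = logical(), stringsAsFactors = FALSE)
  rownames(results) <- NULL

  summary <- do.call(rbind, lapply(c("adult_mother", "infant"), function(r) {
    x <- results[results$receptor == r, ]
    if (nrow(x) == 0L)
      data.frame(receptor = r, n = 0L, n_skipped = skipped[[r]],
                 ADD_min = NA_real_, ADD_max = NA_real_, ADD_mean = NA_real_,
                 HQ_min = NA_real_, HQ_max = NA_real_, HQ_mean = NA_real_,
                 stringsAsFactors = FALSE)
    else
      data.frame(receptor = r, n = nrow(x), n_skipped = skipped[[r]],
                 ADD_min = min(x$ADD), ADD_max = max(x$ADD),
                 ADD_mean = mean(x$ADD), HQ_min = min(x$HQ),
                 HQ_max = max(x$HQ), HQ_mean = mean(x$HQ),
                 stringsAsFactors = FALSE)
  }))
  list(results = results, summary = summary)
}
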