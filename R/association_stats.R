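# Association between breastmilk mercury and urinary mercury: paired
# series construction through the cohort's linkage ids, a simple linear
# (OLS) fit, and the fixed-factor variant that treats each distinct milk
# value as a categorical level (kept for fidelity with common
# general-linear-model practice, and flagged when near-saturation inflates
# its R-squared).

#' Pair breastmilk values with a urine response
#'
#' For `response_matrix = "mother_urine"` each mother's milk value is
#' paired with her own urine value; for `"child_urine"` with her linked
#' infant's urine value (through `linked_mother_id`). Records that cannot
#' be paired on either side are counted, not silently dropped.
#'
#' @param ds An `hg_cohort`.
#' @param response_matrix `"child_urine"` or `"mother_urine"`.
#' @return An object of class `hg_pairs`: data.frame `pairs` (predictor =
#'   milk ug/L, response = urine ug/L, with both subject ids), `n`,
#'   `n_unpaired`, `response_matrix`.
#' @export
pair_series <- function(ds,
                        response_matrix = c("child_urine", "mother_urine")) {
  stopifnot(inherits(ds, "hg_cohort"))
  response_matrix <- match.arg(response_matrix)
  df <- ds$records
  milk <- df[df$matrix == "breastmilk", ]
  resp <- df[df$matrix == response_matrix, ]
  mother_of <- if (response_matrix == "mother_urine") resp$subject_id else
    resp$linked_mother_id
  i <- match(mother_of, milk$subject_id)
  keep <- !is.na(i)
  pairs <- data.frame(predictor_id = milk$subject_id[i[keep]],
                      response_id = resp$subject_id[keep],
                      predictor = milk$value[i[keep]],
                      response = resp$value[keep],
                      stringsAsFactors = FALSE)
  n_unpaired <- sum(!keep) + sum(!milk$subject_id %in% mother_of[keep])
  if (nrow(pairs) == 0L)
    hg_error("no milk-urine pairs could be formed", "hg_pairing_error")
  structure(list(pairs = pairs, n = nrow(pairs), n_unpaired = n_unpaired,
                 response_matrix = response_matrix), class = "hg_pairs")
}

fit_report <- function(kind, fit, n, extra = list()) {
  # an exact-fit summary is legitimate here (e.g. saturated or noiseless
  # fixtures); silence only stats's perfect-fit caveat
  s <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  c(list(kind = kind, n = n,
         r_squared = s$r.squared, adjusted_r_squared = s$adj.r.squared,
         f_statistic = unname(s$fstatistic["value"]),
         df_model = unname(s$fstatistic["numdf"]),
         df_residual = unname(s$fstatistic["dendf"]),
         p_value = unname(stats::pf(s$fstatistic["value"],
                                    s$fstatistic["numdf"],
                                    s$fstatistic["dendf"],
                                    lower.tail = FALSE)),
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit))),
    extra)
}

#' Simple linear (OLS) fit of urine on breastmilk mercury
#'
#' Ordinary least squares with intercept, on the raw concentration scale.
#' Reports r-squared (the squared Pearson correlation), adjusted
#' r-squared, the F statistic with its p-value, slope, intercept and the
#' residual series (suitable for a residual plot). Set `log_scale = TRUE`
#' to fit on log-log scale instead (both series must then be positive).
#'
#' @param s An `hg_pairs`.
#' @param log_scale Fit `log(response) ~ log(predictor)` instead.
#' @return A list of class `hg_fitreport` (`kind = "simple_linear"`).
#' @export
simple_linear_fit <- function(s, log_scale = FALSE) {
  stopifnot(inherits(s, "hg_pairs"))
  x <- s$pairs$predictor; y <- s$pairs$response
  if (log_scale) {
    keep <- x > 0 & y > 0
    x <- log(x[keep]); y <- log(y[keep])
  }
  if (length(x) < 3L)
    hg_error("need at least 3 pairs for a linear fit", "hg_fitting_error")
  if (stats::var(x) == 0)
    hg_error("predictor has zero variance", "hg_fitting_error")
  fit <- stats::lm(y ~ x)
  rep <- fit_report("simple_linear", fit, length(x),
                    extra = list(slope = unname(stats::coef(fit)[2]),
                                 intercept = unname(stats::coef(fit)[1]),
                                 log_scale = log_scale,
                                 response_matrix = s$response_matrix))
  structure(rep, class = "hg_fitreport")
}

#' Fixed-factor (one-way) fit of urine on breastmilk levels
#'
#' Treats the milk value as a categorical factor, optionally binned into
#' `n_bins` quantile classes first, and fits the one-way fixed-effects
#' model. When every level is a singleton the design is saturated: the
#' model reproduces the data exactly, R-squared is 1 by construction and
#' the adjusted value is undefined; the report flags this rather than
#' presenting the inflated fit as evidence.
#'
#' @param s An `hg_pairs`.
#' @param n_bins Optional number of quantile bins for the milk levels;
#'   `NULL` (default) uses each distinct value as its own level.
#' @return A list of class `hg_fitreport` (`kind = "fixed_factor"`), with
#'   `saturated` flag and `n_levels`.
#' @export
fixed_factor_fit <- function(s, n_bins = NULL) {
  stopifnot(inherits(s, "hg_pairs"))
  x <- s$pairs$predictor; y <- s$pairs$response
  f <- if (is.null(n_bins)) factor(x) else
    cut(x, breaks = unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1))),
        include.lowest = TRUE)
  k <- nlevels(f)
  if (k < 2L)
    hg_error("need at least 2 factor levels", "hg_fitting_error")
  if (length(y) - k <= 0L) {
    warning("saturated fixed-factor design: every level is (near) a ",
            "singleton; R-squared is 1 by construction")
    return(structure(list(kind = "fixed_factor", n = length(y),
                          n_levels = k, saturated = TRUE,
                          r_squared = 1, adjusted_r_squared = NA_real_,
                          f_statistic = NA_real_, p_value = NA_real_,
                          df_model = k - 1L, df_residual = length(y) - k,
                          fitted = y, residuals = rep(0, length(y)),
                          response_matrix = s$response_matrix),
                     class = "hg_fitreport"))
  }
  fit <- stats::lm(y ~ f)
  rep <- fit_report("fixed_factor", fit, length(y),
                    extra = list(n_levels = k, saturated = FALSE,
                                 response_matrix = s$response_matrix))
  structure(rep, class = "hg_fitreport")
}

#' @export
print.hg_fitreport <- function(x, ...) {
  cat(sprintf("<hg_fitreport> %s (n = %d)\n", x$kind, x$n))
  cat(sprintf("  R2 = %.4f  adj R2 = %s  F = %s  p = %s\n",
              x$r_squared,
              format(x$adjusted_r_squared, digits = 4),
              format(x$f_statistic, digits = 4),
              format(x$p_value, digits = 4)))
  invisible(x)
}
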