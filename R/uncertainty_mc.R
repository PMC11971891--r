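# Monte Carlo uncertainty propagation: fit a lognormal to a cohort's
# concentrations (zeros treated as a point mass, i.e. zero inflation),
# draw concentrations, map each draw through the deterministic ADD/HQ
# equations, and summarise the resulting HQ distribution. Only the
# concentration is randomised; all other exposure factors are the
# deterministic point values of the parameter set.

#' Construct a fitted concentration distribution
#'
#' Usually produced by [fit_concentration()]; direct construction is
#' useful for degenerate (point-mass) inputs with `sdlog = 0`, for which
#' the Monte Carlo collapses to the deterministic value.
#'
#' @param matrix Sample matrix the distribution describes.
#' @param meanlog,sdlog Lognormal parameters (`sdlog >= 0`; 0 means a point
#'   mass at `exp(meanlog)`).
#' @param n_used Positive values used in the fit.
#' @param n_zeros_excluded Zero (non-detect) values excluded; drives the
#'   zero-inflation weight in [run_mc()].
#' @param ks_statistic Optional goodness-of-fit statistic.
#' @param family Distribution family label (only `"lognormal"` is fitted).
#' @return An object of class `hg_fit`.
#' @export
fitted_distribution <- function(matrix, meanlog, sdlog, n_used,
                                n_zeros_excluded = 0L,
                                ks_statistic = NA_real_,
                                family = "lognormal") {
  if (sdlog < 0) hg_error("sdlog must be >= 0", "hg_config_error")
  structure(list(matrix = matrix, family = family, meanlog = meanlog,
                 sdlog = sdlog, n_used = as.integer(n_used),
                 n_zeros_excluded = as.integer(n_zeros_excluded),
                 ks_statistic = ks_statistic),
            class = "hg_fit")
}

#' Fit a lognormal concentration distribution to one matrix
#'
#' Maximum-likelihood lognormal fit (via \pkg{fitdistrplus}) to the
#' strictly positive values of a matrix; zeros (non-detects) are excluded
#' from the fit but counted, so [run_mc()] can mix a point mass at zero in
#' proportion. A Kolmogorov-Smirnov statistic against the fitted
#' distribution is reported as a goodness-of-fit diagnostic.
#'
#' @param ds An `hg_cohort`.
#' @param matrix Matrix label to fit.
#' @param family Only `"lognormal"` is supported.
#' @return An `hg_fit`.
#' @export
fit_concentration <- function(ds, matrix, family = "lognormal") {
  stopifnot(inherits(ds, "hg_cohort"))
  if (!identical(family, "lognormal"))
    hg_error("only the lognormal family is supported for fitting",
             "hg_config_error")
  x <- ds$records$value[ds$records$matrix == matrix]
  pos <- x[x > 0]
  n_zeros <- sum(x == 0)
  if (length(pos) < 3L)
    hg_error("need at least 3 positive values to fit", "hg_fitting_error")
  if (stats::sd(log(pos)) == 0)
    hg_error("degenerate sample: all positive values identical (log-sd 0)",
             "hg_fitting_error")
  fit <- fitdistrplus::fitdist(pos, "lnorm", method = "mle")
  est <- fit$estimate
  ks <- suppressWarnings(
    stats::ks.test(pos, stats::plnorm, est[["meanlog"]],
                   est[["sdlog"]])$statistic)
  fitted_distribution(matrix, est[["meanlog"]], est[["sdlog"]],
                      n_used = length(pos), n_zeros_excluded = n_zeros,
                      ks_statistic = unname(ks))
}

#' Propagate a fitted concentration distribution through ADD/HQ
#'
#' Draws `n_draws` concentrations (a zero with probability
#' `n_zeros_excluded / (n_used + n_zeros_excluded)`, otherwise a lognormal
#' draw), maps each through [compute_add()] and [compute_hq()], and
#' summarises the HQ distribution. Deterministic for a fixed seed
#' (Mersenne-Twister).
#'
#' @param fit An `hg_fit` whose matrix is the intake route of `params`.
#' @param params An `hg_exposure`.
#' @param n_draws Number of simulations (default 10000).
#' @param seed Integer seed.
#' @return An object of class `hg_mc`: receptor, n_draws, seed, rng,
#'   zero-inflation weight, `HQ` (min, max, mean, sd, percentiles
#'   5/25/50/75/95), `ADD` (min, max, mean) and `prob_hq_gt_1`.
#' @export
run_mc <- function(fit, params, n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "hg_fit"), inherits(params, "hg_exposure"))
  if (n_draws < 1) hg_error("n_draws must be >= 1", "hg_usage_error")
  w0 <- fit$n_zeros_excluded / max(fit$n_used + fit$n_zeros_excluded, 1L)
  conc <- with_seed(seed, {
    v <- stats::rlnorm(n_draws, fit$meanlog, fit$sdlog)
    if (w0 > 0) v[stats::runif(n_draws) < w0] <- 0
    v
  })
  add <- compute_add(conc, fit$matrix, params)
  hq <- compute_hq(add, params$RfD)
  q <- stats::quantile(hq, c(.05, .25, .50, .75, .95), names = FALSE)
  structure(list(
    receptor = params$receptor, matrix = fit$matrix,
    n_draws = as.integer(n_draws), seed = as.integer(seed),
    rng = HG_RNG_KIND, family = fit$family,
    meanlog = fit$meanlog, sdlog = fit$sdlog, zero_weight = w0,
    HQ = list(min = min(hq), max = max(hq), mean = mean(hq),
              sd = stats::sd(hq),
              p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5]),
    ADD = list(min = min(add), max = max(add), mean = mean(add)),
    prob_hq_gt_1 = mean(hq > 1)), class = "hg_mc")
}

#' Closed-form mean HQ implied by a lognormal fit
#'
#' Because ADD is linear in the concentration, the mean HQ is the
#' zero-deflated lognormal mean `exp(meanlog + sdlog^2/2)` mapped through
#' the ADD constant and divided by RfD. Used as the analytic limit the
#' Monte Carlo mean converges to.
#'
#' @param fit An `hg_fit`.
#' @param params An `hg_exposure`.
#' @return The analytic mean HQ.
#' @export
analytic_mean_hq <- function(fit, params) {
  w0 <- fit$n_zeros_excluded / max(fit$n_used + fit$n_zeros_excluded, 1L)
  mean_conc <- (1 - w0) * exp(fit$meanlog + fit$sdlog^2 / 2)
  compute_hq(compute_add(mean_conc, fit$matrix, params), params$RfD)
}

#' Compare adult and infant Monte Carlo summaries
#'
#' @param adult,infant `hg_mc` summaries from the same cohort.
#' @return A list with the infant/adult ratios of the HQ means and maxima
#'   and the flag `infant_risk_higher` (infant mean HQ strictly greater
#'   than the adult's). A zero adult mean yields an infinite ratio with a
#'   warning.
#' @export
mc_report <- function(adult, infant) {
  stopifnot(inherits(adult, "hg_mc"), inherits(infant, "hg_mc"))
  if (adult$HQ$mean == 0) {
    warning("adult mean HQ is 0; ratios reported as Inf")
    mean_ratio <- if (infant$HQ$mean == 0) 1 else Inf
  } else mean_ratio <- infant$HQ$mean / adult$HQ$mean
  max_ratio <- if (adult$HQ$max == 0) {
    if (infant$HQ$max == 0) 1 else Inf
  } else infant$HQ$max / adult$HQ$max
  list(mean_ratio = mean_ratio, max_ratio = max_ratio,
       infant_risk_higher = infant$HQ$mean > adult$HQ$mean)
}
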