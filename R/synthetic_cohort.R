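# Seeded synthetic-cohort generator. Marginal concentration distributions
# are lognormals calibrated so that (i) the probability of exceeding the
# permissible limit equals a target fraction exactly and (ii) the expected
# maximum of n draws equals a target maximum; dependence between a mother's
# breastmilk and the urine matrices is induced by a Gaussian copula on the
# log scale.

#' Expected maximum of n lognormal draws
#'
#' Computed by numerical integration of the order-statistic expectation
#' `E[max] = \int exp(mu + sigma z) n phi(z) Phi(z)^(n-1) dz`.
#'
#' @param meanlog,sdlog Lognormal parameters (`sdlog >= 0`).
#' @param n Number of i.i.d. draws.
#' @return Expected value of the sample maximum.
#' @export
expected_lognormal_max <- function(meanlog, sdlog, n) {
  stopifnot(sdlog >= 0, n >= 1)
  if (sdlog == 0) return(exp(meanlog))
  f <- function(z) exp(meanlog + sdlog * z) * n * stats::dnorm(z) *
    stats::pnorm(z)^(n - 1)
  stats::integrate(f, -12, 12, rel.tol = 1e-10, abs.tol = 0)$value
}

#' Calibrate a lognormal to an exceedance fraction and an expected maximum
#'
#' Solves the 2x2 system in `(meanlog, sdlog)` so that
#' `P(X > limit) = fraction` holds exactly (the log-limit is the
#' `1 - fraction` quantile, a linear relation between the two parameters)
#' and the expected maximum of `n` draws equals `target_max` (solved by
#' root-finding on `sdlog` through [expected_lognormal_max()]).
#'
#' @param fraction Target exceedance probability in (0, 1).
#' @param limit Permissible limit (positive).
#' @param target_max Target expected maximum of `n` draws; must exceed
#'   `limit`.
#' @param n Sample size the maximum refers to.
#' @return A list with `meanlog`, `sdlog`, `fraction`, `limit`,
#'   `target_max`, `n` and the achieved `expected_max`.
#' @export
#' @examples
#' calibrate_lognormal(134 / 181, limit = 1.7, target_max = 61.91, n = 181)
calibrate_lognormal <- function(fraction, limit, target_max, n) {
  if (!(fraction > 0 && fraction < 1))
    hg_error("fraction must be in (0, 1)", "hg_calibration_error")
  if (limit <= 0)
    hg_error("limit must be positive", "hg_calibration_error")
  if (target_max <= limit)
    hg_error("target_max must exceed the limit", "hg_calibration_error")
  z <- stats::qnorm(1 - fraction)
  mu_of <- function(s) log(limit) - s * z
  f <- function(s) expected_lognormal_max(mu_of(s), s, n) - target_max
  lo <- 1e-6; hi <- 15
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0)
    hg_error(sprintf(paste0(
      "infeasible calibration: E[max] ranges over [%.6g, %.6g] for ",
      "sdlog in [%g, %g], target_max = %g"),
      flo + target_max, fhi + target_max, lo, hi, target_max),
      "hg_calibration_error")
  s <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  list(meanlog = mu_of(s), sdlog = s, fraction = fraction, limit = limit,
       target_max = target_max, n = n,
       expected_max = expected_lognormal_max(mu_of(s), s, n))
}

#' Latent copula correlation for a desired raw-scale r-squared
#'
#' For two lognormal margins joined by a Gaussian copula on the log scale
#' with latent correlation `rho`, the raw-scale Pearson correlation has the
#' closed form `r = (exp(rho sx sy) - 1) / sqrt((exp(sx^2)-1)(exp(sy^2)-1))`.
#' This inverts that relation: given a target raw-scale `r^2` (variance
#' explained in a simple linear fit), it returns the `rho` to configure.
#'
#' @param target_r2 Desired raw-scale squared correlation in \[0, 1).
#' @param sdlog_x,sdlog_y Log-scale standard deviations of the two margins.
#' @return Latent correlation `rho` in \[0, 1).
#' @export
rho_for_target_r2 <- function(target_r2, sdlog_x, sdlog_y) {
  stopifnot(target_r2 >= 0, target_r2 < 1, sdlog_x > 0, sdlog_y > 0)
  r <- sqrt(target_r2)
  k <- sqrt((exp(sdlog_x^2) - 1) * (exp(sdlog_y^2) - 1))
  rho <- log1p(r * k) / (sdlog_x * sdlog_y)
  if (rho >= 1)
    hg_error("target r-squared not attainable by a Gaussian log-scale copula",
             "hg_calibration_error")
  rho
}

#' Build a synthetic-cohort generator configuration
#'
#' Defaults reproduce the structure of the field campaign the package
#' models: 224 mothers (all giving urine), of whom 181 give breastmilk and
#' 70 give blood; 172 linked infants giving urine; 53 households with a
#' wheat (food) sample; GPS points uniform over the Gangetic-plain bounding
#' box lat 24.3-27.5, lon 83.3-88.3. Each biological matrix is a lognormal
#' calibrated via [calibrate_lognormal()] to the campaign's exceedance
#' fraction and maximum (milk 134/181 above 1.7 ug/L, max 61.91; blood
#' 13/70 above 20, max 38.35; mother urine 109/224 above 10, max 151.34;
#' child urine 93/172 above 10, max 137.56). Food is generated entirely
#' below the 100 ug/kg limit with its maximum pinned at 44.44 ug/kg.
#' Dependence defaults are chosen through [rho_for_target_r2()] so that
#' raw-scale variance explained between milk and the urine matrices is
#' 0.024 (child) and 0.108 (mother).
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param sizes Named integer vector of per-matrix sample sizes.
#' @param targets Named list of per-matrix calibration targets, each
#'   `list(fraction, limit, max)`; defaults as above.
#' @param rho_milk_child_urine,rho_milk_mother_urine Latent log-scale
#'   copula correlations in (-1, 1); by default derived from
#'   `target_r2_child` / `target_r2_mother`.
#' @param target_r2_child,target_r2_mother Raw-scale r-squared targets used
#'   when the corresponding `rho` is not given.
#' @param bbox Named numeric `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param nondetect_prob Named per-matrix probability that a sample is a
#'   non-detect, recorded as value 0 (default 0 everywhere).
#' @param trunc_factor Values above `trunc_factor * target max` are
#'   rejected and redrawn, to keep absurd outliers out of Monte Carlo
#'   summaries.
#' @param food_max,food_meanlog,food_sdlog Food-generator settings (see
#'   [generate_food_below_limit()]).
#' @return An object of class `hg_generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    sizes = c(breastmilk = 181L, blood = 70L, mother_urine = 224L,
              child_urine = 172L, food = 53L),
    targets = list(
      breastmilk   = list(fraction = 134 / 181, limit = 1.7,  max = 61.91),
      blood        = list(fraction = 13 / 70,   limit = 20,   max = 38.35),
      mother_urine = list(fraction = 109 / 224, limit = 10,   max = 151.34),
      child_urine  = list(fraction = 93 / 172,  limit = 10,   max = 137.56)),
    rho_milk_child_urine = NULL, rho_milk_mother_urine = NULL,
    target_r2_child = 0.024, target_r2_mother = 0.108,
    bbox = c(lat_min = 24.3, lat_max = 27.5, lon_min = 83.3, lon_max = 88.3),
    nondetect_prob = c(breastmilk = 0, blood = 0, mother_urine = 0,
                       child_urine = 0, food = 0),
    trunc_factor = 3,
    food_max = 44.44, food_meanlog = log(8), food_sdlog = 0.8) {
  sizes <- sizes[HG_MATRICES]
  names(sizes) <- HG_MATRICES
  sizes[is.na(sizes)] <- 0L
  if (any(sizes < 0)) hg_error("sizes must be >= 0", "hg_config_error")
  if (!(bbox[["lat_min"]] < bbox[["lat_max"]] &&
        bbox[["lon_min"]] < bbox[["lon_max"]]))
    hg_error("bounding box is not well-ordered", "hg_config_error")
  if (trunc_factor <= 1)
    hg_error("trunc_factor must exceed 1", "hg_config_error")
  nd <- nondetect_prob[HG_MATRICES]
  names(nd) <- HG_MATRICES
  nd[is.na(nd)] <- 0
  if (any(nd < 0 | nd >= 1))
    hg_error("nondetect_prob must be in [0, 1)", "hg_config_error")

  marginals <- lapply(names(targets), function(m) {
    tg <- targets[[m]]
    cal <- calibrate_lognormal(tg$fraction, tg$limit, tg$max,
                               n = max(sizes[[m]], 2L))
    c(cal, list(family = "lognormal", trunc_max = trunc_factor * tg$max))
  })
  names(marginals) <- names(targets)

  if (is.null(rho_milk_child_urine))
    rho_milk_child_urine <- rho_for_target_r2(
      target_r2_child, marginals$breastmilk$sdlog,
      marginals$child_urine$sdlog)
  if (is.null(rho_milk_mother_urine))
    rho_milk_mother_urine <- rho_for_target_r2(
      target_r2_mother, marginals$breastmilk$sdlog,
      marginals$mother_urine$sdlog)
  for (r in c(rho_milk_child_urine, rho_milk_mother_urine))
    if (abs(r) >= 1) hg_error("|rho| must be < 1", "hg_config_error")

  structure(list(
    seed = as.integer(seed), sizes = sizes, marginals = marginals,
    rho = c(child_urine = rho_milk_child_urine,
            mother_urine = rho_milk_mother_urine),
    bbox = bbox, nondetect_prob = nd,
    food = list(max = food_max, meanlog = food_meanlog, sdlog = food_sdlog),
    rng = HG_RNG_KIND), class = "hg_generator_config")
}

#' Read a generator configuration from YAML
#'
#' Top-level keys mirror the arguments of [generator_config()]; unlisted
#' keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `hg_generator_config`.
#' @export
generator_config_from_yaml <- function(path) {
  if (!file.exists(path))
    hg_error(paste0("config file not found: ", path), "hg_io_error")
  args <- yaml::read_yaml(path)
  for (nm in c("sizes", "bbox", "nondetect_prob"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  do.call(generator_config, args)
}

# draw lognormal values from latent standard-normal scores, rejecting and
# redrawing (the marginal score only) above the truncation maximum
draw_truncated <- function(z, marg) {
  v <- exp(marg$meanlog + marg$sdlog * z)
  bad <- which(v > marg$trunc_max)
  while (length(bad)) {
    z2 <- stats::rnorm(length(bad))
    v[bad] <- exp(marg$meanlog + marg$sdlog * z2)
    bad <- bad[v[bad] > marg$trunc_max]
  }
  v
}

apply_nondetect <- function(v, p) {
  if (p > 0) v[stats::runif(length(v)) < p] <- 0
  v
}

#' Generate food records entirely below the permissible limit
#'
#' Mirrors the campaign's food result: every household wheat sample below
#' the 100 ug/kg WHO/FAO limit, with the sample maximum pinned exactly at
#' `max_target` (one record carries it). Remaining values are lognormal
#' draws rejected-and-redrawn at `max_target`.
#'
#' @param n Number of food records.
#' @param max_target Pinned maximum, must be below `limit`.
#' @param household_ids Optional character ids (length `n`).
#' @param limit Permissible food limit (default 100 ug/kg).
#' @param meanlog,sdlog Lognormal parameters of the bulk of the values.
#' @param seed Optional seed; if `NULL` the ambient RNG state is used (as
#'   when called from [generate_cohort()]).
#' @return A data.frame of food sample records (`group = "household"`).
#' @export
generate_food_below_limit <- function(n, max_target = 44.44,
                                      household_ids = NULL, limit = 100,
                                      meanlog = log(8), sdlog = 0.8,
                                      seed = NULL) {
  if (max_target >= limit)
    hg_error("max_target must be below the permissible food limit",
             "hg_config_error")
  if (n < 1) hg_error("n must be >= 1", "hg_config_error")
  draw <- function() {
    v <- stats::rlnorm(n, meanlog, sdlog)
    bad <- which(v >= max_target)
    while (length(bad)) {
      v[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
      bad <- bad[v[bad] >= max_target]
    }
    v[sample.int(n, 1L)] <- max_target
    v
  }
  v <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (is.null(household_ids)) household_ids <- sprintf("H%04d", seq_len(n))
  data.frame(subject_id = household_ids, group = "household",
             matrix = "food", value = v, unit = "ug_per_kg",
             latitude = NA_real_, longitude = NA_real_,
             linked_mother_id = NA_character_,
             linked_household_id = household_ids,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed seed. Mothers are drawn first; each mother has
#' one household with a uniform GPS point inside the configured bounding
#' box, shared by all of her (and her infant's) records. Breastmilk, mother
#' urine and child urine come from a trivariate Gaussian copula on the log
#' scale (milk-urine latent correlations from the config); blood is
#' independent; food uses [generate_food_below_limit()]. Values above the
#' truncation maximum are redrawn; non-detects are recorded as value 0 with
#' the configured per-matrix probability.
#'
#' @param cfg An `hg_generator_config`.
#' @return An `hg_cohort` whose provenance records the seed.
#' @export
#' @examples
#' ds <- generate_cohort(generator_config(seed = 1))
#' matrix_counts(ds)
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "hg_generator_config"))
  with_seed(cfg$seed, {
    sz <- cfg$sizes
    n_mothers <- max(sz[["breastmilk"]], sz[["blood"]], sz[["mother_urine"]])
    if (n_mothers < 1)
      hg_error("config generates no mother-side samples", "hg_config_error")
    if (sz[["child_urine"]] > n_mothers)
      hg_error("more children than mothers to link them to",
               "hg_config_error")
    wid <- max(4L, nchar(n_mothers))
    mid <- sprintf(paste0("M%0", wid, "d"), seq_len(n_mothers))
    hid <- sprintf(paste0("H%0", wid, "d"), seq_len(n_mothers))
    lat <- stats::runif(n_mothers, cfg$bbox[["lat_min"]], cfg$bbox[["lat_max"]])
    lon <- stats::runif(n_mothers, cfg$bbox[["lon_min"]], cfg$bbox[["lon_max"]])

    # latent trivariate copula scores per mother
    z_milk <- stats::rnorm(n_mothers)
    r_cu <- cfg$rho[["child_urine"]]
    r_mu <- cfg$rho[["mother_urine"]]
    z_cu <- r_cu * z_milk + sqrt(1 - r_cu^2) * stats::rnorm(n_mothers)
    z_mu <- r_mu * z_milk + sqrt(1 - r_mu^2) * stats::rnorm(n_mothers)

    rec <- list()
    pick <- function(k) sort(sample.int(n_mothers, k))
    i_milk <- pick(sz[["breastmilk"]])

    if (sz[["breastmilk"]] > 0) {
      i <- i_milk
      v <- apply_nondetect(draw_truncated(z_milk[i], cfg$marginals$breastmilk),
                           cfg$nondetect_prob[["breastmilk"]])
      rec$milk <- data.frame(subject_id = mid[i], group = "mother",
                             matrix = "breastmilk", value = v,
                             unit = "ug_per_L", latitude = lat[i],
                             longitude = lon[i],
                             linked_mother_id = NA_character_,
                             linked_household_id = hid[i],
                             stringsAsFactors = FALSE)
    }
    if (sz[["blood"]] > 0) {
      i <- pick(sz[["blood"]])
      v <- apply_nondetect(
        draw_truncated(stats::rnorm(length(i)), cfg$marginals$blood),
        cfg$nondetect_prob[["blood"]])
      rec$blood <- data.frame(subject_id = mid[i], group = "mother",
                              matrix = "blood", value = v,
                              unit = "ug_per_L", latitude = lat[i],
                              longitude = lon[i],
                              linked_mother_id = NA_character_,
                              linked_household_id = hid[i],
                              stringsAsFactors = FALSE)
    }
    if (sz[["mother_urine"]] > 0) {
      i <- pick(sz[["mother_urine"]])
      v <- apply_nondetect(
        draw_truncated(z_mu[i], cfg$marginals$mother_urine),
        cfg$nondetect_prob[["mother_urine"]])
      rec$murine <- data.frame(subject_id = mid[i], group = "mother",
                               matrix = "mother_urine", value = v,
                               unit = "ug_per_L", latitude = lat[i],
                               longitude = lon[i],
                               linked_mother_id = NA_character_,
                               linked_household_id = hid[i],
                               stringsAsFactors = FALSE)
    }
    if (sz[["child_urine"]] > 0) {
      # studied infants belong to the milk-donating mothers where possible,
      # so milk-child-urine pairs and the infant intake route are complete
      i <- if (sz[["child_urine"]] <= length(i_milk))
        sort(sample(i_milk, sz[["child_urine"]])) else pick(sz[["child_urine"]])
      cid <- sub("^M", "C", mid[i])
      v <- apply_nondetect(
        draw_truncated(z_cu[i], cfg$marginals$child_urine),
        cfg$nondetect_prob[["child_urine"]])
      rec$curine <- data.frame(subject_id = cid, group = "infant",
                               matrix = "child_urine", value = v,
                               unit = "ug_per_L", latitude = lat[i],
                               longitude = lon[i],
                               linked_mother_id = mid[i],
                               linked_household_id = hid[i],
                               stringsAsFactors = FALSE)
    }
    if (sz[["food"]] > 0) {
      if (sz[["food"]] > n_mothers)
        hg_error("more food samples than households", "hg_config_error")
      i <- pick(sz[["food"]])
      food <- generate_food_below_limit(length(i), cfg$food$max,
                                        household_ids = hid[i],
                                        meanlog = cfg$food$meanlog,
                                        sdlog = cfg$food$sdlog)
      food <- apply_nondetect_df(food, cfg$nondetect_prob[["food"]])
      food$latitude <- lat[i]
      food$longitude <- lon[i]
      rec$food <- food
    }
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
    as_cohort(records,
              provenance = paste0("generator seed ", cfg$seed))
  })
}

apply_nondetect_df <- function(df, p) {
  df$value <- apply_nondetect(df$value, p)
  df
}
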