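#' Parameter uncertainty distributions
#'
#' Published model inputs arrive as a point estimate plus a 95% range, with
#' a distribution family chosen by parameter type: beta for probabilities
#' and utilities, gamma for costs, lognormal for hazard ratios. The fitting
#' functions below convert (mean, 95% range) into the family's
#' hyper-parameters. Throughout, the 95% range is treated as a
#' normal-approximation confidence interval, so the standard error is
#' (high - low) / 3.92.
#'
#' @name distribution-fitting
NULL

Z95 <- 1.96        # normal 97.5% quantile, at the precision ranges are printed
RANGE_TO_SE <- 3.92  # divide a 95% range width by this to get an SE

new_dist_spec <- function(family, mean, low95, high95, par1, par2,
                          negate = FALSE, truncate = NULL) {
  structure(
    list(family = family, mean = mean, low95 = low95, high95 = high95,
         par1 = par1, par2 = par2, negate = negate, truncate = truncate,
         degenerate = isTRUE(all.equal(low95, high95))),
    class = "bbtnbc_dist"
  )
}

#' Fit a beta distribution from a mean and 95% range
#'
#' Method-of-moments fit: with se = (high95 - low95)/3.92, the shape
#' parameters are a = m (m(1-m)/se^2 - 1) and b = (1-m)(m(1-m)/se^2 - 1),
#' so the fitted mean a/(a+b) recovers the input mean exactly. A zero-width
#' range yields a degenerate (point-mass) spec.
#'
#' @param mean point estimate in (0, 1).
#' @param low95,high95 bounds of the 95% range.
#' @return an object of class `bbtnbc_dist` with shape parameters in
#'   `par1` (a) and `par2` (b).
#' @export
fit_beta <- function(mean, low95, high95) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("fit_beta: mean must lie strictly inside (0, 1), got ", mean)
  if (high95 < low95)
    stop("fit_beta: high95 < low95")
  se <- (high95 - low95) / RANGE_TO_SE
  if (se == 0)
    return(new_dist_spec("beta", mean, low95, high95, Inf, Inf))
  if (se^2 >= mean * (1 - mean))
    stop("fit_beta: infeasible moments, se^2 = ", se^2,
         " >= mean(1-mean) = ", mean * (1 - mean))
  nu <- mean * (1 - mean) / se^2 - 1
  new_dist_spec("beta", mean, low95, high95, mean * nu, (1 - mean) * nu)
}

#' Fit a gamma distribution from a mean and standard error
#'
#' shape = (mean/se)^2, scale = se^2/mean, so the fitted mean and variance
#' equal the inputs exactly. Cost parameters use se = 10% of the mean,
#' which is equivalent to fitting from their printed 95% ranges.
#'
#' @param mean point estimate (> 0), typically AUD.
#' @param se standard error (>= 0); 0 gives a point mass.
#' @return a `bbtnbc_dist` with shape in `par1` and scale in `par2`.
#' @export
fit_gamma <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0)
    stop("fit_gamma: mean must be positive, got ", mean)
  if (se < 0)
    stop("fit_gamma: se must be non-negative, got ", se)
  low <- mean - Z95 * se
  high <- mean + Z95 * se
  if (se == 0)
    return(new_dist_spec("gamma", mean, low, high, Inf, 0))
  new_dist_spec("gamma", mean, low, high, (mean / se)^2, se^2 / mean)
}

#' Fit a lognormal distribution for a hazard ratio
#'
#' Parameterised so the point estimate is the distribution's median
#' (standard for ratio estimates from proportional-hazards models):
#' meanlog = log(hr), sdlog = (log(high95) - log(low95))/3.92.
#'
#' @param hr point estimate (> 0).
#' @param low95,high95 95% confidence bounds (> 0).
#' @return a `bbtnbc_dist` with meanlog in `par1` and sdlog in `par2`.
#' @export
fit_lognormal <- function(hr, low95, high95) {
  if (any(c(hr, low95, high95) <= 0))
    stop("fit_lognormal: hr and bounds must be positive")
  if (!(low95 <= hr && hr <= high95))
    stop("fit_lognormal: require low95 <= hr <= high95")
  new_dist_spec("lognormal", hr, low95, high95,
                log(hr), (log(high95) - log(low95)) / RANGE_TO_SE)
}

#' Fit a (truncated) normal distribution from a mean and 95% range
#'
#' Used for the terminal-cycle utility decrement, whose printed range
#' crosses zero and so admits no beta fit. Draws are truncated to
#' `truncate` (default [-1, 1], the plausible span of a utility decrement).
#'
#' @param mean point estimate.
#' @param low95,high95 bounds of the 95% range.
#' @param truncate length-2 numeric truncation interval.
#' @return a `bbtnbc_dist` with mean in `par1` and sd in `par2`.
#' @export
fit_normal <- function(mean, low95, high95, truncate = c(-1, 1)) {
  if (high95 < low95) stop("fit_normal: high95 < low95")
  se <- (high95 - low95) / RANGE_TO_SE
  new_dist_spec("normal", mean, low95, high95, mean, se, truncate = truncate)
}

#' Sample from a fitted distribution
#'
#' Uses the current RNG state. Degenerate (zero-width) specs return the
#' point estimate without consuming random numbers, so switching a
#' parameter between fixed and sampled does not shift other draws taken
#' from a dedicated sub-stream.
#'
#' @param spec a `bbtnbc_dist`.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "bbtnbc_dist"))
  if (spec$degenerate) return(rep(spec$mean, n))
  x <- switch(spec$family,
    beta      = stats::rbeta(n, spec$par1, spec$par2),
    gamma     = stats::rgamma(n, shape = spec$par1, scale = spec$par2),
    lognormal = stats::rlnorm(n, meanlog = spec$par1, sdlog = spec$par2),
    normal    = {
      tr <- if (is.null(spec$truncate)) c(-Inf, Inf) else spec$truncate
      lo <- stats::pnorm(tr[1], spec$par1, spec$par2)
      hi <- stats::pnorm(tr[2], spec$par1, spec$par2)
      stats::qnorm(stats::runif(n, lo, hi), spec$par1, spec$par2)
    },
    stop("unknown family: ", spec$family)
  )
  if (spec$negate) -x else x
}

#' Fit the distribution for one parameter-table row
#'
#' Dispatches on the `family` column. A beta row with a negative mean
#' (a utility decrement) is fit to the magnitude |mean| with the range
#' magnitudes swapped accordingly, and draws are negated.
#'
#' @param family one of "beta", "gamma", "lognormal", "normal".
#' @param mean,low95,high95 row values as printed.
#' @return a `bbtnbc_dist`.
#' @export
fit_spec <- function(family, mean, low95, high95) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "normal"))
  if (family == "beta" && mean < 0) {
    spec <- fit_beta(-mean, -high95, -low95)
    spec$negate <- TRUE
    spec$mean <- mean
    spec$low95 <- low95
    spec$high95 <- high95
    return(spec)
  }
  switch(family,
    beta      = fit_beta(mean, low95, high95),
    gamma     = fit_gamma(mean, (high95 - low95) / RANGE_TO_SE),
    lognormal = fit_lognormal(mean, low95, high95),
    normal    = fit_normal(mean, low95, high95)
  )
}

#' Analytic mean of a fitted distribution
#'
#' For the lognormal the reported central value is the median (the fitting
#' convention for hazard ratios); all other families report the mean.
#'
#' @param spec a `bbtnbc_dist`.
#' @return scalar central value.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "bbtnbc_dist"))
  if (spec$degenerate) return(spec$mean)
  m <- switch(spec$family,
    beta      = spec$par1 / (spec$par1 + spec$par2),
    gamma     = spec$par1 * spec$par2,
    lognormal = exp(spec$par1),          # median convention
    normal    = spec$par1                # untruncated mean; truncation is wide
  )
  if (spec$negate) -m else m
}

#' Load the published parameter table
#'
#' Reads the packaged CSV mirroring the published table of model parameters
#' (name, family, mean, 95% range), or a user-supplied file in the same
#' format.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return data.frame with columns name, family, mean, low95, high95.
#' @export
parameter_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_parameters.csv",
                        package = "bbtnbc", mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "family", "mean", "low95", "high95")
  if (!all(need %in% names(tbl)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (any(tbl$low95 > tbl$mean | tbl$mean > tbl$high95))
    stop("parameter table: require low95 <= mean <= high95 in every row")
  tbl
}

#' Fit distributions for every row of a parameter table
#'
#' @param tbl data.frame as returned by [parameter_table()].
#' @return named list of `bbtnbc_dist` objects.
#' @export
fit_parameter_table <- function(tbl) {
  specs <- lapply(seq_len(nrow(tbl)), function(i)
    fit_spec(tbl$family[i], tbl$mean[i], tbl$low95[i], tbl$high95[i]))
  names(specs) <- tbl$name
  specs
}

#' Construct the scalar parameter set for one model run
#'
#' Defaults are the base-case values: annual TNBC death probability 0.039,
#' hazard ratio 0.66 under beta-blockade, utility decrements -0.024
#' (alive with TNBC) and -0.11 (terminal cycle), population-average
#' utility 0.90 for evLY valuation, propranolol at AUD 113.95/year,
#' year-since-diagnosis management costs (42,409; 8,745; 3,487; 3,595;
#' 2,839), terminal TNBC cost 44,327, non-TNBC death cost 5,844, 5%
#' annual discounting, WTP AUD 28,000/QALY, eligibility exclusions of
#' 14.8% (already on beta-blockers) and 20% (contraindicated), censoring
#' at age 85. All costs are 2022 AUD.
#'
#' @param p_tnbc_death annual probability of TNBC-specific death.
#' @param hr_treatment hazard ratio for TNBC death under beta-blockers.
#' @param u_decrement_tnbc utility decrement while alive with TNBC (<= 0).
#' @param u_decrement_terminal extra decrement in the TNBC death cycle.
#' @param u_population_average population utility for evLY valuation.
#' @param c_drug_annual annual drug cost (AUD/year).
#' @param c_mgmt_by_year length-5 vector of management costs for years
#'   1..5 since diagnosis (AUD/year).
#' @param c_mgmt_beyond_5y annual management cost after year 5.
#' @param c_terminal_tnbc cost of the terminal TNBC year (AUD).
#' @param c_death_other cost of a non-TNBC death (AUD).
#' @param discount_rate annual discount rate (fraction).
#' @param wtp willingness-to-pay threshold (AUD/QALY).
#' @param frac_already_on_bb fraction excluded as already treated.
#' @param frac_contraindicated fraction excluded as contraindicated.
#' @param max_age censoring age (years).
#' @return an object of class `bbtnbc_params`.
#' @export
tnbc_parameters <- function(p_tnbc_death = 0.039,
                            hr_treatment = 0.66,
                            u_decrement_tnbc = -0.024,
                            u_decrement_terminal = -0.110,
                            u_population_average = 0.90,
                            c_drug_annual = 113.95,
                            c_mgmt_by_year = c(42409, 8745, 3487, 3595, 2839),
                            c_mgmt_beyond_5y = 0,
                            c_terminal_tnbc = 44327,
                            c_death_other = 5844,
                            discount_rate = 0.05,
                            wtp = 28000,
                            frac_already_on_bb = 0.148,
                            frac_contraindicated = 0.20,
                            max_age = 85) {
  p <- structure(
    list(p_tnbc_death = p_tnbc_death,
         hr_treatment = hr_treatment,
         u_decrement_tnbc = u_decrement_tnbc,
         u_decrement_terminal = u_decrement_terminal,
         u_population_average = u_population_average,
         c_drug_annual = c_drug_annual,
         c_mgmt_by_year = c_mgmt_by_year,
         c_mgmt_beyond_5y = c_mgmt_beyond_5y,
         c_terminal_tnbc = c_terminal_tnbc,
         c_death_other = c_death_other,
         discount_rate = discount_rate,
         wtp = wtp,
         frac_already_on_bb = frac_already_on_bb,
         frac_contraindicated = frac_contraindicated,
         max_age = max_age),
    class = "bbtnbc_params"
  )
  validate_parameters(p)
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "bbtnbc_params"))
  with(p, {
    if (p_tnbc_death < 0 || p_tnbc_death > 1)
      stop("p_tnbc_death must lie in [0, 1]")
    if (hr_treatment <= 0) stop("hr_treatment must be positive")
    if (u_decrement_tnbc > 0) stop("u_decrement_tnbc must be <= 0")
    if (u_population_average < 0 || u_population_average > 1)
      stop("u_population_average must lie in [0, 1]")
    costs <- c(c_drug_annual, c_mgmt_by_year, c_mgmt_beyond_5y,
               c_terminal_tnbc, c_death_other)
    if (any(costs < 0)) stop("costs must be non-negative")
    if (length(c_mgmt_by_year) != 5)
      stop("c_mgmt_by_year must have one entry per year 1..5")
    if (discount_rate < 0) stop("discount_rate must be >= 0")
    if (frac_already_on_bb < 0 || frac_already_on_bb > 1 ||
        frac_contraindicated < 0 || frac_contraindicated > 1)
      stop("exclusion fractions must lie in [0, 1]")
  })
  p
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced; used by the
#' scenario and sensitivity machinery so each variation differs from base
#' in exactly the stated fields.
#'
#' @param params a `bbtnbc_params`.
#' @param ... named replacements.
#' @return a validated `bbtnbc_params`.
#' @export
modify_parameters <- function(params, ...) {
  stopifnot(inherits(params, "bbtnbc_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params[names(repl)] <- repl
  validate_parameters(params)
}
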