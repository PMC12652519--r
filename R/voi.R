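#' Expected value of perfect information
#'
#' Non-parametric EVPI from the PSA draws: the gap between the expected
#' net monetary benefit under perfect information (choosing the best
#' strategy in every draw) and under current information (choosing the
#' strategy with the best expected net benefit). Scaled to the eligible
#' population over the technology horizon.
#'
#' @name value-of-information
NULL

per_person_nmb <- function(psa, wtp) {
  n <- psa$n_treated
  list(
    standard = (wtp * psa$draws$qaly_std - psa$draws$cost_std) / n,
    intervention = (wtp * psa$draws$qaly_int - psa$draws$cost_int) / n
  )
}

#' Per-person EVPI at one willingness-to-pay value
#'
#' EVPI = mean_i max_j NMB_ij - max_j mean_i NMB_ij, with per-person net
#' monetary benefit obtained by dividing the population-level arm totals
#' by the treated cohort size. Non-negative by construction (Jensen-type
#' inequality of max over mean), and zero when one strategy is optimal in
#' every draw.
#'
#' @param psa a `bbtnbc_psa` with per-draw arm totals.
#' @param wtp willingness-to-pay (AUD/QALY).
#' @return per-person EVPI in AUD.
#' @export
evpi_per_person <- function(psa, wtp = psa$wtp) {
  stopifnot(inherits(psa, "bbtnbc_psa"))
  if (nrow(psa$draws) == 0) stop("empty PSA: no draws available")
  nmb <- per_person_nmb(psa, wtp)
  mean(pmax(nmb$standard, nmb$intervention)) -
    max(mean(nmb$standard), mean(nmb$intervention))
}

#' Population EVPI over the technology horizon
#'
#' Per-person EVPI scaled by the annual eligible cohort and the number of
#' years the technology is assumed current (default 10, i.e. annual
#' cohorts of newly diagnosed women over a decade). Future cohorts are
#' not discounted by default, matching the convention that the population
#' multiplier is a simple head count; set `discount_rate > 0` for
#' discounted accrual.
#'
#' @param evpi_pp per-person EVPI (AUD).
#' @param annual_cohort women commencing treatment per year.
#' @param horizon_years technology lifetime (years).
#' @param discount_rate annual rate for discounted accrual (default 0).
#' @return population EVPI in AUD.
#' @export
population_evpi <- function(evpi_pp, annual_cohort, horizon_years,
                            discount_rate = 0) {
  if (annual_cohort < 0 || horizon_years < 0)
    stop("annual_cohort and horizon_years must be non-negative")
  if (discount_rate == 0) return(evpi_pp * annual_cohort * horizon_years)
  evpi_pp * annual_cohort *
    sum((1 + discount_rate)^(-(seq_len(horizon_years) - 1)))
}

#' EVPI curve over a willingness-to-pay grid
#'
#' @param psa a `bbtnbc_psa`.
#' @param wtp_grid non-empty grid of non-negative WTP values.
#' @param annual_cohort women commencing treatment per year (defaults to
#'   the PSA's treated cohort size).
#' @param horizon_years technology lifetime (years).
#' @param discount_rate annual rate for discounted population accrual.
#' @return data.frame with columns wtp, evpi_per_person,
#'   evpi_population; plot-ready.
#' @export
evpi_curve <- function(psa, wtp_grid = seq(0, 56000, by = 2000),
                       annual_cohort = psa$n_treated, horizon_years = 10,
                       discount_rate = 0) {
  stopifnot(length(wtp_grid) > 0, all(wtp_grid >= 0))
  pp <- vapply(wtp_grid, function(l) evpi_per_person(psa, l), numeric(1))
  data.frame(
    wtp = wtp_grid,
    evpi_per_person = pp,
    evpi_population = vapply(pp, population_evpi, numeric(1),
                             annual_cohort = annual_cohort,
                             horizon_years = horizon_years,
                             discount_rate = discount_rate)
  )
}
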