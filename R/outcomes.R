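#' Discounting, outcome aggregation and incremental comparison
#'
#' Per-cycle accruals from the cohort trace are discounted at the annual
#' rate with mid-cycle timing, summed into arm-level totals (life years,
#' QALYs, cost components), valued as evLYs, and compared between arms as
#' an ICER with dominance classification and net monetary benefit.
#'
#' @name outcomes
NULL

#' Discount a per-cycle series
#'
#' Flows accrue mid-cycle (consistent with half-cycle-corrected accrual),
#' so cycle t (0-based) is discounted by (1 + rate)^-(t + 0.5). With
#' `timing = "end"` the conventional end-of-cycle factor
#' (1 + rate)^-(t + 1) is used instead. Rate 0 returns the raw sum.
#'
#' @param values per-cycle amounts, cycle 0 first.
#' @param rate annual discount rate (>= 0).
#' @param timing "mid" (default) or "end".
#' @return the discounted sum.
#' @export
discount_series <- function(values, rate, timing = c("mid", "end")) {
  timing <- match.arg(timing)
  if (rate < 0) stop("discount rate must be >= 0")
  if (length(values) == 0) return(0)
  t <- seq_along(values) - 1
  shift <- if (timing == "mid") 0.5 else 1
  sum(values * (1 + rate)^(-(t + shift)))
}

#' Summarise a cohort trace into arm-level totals
#'
#' @param trace a `bbtnbc_trace` from [run_cohort()].
#' @param params a `bbtnbc_params` (supplies the discount rate).
#' @param timing discount timing passed to [discount_series()].
#' @return a `bbtnbc_arm` list with discounted totals `yll` (life
#'   years), `qaly`, `cost_drug`, `cost_mgmt`, `cost_terminal`,
#'   `cost_other`, `cost_total`, and undiscounted counterparts
#'   `ly_undisc`, `qaly_undisc`, `cost_undisc`.
#' @export
summarize_arm <- function(trace, params, timing = "mid") {
  tr <- as.data.frame(trace)
  r <- params$discount_rate
  d <- function(col) discount_series(tr[[col]], r, timing)
  cost_cols <- c("cost_drug", "cost_mgmt", "cost_terminal", "cost_other")
  out <- list(
    yll = d("ly"),
    qaly = d("qaly"),
    cost_drug = d("cost_drug"),
    cost_mgmt = d("cost_mgmt"),
    cost_terminal = d("cost_terminal"),
    cost_other = d("cost_other"),
    ly_undisc = sum(tr$ly),
    qaly_undisc = sum(tr$qaly),
    cost_drug_undisc = sum(tr$cost_drug),
    cost_undisc = sum(unlist(tr[cost_cols]))
  )
  out$cost_total <- out$cost_drug + out$cost_mgmt +
    out$cost_terminal + out$cost_other
  structure(out, class = "bbtnbc_arm")
}

#' Sum arm results over cohorts
#'
#' Element-wise sum of `bbtnbc_arm` totals, used to aggregate per-band
#' (or per-stage) runs into a population result.
#'
#' @param arms list of `bbtnbc_arm` objects.
#' @return a `bbtnbc_arm`.
#' @export
aggregate_arms <- function(arms) {
  stopifnot(length(arms) > 0, all(vapply(arms, inherits, TRUE, "bbtnbc_arm")))
  fields <- names(arms[[1]])
  out <- lapply(fields, function(f)
    sum(vapply(arms, function(a) a[[f]], numeric(1))))
  names(out) <- fields
  structure(out, class = "bbtnbc_arm")
}

#' Equal-value life-year totals for two arms
#'
#' Incremental survival is valued at the population-average utility
#' rather than the diseased-state utility: with the longer-lived arm
#' called the extender, evLY(comparator) = QALY(comparator) and
#' evLY(extender) = QALY(comparator) + u * (YLL(extender) -
#' YLL(comparator)). The increment is therefore u * dYLL regardless of
#' which arm lives longer.
#'
#' @param standard,intervention `bbtnbc_arm` objects.
#' @param u_population_average population-average utility in [0, 1].
#' @return list with `evly_standard`, `evly_intervention`, `d_evly`.
#' @export
evly_totals <- function(standard, intervention, u_population_average) {
  d_yll <- intervention$yll - standard$yll
  if (d_yll >= 0) {
    evly_std <- standard$qaly
    evly_int <- standard$qaly + u_population_average * d_yll
  } else {
    evly_int <- intervention$qaly
    evly_std <- intervention$qaly + u_population_average * (-d_yll)
  }
  list(evly_standard = evly_std, evly_intervention = evly_int,
       d_evly = evly_int - evly_std)
}

#' Incremental comparison of two arms
#'
#' Computes incremental discounted cost, life years, QALYs and evLYs, the
#' ICER per QALY and per evLY, the dominance status from the sign pattern
#' of (dQALY, dcost), and net monetary benefit at the willingness-to-pay
#' threshold. A dominant strategy's ICER is still reported as its signed
#' value alongside the status flag.
#'
#' @param standard,intervention `bbtnbc_arm` objects.
#' @param wtp willingness-to-pay threshold (AUD/QALY).
#' @param u_population_average utility for the evLY valuation.
#' @return a `bbtnbc_comparison` list with d_yll, d_qaly, d_evly,
#'   d_cost, icer_qaly, icer_evly, status, nmb.
#' @export
compare_arms <- function(standard, intervention, wtp = 28000,
                         u_population_average = 0.90) {
  d_yll <- intervention$yll - standard$yll
  d_qaly <- intervention$qaly - standard$qaly
  d_cost <- intervention$cost_total - standard$cost_total
  ev <- evly_totals(standard, intervention, u_population_average)
  eps <- 1e-12
  status <-
    if (abs(d_qaly) < eps && abs(d_cost) < eps) "equivalent"
    else if (d_qaly > 0 && d_cost < 0) "dominant"
    else if (d_qaly < 0 && d_cost > 0) "dominated"
    else if (d_cost >= 0) "tradeoff-NE"
    else "tradeoff-SW"
  structure(list(
    d_yll = d_yll, d_qaly = d_qaly, d_evly = ev$d_evly, d_cost = d_cost,
    icer_qaly = if (abs(d_qaly) > eps) d_cost / d_qaly else NA_real_,
    icer_evly = if (abs(ev$d_evly) > eps) d_cost / ev$d_evly else NA_real_,
    status = status,
    nmb = wtp * d_qaly - d_cost,
    wtp = wtp
  ), class = "bbtnbc_comparison")
}

#' @export
print.bbtnbc_comparison <- function(x, ...) {
  cat(sprintf("Incremental results (intervention - standard):\n"))
  cat(sprintf("  life years   %12.1f\n", x$d_yll))
  cat(sprintf("  QALYs        %12.1f\n", x$d_qaly))
  cat(sprintf("  evLYs        %12.1f\n", x$d_evly))
  cat(sprintf("  cost (AUD)   %12.0f\n", x$d_cost))
  icer <- if (is.na(x$icer_qaly)) "undefined"
    else sprintf("%.0f%s", x$icer_qaly,
                 if (x$status == "dominant") " (Dominant)" else "")
  cat(sprintf("  ICER AUD/QALY %11s\n", icer))
  cat(sprintf("  NMB at %s:  %10.0f\n", format(x$wtp, big.mark = ","), x$nmb))
  invisible(x)
}
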