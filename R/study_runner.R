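#' Published-analysis orchestration
#'
#' Runs the full set of reported analyses over the two-arm model: base
#' case (six 5-year age bands aggregated), per-band and disease-stage
#' sub-groups, six scenario analyses, and the trial sample-size
#' calculation. Probabilistic analyses live in [run_psa()] and
#' [evpi_curve()].
#'
#' @name study-runner
NULL

#' Disease-stage mix and stage-specific inputs
#'
#' Fractions of the cohort by stage at diagnosis (60.5% localized,
#' 35.6% regional, 3.9% distant) with stage-specific annual TNBC death
#' probabilities and treatment hazard ratios. Management costs are not
#' stage-specific.
#'
#' @return data.frame with columns stage, fraction, p_tnbc, hr.
#' @export
stage_mix <- function() {
  data.frame(
    stage = c("localized", "regional", "distant"),
    fraction = c(0.605, 0.356, 0.039),
    p_tnbc = c(0.017, 0.066, 0.290),
    hr = c(0.86, 0.54, 0.69),
    stringsAsFactors = FALSE
  )
}

#' Evaluate both arms for an eligible cohort
#'
#' Runs standard-care and intervention traces for every age band of the
#' cohort and aggregates to population totals.
#'
#' @param cohort data.frame from [eligible_population()] (columns
#'   entry_age, n_entry).
#' @param params a `bbtnbc_params`.
#' @param schedule a `bbtnbc_schedule`.
#' @return list with `standard` and `intervention` (`bbtnbc_arm`
#'   totals) and `per_band` (list of per-band arm pairs).
#' @export
evaluate_arms <- function(cohort, params, schedule) {
  per_band <- lapply(seq_len(nrow(cohort)), function(i) {
    std <- summarize_arm(run_cohort(cohort$n_entry[i], cohort$entry_age[i],
                                    "standard", params, schedule), params)
    int <- summarize_arm(run_cohort(cohort$n_entry[i], cohort$entry_age[i],
                                    "intervention", params, schedule), params)
    list(standard = std, intervention = int)
  })
  names(per_band) <- if (!is.null(cohort$band)) cohort$band else
    as.character(cohort$entry_age)
  list(
    standard = aggregate_arms(lapply(per_band, `[[`, "standard")),
    intervention = aggregate_arms(lapply(per_band, `[[`, "intervention")),
    per_band = per_band
  )
}

#' Run the base case
#'
#' Both arms over all six age bands of the eligible cohort, aggregated,
#' with the incremental comparison and per-patient values.
#'
#' @param schedule a `bbtnbc_schedule`.
#' @param params a `bbtnbc_params`.
#' @return a `bbtnbc_basecase` list: cohort, standard, intervention,
#'   comparison, per_patient (list of per-treated-woman increments),
#'   n_treated.
#' @export
run_base_case <- function(schedule, params = tnbc_parameters()) {
  cohort <- eligible_population(schedule, params)
  arms <- evaluate_arms(cohort, params, schedule)
  cmp <- compare_arms(arms$standard, arms$intervention, params$wtp,
                      params$u_population_average)
  n <- attr(cohort, "total")
  structure(list(
    cohort = cohort,
    standard = arms$standard,
    intervention = arms$intervention,
    per_band = arms$per_band,
    comparison = cmp,
    n_treated = n,
    per_patient = list(
      yll_gained = cmp$d_yll / n,
      qalys_gained = cmp$d_qaly / n,
      evlys_gained = cmp$d_evly / n,
      drug_cost = arms$intervention$cost_drug_undisc / n,
      health_cost_change = cmp$d_cost / n
    )
  ), class = "bbtnbc_basecase")
}

#' Per-age-band sub-group analysis
#'
#' @inheritParams run_base_case
#' @return data.frame, one row per band: band, n_entry, d_yll, d_qaly,
#'   drug_cost, d_cost, icer_qaly, status.
#' @export
run_age_subgroup <- function(schedule, params = tnbc_parameters()) {
  cohort <- eligible_population(schedule, params)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    arms <- evaluate_arms(cohort[i, , drop = FALSE], params, schedule)
    cmp <- compare_arms(arms$standard, arms$intervention, params$wtp,
                        params$u_population_average)
    data.frame(band = cohort$band[i], n_entry = cohort$n_entry[i],
               d_yll = cmp$d_yll, d_qaly = cmp$d_qaly,
               drug_cost = arms$intervention$cost_drug_undisc,
               d_cost = cmp$d_cost, icer_qaly = cmp$icer_qaly,
               status = cmp$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Disease-stage sub-group analysis
#'
#' Allocates the eligible cohort across stages by the stage mix, re-runs
#' both arms with stage-specific TNBC mortality and hazard ratio, and
#' keeps the cost schedule unchanged (treatment costs are not varied by
#' stage, so stage differences are driven solely by survival).
#'
#' @inheritParams run_base_case
#' @param mix data.frame as from [stage_mix()]; fractions must sum to 1.
#' @return data.frame, one row per stage: stage, fraction, n_entry,
#'   d_yll, d_qaly, drug_cost, d_cost, icer_qaly, status.
#' @export
run_stage_subgroup <- function(schedule, params = tnbc_parameters(),
                               mix = stage_mix()) {
  if (abs(sum(mix$fraction) - 1) > 1e-9)
    stop("stage fractions must sum to 1")
  cohort <- eligible_population(schedule, params)
  rows <- lapply(seq_len(nrow(mix)), function(s) {
    sub <- cohort
    sub$n_entry <- cohort$n_entry * mix$fraction[s]
    p_s <- modify_parameters(params, p_tnbc_death = mix$p_tnbc[s],
                             hr_treatment = mix$hr[s])
    arms <- evaluate_arms(sub, p_s, schedule)
    cmp <- compare_arms(arms$standard, arms$intervention, params$wtp,
                        params$u_population_average)
    data.frame(stage = mix$stage[s], fraction = mix$fraction[s],
               n_entry = sum(sub$n_entry),
               d_yll = cmp$d_yll, d_qaly = cmp$d_qaly,
               drug_cost = arms$intervention$cost_drug_undisc,
               d_cost = cmp$d_cost, icer_qaly = cmp$icer_qaly,
               status = cmp$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scenario parameter overrides
#'
#' Each scenario changes exactly one assumption relative to base:
#' \enumerate{
#'   \item discount rate 0%;
#'   \item discount rate 3.5%;
#'   \item smaller treatment effect, risk ratio 0.74 (applied on the
#'     hazard scale like the base-case hazard ratio);
#'   \item carvedilol 12.5 mg twice daily, AUD 258.18/year;
#'   \item propranolol 80 mg twice daily, AUD 227.90/year;
#'   \item breast-cancer management cost extrapolated beyond year five
#'     at AUD 2,838/year for life.
#' }
#'
#' @param id integer 1..6.
#' @return named list of parameter overrides.
#' @export
scenario_overrides <- function(id) {
  switch(as.character(id),
    "1" = list(discount_rate = 0),
    "2" = list(discount_rate = 0.035),
    "3" = list(hr_treatment = 0.74),
    "4" = list(c_drug_annual = 258.18),
    "5" = list(c_drug_annual = 227.90),
    "6" = list(c_mgmt_beyond_5y = 2838),
    stop("unknown scenario id: ", id)
  )
}

#' Run one scenario analysis
#'
#' @inheritParams run_base_case
#' @param id scenario number 1..6 (see [scenario_overrides()]).
#' @return a `bbtnbc_basecase` run under the scenario's parameters, with
#'   the overrides recorded in attribute `overrides`.
#' @export
run_scenario <- function(id, schedule, params = tnbc_parameters()) {
  ov <- scenario_overrides(id)
  res <- run_base_case(schedule, do.call(modify_parameters, c(list(params), ov)))
  attr(res, "overrides") <- ov
  attr(res, "scenario") <- id
  res
}

#' Two-proportion trial sample size
#'
#' Normal-approximation sample size for a 1:1 two-arm trial detecting a
#' difference between proportions p1 and p2: per-group
#' n = ceiling((z_{1-alpha/2} sqrt(2 pbar (1-pbar)) +
#' z_{1-beta} sqrt(p1(1-p1) + p2(1-p2)))^2 / (p1-p2)^2) with
#' pbar = (p1+p2)/2; no continuity correction. Returns the total over
#' both groups.
#'
#' @param p1,p2 event proportions in (0, 1), p1 != p2.
#' @param power target power (default 0.80).
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `n_per_group` and `n_total`.
#' @export
two_proportion_sample_size <- function(p1, p2, power = 0.80, alpha = 0.05) {
  if (any(c(p1, p2) <= 0 | c(p1, p2) >= 1))
    stop("proportions must lie strictly inside (0, 1)")
  if (p1 == p2) stop("infeasible: p1 must differ from p2")
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  pbar <- (p1 + p2) / 2
  num <- (z_a * sqrt(2 * pbar * (1 - pbar)) +
          z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2
  n <- ceiling(num / (p1 - p2)^2)
  list(n_per_group = n, n_total = 2 * n)
}

#' Run a configured analysis
#'
#' Single entry point dispatching on `analysis`: "base",
#' "age_subgroup", "stage_subgroup", "scenario_1" .. "scenario_6",
#' "psa", "evpi", or "samplesize".
#'
#' @param analysis analysis identifier (see above).
#' @param schedule a `bbtnbc_schedule`; defaults to the synthetic
#'   schedule under `synthetic_seed`.
#' @param params a `bbtnbc_params`.
#' @param synthetic_seed seed for [synthesize_schedule()] when no
#'   schedule is supplied.
#' @param psa_n,psa_seed probabilistic-analysis settings.
#' @param wtp_grid willingness-to-pay grid for the EVPI curve.
#' @param ... passed to the underlying analysis function.
#' @return the underlying analysis result object.
#' @export
run_study <- function(analysis, schedule = NULL,
                      params = tnbc_parameters(),
                      synthetic_seed = 1,
                      psa_n = 1000, psa_seed = 1,
                      wtp_grid = seq(0, 56000, by = 2000), ...) {
  if (is.null(schedule))
    schedule <- synthesize_schedule(seed = synthetic_seed, params = params)
  if (grepl("^scenario_[1-6]$", analysis))
    return(run_scenario(as.integer(sub("scenario_", "", analysis)),
                        schedule, params))
  switch(analysis,
    base = run_base_case(schedule, params),
    age_subgroup = run_age_subgroup(schedule, params),
    stage_subgroup = run_stage_subgroup(schedule, params, ...),
    psa = run_psa(n_draws = psa_n, seed = psa_seed, schedule = schedule,
                  params = params, ...),
    evpi = {
      psa <- run_psa(n_draws = psa_n, seed = psa_seed, schedule = schedule,
                     params = params, ...)
      evpi_curve(psa, wtp_grid)
    },
    samplesize = two_proportion_sample_size(0.12, 0.18),
    stop("unknown analysis id: ", analysis)
  )
}
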