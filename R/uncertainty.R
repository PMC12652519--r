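#' Deterministic and probabilistic sensitivity analysis
#'
#' One-way (tornado) analysis re-evaluates the deterministic ICER with
#' each parameter set to its 95% bounds; probabilistic analysis draws all
#' uncertain parameters jointly (independently, from their fitted
#' distributions) and re-evaluates the full two-arm model per draw.
#'
#' @name uncertainty
NULL

# Parameter-table rows sampled in the base-case PSA, mapped to fields of
# the parameter set. Incidence/prevalence schedules are explored in the
# deterministic analysis only.
PSA_PARAM_MAP <- c(
  p_tnbc_all = "p_tnbc_death",
  hr_all = "hr_treatment",
  u_decrement_tnbc = "u_decrement_tnbc",
  u_decrement_terminal = "u_decrement_terminal",
  u_population_average = "u_population_average",
  c_drug_propranolol = "c_drug_annual",
  c_mgmt_y1 = "c_mgmt_y1", c_mgmt_y2 = "c_mgmt_y2", c_mgmt_y3 = "c_mgmt_y3",
  c_mgmt_y4 = "c_mgmt_y4", c_mgmt_y5 = "c_mgmt_y5",
  c_terminal_tnbc = "c_terminal_tnbc",
  c_death_other = "c_death_other"
)

# stable 31-bit string hash so each parameter keeps its own RNG
# sub-stream regardless of table order or additions
name_hash <- function(name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  h
}

substream_seed <- function(seed, name) {
  (abs(seed) * 48271 + name_hash(name)) %% 2147483647
}

#' Draw sampled values for every uncertain parameter
#'
#' Each parameter is drawn from its own seeded RNG sub-stream (derived
#' from the run seed and a hash of the parameter name), so adding or
#' reordering parameters does not perturb the draws of the others, and
#' identical seeds reproduce draws bit-exactly.
#'
#' @param specs named list of `bbtnbc_dist` objects.
#' @param n_draws number of joint draws.
#' @param seed integer run seed.
#' @return data.frame, one column per parameter, `n_draws` rows.
#' @export
sample_parameter_draws <- function(specs, n_draws, seed) {
  stopifnot(n_draws >= 1, length(specs) >= 1, !is.null(names(specs)))
  cols <- lapply(names(specs), function(nm) {
    if (!inherits(specs[[nm]], "bbtnbc_dist"))
      stop("configuration error: unfitted spec for ", nm)
    with_seed(substream_seed(seed, nm), sample_dist(specs[[nm]], n_draws))
  })
  names(cols) <- names(specs)
  as.data.frame(cols)
}

apply_draw_to_params <- function(params, draw) {
  mg <- params$c_mgmt_by_year
  for (nm in names(draw)) {
    field <- PSA_PARAM_MAP[[nm]]
    if (is.null(field)) next
    v <- as.numeric(draw[[nm]])
    if (grepl("^c_mgmt_y", field)) {
      mg[as.integer(sub("c_mgmt_y", "", field))] <- v
    } else {
      params[[field]] <- v
    }
  }
  params$c_mgmt_by_year <- mg
  validate_parameters(params)
}

#' Sample one parameter set
#'
#' Joint independent draw of all uncertain parameters applied to the base
#' parameter set. Degenerate (zero-width) specs return the base value, so
#' an all-degenerate table reproduces `base` exactly.
#'
#' @param base a `bbtnbc_params`.
#' @param specs named list of fitted `bbtnbc_dist` objects (defaults to
#'   the packaged parameter table, base-case rows).
#' @param seed integer seed.
#' @return a `bbtnbc_params`.
#' @export
sample_parameters <- function(base = tnbc_parameters(), specs = NULL,
                              seed = 1) {
  if (is.null(specs)) specs <- psa_specs()
  apply_draw_to_params(base, sample_parameter_draws(specs, 1, seed)[1, , drop = FALSE])
}

#' Fitted distributions for the base-case PSA parameters
#'
#' @param tbl parameter table (defaults to the packaged fixture).
#' @return named list of `bbtnbc_dist` objects, base-case rows only.
#' @export
psa_specs <- function(tbl = parameter_table()) {
  specs <- fit_parameter_table(tbl)
  specs[intersect(names(PSA_PARAM_MAP), names(specs))]
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint parameter sets and re-evaluates the two-arm
#' model (all age bands, fixed eligible cohort) for each, retaining the
#' per-draw incremental outcomes and arm-level totals for
#' value-of-information analysis.
#'
#' @param n_draws number of iterations (published analysis: 1000).
#' @param seed integer run seed.
#' @param schedule a `bbtnbc_schedule`.
#' @param params base `bbtnbc_params`.
#' @param specs named list of fitted `bbtnbc_dist`; defaults to the
#'   packaged parameter table.
#' @return a `bbtnbc_psa` list: `draws` (per-draw data.frame with sampled
#'   values, arm totals and increments), `summary` (percentile 95%
#'   intervals, fraction cost-saving, CEAC point at the WTP threshold),
#'   `n_draws`, `seed`, `n_treated`, `wtp`.
#' @export
run_psa <- function(n_draws = 1000, seed = 1, schedule,
                    params = tnbc_parameters(), specs = NULL) {
  stopifnot(n_draws >= 1)
  if (is.null(specs)) specs <- psa_specs()
  cohort <- eligible_population(schedule, params)
  sampled <- sample_parameter_draws(specs, n_draws, seed)
  out <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    p_i <- apply_draw_to_params(params, sampled[i, , drop = FALSE])
    arms <- evaluate_arms(cohort, p_i, schedule)
    cmp <- compare_arms(arms$standard, arms$intervention, params$wtp,
                        p_i$u_population_average)
    out[[i]] <- c(
      yll_std = arms$standard$yll, yll_int = arms$intervention$yll,
      qaly_std = arms$standard$qaly, qaly_int = arms$intervention$qaly,
      cost_std = arms$standard$cost_total,
      cost_int = arms$intervention$cost_total,
      drug_cost = arms$intervention$cost_drug,
      d_yll = cmp$d_yll, d_qaly = cmp$d_qaly, d_evly = cmp$d_evly,
      d_cost = cmp$d_cost
    )
  }
  draws <- cbind(draw = seq_len(n_draws), sampled,
                 as.data.frame(do.call(rbind, out)))
  wtp <- params$wtp
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  summ <- list(
    d_yll_mean = mean(draws$d_yll), d_yll_ci = ci(draws$d_yll),
    d_qaly_mean = mean(draws$d_qaly), d_qaly_ci = ci(draws$d_qaly),
    d_evly_mean = mean(draws$d_evly), d_evly_ci = ci(draws$d_evly),
    d_cost_mean = mean(draws$d_cost), d_cost_ci = ci(draws$d_cost),
    drug_cost_mean = mean(draws$drug_cost),
    drug_cost_ci = ci(draws$drug_cost),
    frac_cost_saving = mean(draws$d_cost < 0),
    frac_cost_effective = mean(wtp * draws$d_qaly - draws$d_cost > 0)
  )
  structure(list(draws = draws, summary = summ, n_draws = n_draws,
                 seed = seed, n_treated = attr(cohort, "total"), wtp = wtp),
            class = "bbtnbc_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive net monetary benefit at each
#' willingness-to-pay value.
#'
#' @param psa a `bbtnbc_psa`.
#' @param wtp_grid non-negative willingness-to-pay values (AUD/QALY).
#' @return data.frame with columns wtp, prob_cost_effective.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 56000, by = 2000)) {
  stopifnot(inherits(psa, "bbtnbc_psa"))
  data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(l)
      mean(l * psa$draws$d_qaly - psa$draws$d_cost > 0), numeric(1))
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' Sets each uncertain parameter in turn to its lower and upper 95%
#' bound, all others at base, and recomputes the deterministic ICER per
#' QALY; rows are sorted by descending ICER span.
#'
#' @param schedule a `bbtnbc_schedule`.
#' @param params base `bbtnbc_params`.
#' @param tbl parameter table with low95/high95 bounds.
#' @return data.frame with columns parameter, low, high, icer_low,
#'   icer_high, span, sorted by descending span.
#' @export
tornado <- function(schedule, params = tnbc_parameters(),
                    tbl = parameter_table()) {
  tbl <- tbl[tbl$name %in% names(PSA_PARAM_MAP), , drop = FALSE]
  icer_at <- function(nm, value) {
    draw <- stats::setNames(data.frame(value), nm)
    p <- apply_draw_to_params(params, draw)
    run_base_case(schedule, p)$comparison$icer_qaly
  }
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    lo <- icer_at(tbl$name[i], tbl$low95[i])
    hi <- icer_at(tbl$name[i], tbl$high95[i])
    data.frame(parameter = tbl$name[i], low = tbl$low95[i],
               high = tbl$high95[i], icer_low = lo, icer_high = hi,
               span = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$span), , drop = FALSE]
}
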