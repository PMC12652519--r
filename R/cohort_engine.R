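#' Markov cohort life-table engine
#'
#' Three health states: Alive-with-TNBC, TNBC-death, non-TNBC-death
#' (both death states absorbing). One-year cycles from diagnosis until
#' the cohort reaches the censoring age. The annual TNBC-specific death
#' probability is fixed over time since diagnosis; the non-TNBC death
#' probability is the age-specific all-cause probability from the
#' schedule.
#'
#' @name cohort-engine
NULL

#' Convert a five-year risk to an annual event rate
#'
#' r = -log(1 - alpha) / 5, the constant per-person-year rate whose
#' five-year cumulative incidence is `alpha`.
#'
#' @param alpha five-year cumulative incidence in [0, 1).
#' @return rate per person-year.
#' @export
annual_rate_from_five_year_risk <- function(alpha) {
  if (any(alpha < 0 | alpha >= 1))
    stop("alpha must lie in [0, 1)")
  -log(1 - alpha) / 5
}

#' Convert an annual rate to an annual probability
#'
#' p = 1 - exp(-r). Composed with [annual_rate_from_five_year_risk()],
#' maps a five-year risk to the fixed annual transition probability.
#'
#' @param r rate per person-year (>= 0).
#' @return annual probability.
#' @export
probability_from_rate <- function(r) {
  if (any(r < 0)) stop("rate must be non-negative")
  1 - exp(-r)
}

#' Apply a hazard ratio to an annual probability
#'
#' The ratio acts on the hazard scale: p' = 1 - (1 - p)^hr, i.e.
#' probability -> rate, multiply, -> probability. Identity at hr = 1.
#'
#' @param p annual probability in [0, 1).
#' @param hr hazard ratio (>= 0; 0 eliminates the event).
#' @return adjusted annual probability.
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (any(hr < 0)) stop("hazard ratio must be non-negative")
  if (any(p < 0 | p >= 1))
    stop("probability must lie in [0, 1) for hazard-scale adjustment")
  1 - (1 - p)^hr
}

#' Run one cohort arm through the Markov life table
#'
#' Each cycle, the cohort alive at the cycle start faces the fixed annual
#' TNBC death probability (hazard-ratio adjusted in the intervention arm)
#' and the age-specific all-cause probability for a non-TNBC death. The
#' two competing risks are combined with a symmetric half-overlap
#' correction: P(TNBC death) = p_t (1 - p_o/2) and P(other death) =
#' p_o (1 - p_t/2), which is order-free and reduces to the marginal
#' probability when the competing risk vanishes.
#'
#' Accruals per cycle (undiscounted; discounting happens in
#' [summarize_arm()]):
#' \itemize{
#'   \item life-years: half-cycle corrected, (alive_start + alive_end)/2;
#'   \item utility-weighted life-years: life-years times
#'     (u_norm(age) + u_decrement_tnbc), plus u_decrement_terminal for
#'     each new TNBC death in its death cycle;
#'   \item drug cost (intervention arm only): annual drug cost times the
#'     half-cycle-corrected alive person-years, i.e. perfect adherence
#'     until death;
#'   \item management cost: the year-since-diagnosis cost (years 1..5,
#'     then the beyond-5-year cost) times alive person-years;
#'   \item terminal TNBC cost per new TNBC death; non-TNBC death cost per
#'     new non-TNBC death.
#' }
#'
#' @param entry_count cohort size at diagnosis.
#' @param entry_age age at diagnosis (years); cycles run to `max_age`.
#' @param arm "standard" or "intervention".
#' @param params a `bbtnbc_params`.
#' @param schedule a `bbtnbc_schedule` covering ages `entry_age` to
#'   `max_age - 1`.
#' @return a `bbtnbc_trace` data.frame, one row per cycle, with columns
#'   cycle, age, alive_start, alive_end, d_tnbc, d_other, cum_d_tnbc,
#'   cum_d_other, ly, qaly, cost_drug, cost_mgmt, cost_terminal,
#'   cost_other.
#' @export
run_cohort <- function(entry_count, entry_age,
                       arm = c("standard", "intervention"),
                       params = tnbc_parameters(),
                       schedule) {
  arm <- match.arg(arm)
  if (entry_age < 50 || entry_age >= params$max_age)
    stop("entry_age must lie in [50, max_age)")
  sched <- as.data.frame(schedule)
  ages <- seq(entry_age, params$max_age - 1)
  idx <- match(ages, sched$age)
  if (anyNA(idx))
    stop("schedule lacks required age(s): ",
         paste(ages[is.na(idx)], collapse = ", "))
  q_all <- sched$q_all[idx]
  u_norm <- sched$u_norm[idx]

  p_t_base <- params$p_tnbc_death
  p_t <- if (arm == "intervention")
    apply_hazard_ratio(p_t_base, params$hr_treatment) else p_t_base

  # the symmetric competing-risk split sums to p_t + p_o - p_t*p_o, so the
  # per-cycle survival factor is exactly (1 - p_t)(1 - p_o): the whole
  # occupancy path is a cumulative product
  n_cyc <- length(ages)
  surv <- (1 - p_t) * (1 - q_all)
  alive_start <- entry_count * c(1, cumprod(surv)[-n_cyc])
  keep <- alive_start >= 1e-12
  if (!all(keep)) {
    n_cyc <- which(!keep)[1] - 1
    ages <- ages[seq_len(n_cyc)]
    q_all <- q_all[seq_len(n_cyc)]
    u_norm <- u_norm[seq_len(n_cyc)]
    alive_start <- alive_start[seq_len(n_cyc)]
  }
  d_tnbc <- alive_start * p_t * (1 - q_all / 2)
  d_other <- alive_start * q_all * (1 - p_t / 2)
  alive_end <- alive_start - d_tnbc - d_other
  ly <- (alive_start + alive_end) / 2
  qaly <- ly * (u_norm + params$u_decrement_tnbc) +
    d_tnbc * params$u_decrement_terminal
  mgmt_rate <- c(params$c_mgmt_by_year,
                 rep(params$c_mgmt_beyond_5y, max(0, n_cyc - 5)))[seq_len(n_cyc)]
  tr <- data.frame(
    cycle = seq_len(n_cyc) - 1, age = ages,
    alive_start = alive_start, alive_end = alive_end,
    d_tnbc = d_tnbc, d_other = d_other,
    cum_d_tnbc = cumsum(d_tnbc), cum_d_other = cumsum(d_other),
    ly = ly, qaly = qaly,
    cost_drug = if (arm == "intervention") params$c_drug_annual * ly else 0 * ly,
    cost_mgmt = mgmt_rate * ly,
    cost_terminal = params$c_terminal_tnbc * d_tnbc,
    cost_other = params$c_death_other * d_other
  )
  attr(tr, "arm") <- arm
  attr(tr, "entry_count") <- entry_count
  attr(tr, "entry_age") <- entry_age
  class(tr) <- c("bbtnbc_trace", "data.frame")
  tr
}

#' Write a cohort trace to CSV
#'
#' @param trace a `bbtnbc_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
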