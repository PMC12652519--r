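#' Age-indexed schedules and the eligible cohort
#'
#' The model needs four age-indexed inputs over ages 50-85: female
#' all-cause mortality, population utility norms, incident breast-cancer
#' diagnoses, and the fraction of those that are triple-negative. These
#' come from national registry life tables and cross-sectional utility
#' studies; `load_schedule()` reads such data from CSV. When registry data
#' are not at hand, `synthesize_schedule()` generates a calibrated
#' stand-in with the same structural features.
#'
#' @name age-schedules
NULL

SCHEDULE_AGES <- 50:85
AGE_BANDS <- data.frame(
  band = c("50-54", "55-59", "60-64", "65-69", "70-74", "75-79"),
  age_lo = seq(50, 75, by = 5),
  age_hi = seq(54, 79, by = 5),
  entry_age = seq(52, 77, by = 5),   # band midpoint
  stringsAsFactors = FALSE
)

# Published per-band cohort sizes; used only as the relative age mix of
# incident TNBC in the synthetic schedule (absolute level is re-calibrated).
BAND_WEIGHTS <- c(137, 162, 158, 170, 189, 143)

new_schedule <- function(df) {
  structure(df, class = c("bbtnbc_schedule", "data.frame"))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Gompertz annual death probability q(a) = 1 - exp(-A * exp(B * a)).
gompertz_q <- function(age, A, B) 1 - exp(-A * exp(B * age))

# Period life expectancy at `from` implied by a Gompertz hazard, as the
# curtate expectation plus half a year, evaluated out to age 120.
gompertz_life_expectancy <- function(A, B, from = 50, horizon = 120) {
  ages <- from:(horizon - 1)
  surv <- cumprod(1 - gompertz_q(ages, A, B))
  0.5 + sum(surv)
}

#' Generate a synthetic age schedule
#'
#' Produces a deterministic (seeded) schedule over ages 50-85 emulating
#' the structure of the registry inputs:
#' \itemize{
#'   \item all-cause mortality follows a Gompertz law
#'     \eqn{q(a) = 1 - \exp(-A e^{Ba})} with slope B = 0.1/year and level A
#'     solved so that period life expectancy at age 50 is
#'     `life_expectancy_50` years (default 35, i.e. death near age 85,
#'     the average female life expectancy in Australia);
#'   \item population utility norms decline linearly with age
#'     (0.002/year) with the level calibrated so the cohort-weighted
#'     average equals `u_target` (default 0.90);
#'   \item incident breast-cancer counts follow the published per-band
#'     age mix with mild seeded age-to-age jitter, a constant
#'     triple-negative fraction of 0.15, and an overall level calibrated
#'     so that the post-exclusion eligible cohort (see
#'     [eligible_population()]) totals `calibration_target` exactly.
#' }
#'
#' @param seed integer seed controlling the incidence jitter.
#' @param calibration_target eligible treated cohort size (default 767).
#' @param life_expectancy_50 target period life expectancy at 50 (years).
#' @param u_target cohort-average utility norm.
#' @param params a `bbtnbc_params` providing the exclusion fractions.
#' @return a `bbtnbc_schedule` data.frame with columns age, q_all,
#'   u_norm, n_bc, prev_tnbc.
#' @export
synthesize_schedule <- function(seed = 1, calibration_target = 767,
                                life_expectancy_50 = 35, u_target = 0.90,
                                params = tnbc_parameters()) {
  if (calibration_target <= 0)
    stop("calibration_target must be positive")
  B <- 0.1
  fA <- function(logA)
    gompertz_life_expectancy(exp(logA), B) - life_expectancy_50
  sol <- tryCatch(
    stats::uniroot(fA, interval = c(-25, -2), tol = 1e-12),
    error = function(e) stop("calibration error: no Gompertz level ",
                             "achieves life expectancy ", life_expectancy_50)
  )
  A <- exp(sol$root)
  q_all <- gompertz_q(SCHEDULE_AGES, A, B)

  # incident BC: published band mix spread uniformly within bands, with
  # seeded lognormal jitter (sd 0.05) per year of age; none past 79
  per_age <- rep(BAND_WEIGHTS / 5, each = 5)
  jitter <- with_seed(seed, exp(stats::rnorm(length(per_age), 0, 0.05)))
  n_bc <- c(per_age * jitter, rep(0, 6))
  prev_tnbc <- rep(0.15, length(SCHEDULE_AGES))

  retain <- (1 - params$frac_already_on_bb) * (1 - params$frac_contraindicated)
  pool <- sum(n_bc * prev_tnbc)
  if (pool * retain <= 0) stop("calibration error: empty eligible pool")
  n_bc <- n_bc * calibration_target / (pool * retain)

  # utility norms: linear decline, level set so the eligible-cohort
  # weighted average at band entry ages equals u_target
  slope <- 0.002
  eligible_by_age <- n_bc * prev_tnbc * retain
  band_of_age <- findInterval(SCHEDULE_AGES, c(AGE_BANDS$age_lo, 80))
  w <- vapply(seq_len(nrow(AGE_BANDS)), function(b)
    sum(eligible_by_age[band_of_age == b]), numeric(1))
  mean_entry_age <- sum(w * AGE_BANDS$entry_age) / sum(w)
  u0 <- u_target + slope * (mean_entry_age - 50)
  if (u0 > 1) stop("calibration error: utility level above 1")
  u_norm <- u0 - slope * (SCHEDULE_AGES - 50)

  new_schedule(data.frame(age = SCHEDULE_AGES, q_all = q_all,
                          u_norm = u_norm, n_bc = n_bc,
                          prev_tnbc = prev_tnbc))
}

#' Load an age schedule from CSV
#'
#' Expects columns age, q_all, u_norm, n_bc, prev_tnbc with one row per
#' age 50-85. Violations of the schedule invariants are rejected with the
#' offending age named.
#'
#' @param path CSV path.
#' @return a validated `bbtnbc_schedule`.
#' @export
load_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "q_all", "u_norm", "n_bc", "prev_tnbc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schedule is missing column(s): ", paste(miss, collapse = ", "))
  validate_schedule(df)
}

validate_schedule <- function(df) {
  missing_ages <- setdiff(SCHEDULE_AGES, df$age)
  if (length(missing_ages))
    stop("schedule is missing age(s): ", paste(missing_ages, collapse = ", "))
  if (anyDuplicated(df$age))
    stop("schedule has duplicated age(s): ",
         paste(unique(df$age[duplicated(df$age)]), collapse = ", "))
  df <- df[order(df$age), , drop = FALSE]
  bad <- function(cond) df$age[which(cond)]
  b <- bad(df$q_all < 0 | df$q_all > 1)
  if (length(b)) stop("q_all outside [0, 1] at age(s): ",
                      paste(b, collapse = ", "))
  if (any(diff(df$q_all) < 0))
    stop("q_all must be non-decreasing in age; decreases after age(s): ",
         paste(df$age[which(diff(df$q_all) < 0)], collapse = ", "))
  b <- bad(df$u_norm < 0 | df$u_norm > 1)
  if (length(b)) stop("u_norm outside [0, 1] at age(s): ",
                      paste(b, collapse = ", "))
  b <- bad(df$prev_tnbc < 0 | df$prev_tnbc > 1)
  if (length(b)) stop("prev_tnbc outside [0, 1] at age(s): ",
                      paste(b, collapse = ", "))
  b <- bad(df$n_bc < 0)
  if (length(b)) stop("n_bc negative at age(s): ", paste(b, collapse = ", "))
  rownames(df) <- NULL
  new_schedule(df)
}

#' Write an age schedule to CSV
#'
#' Emits the same format accepted by [load_schedule()].
#'
#' @param schedule a `bbtnbc_schedule`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule)[, c("age", "q_all", "u_norm",
                                               "n_bc", "prev_tnbc")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Derive the eligible treated cohort from a schedule
#'
#' Per 5-year age band (50-54 ... 75-79), the entry count is the sum over
#' ages in the band of incident breast cancers times the triple-negative
#' fraction, with the two eligibility exclusions applied multiplicatively:
#' women already on beta-blockers for another indication
#' (`frac_already_on_bb`) and women with a contraindication
#' (`frac_contraindicated`). The representative entry age is the band
#' midpoint.
#'
#' @param schedule a `bbtnbc_schedule`.
#' @param params a `bbtnbc_params` (supplies the exclusion fractions).
#' @return data.frame with columns band, entry_age, n_entry, and
#'   attribute `total`.
#' @export
eligible_population <- function(schedule, params = tnbc_parameters()) {
  schedule <- validate_schedule(as.data.frame(schedule))
  retain <- (1 - params$frac_already_on_bb) * (1 - params$frac_contraindicated)
  band_of_age <- findInterval(schedule$age, c(AGE_BANDS$age_lo, 80))
  in_band <- band_of_age >= 1 & band_of_age <= nrow(AGE_BANDS) &
    schedule$age <= 79
  elig <- schedule$n_bc * schedule$prev_tnbc * retain
  n_entry <- vapply(seq_len(nrow(AGE_BANDS)), function(b)
    sum(elig[in_band & band_of_age == b]), numeric(1))
  out <- data.frame(band = AGE_BANDS$band, entry_age = AGE_BANDS$entry_age,
                    n_entry = n_entry, stringsAsFactors = FALSE)
  attr(out, "total") <- sum(n_entry)
  out
}
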