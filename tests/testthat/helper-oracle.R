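# Independent individual-level Monte-Carlo oracle for the cohort engine.
# Simulates each woman year by year with the same per-cycle transition
# probabilities (sequential competing-risk split) and half-cycle life-year
# credit, without sharing any code with run_cohort()'s cumulative-product
# path.
microsim_arm <- function(n, entry_age, arm, params, schedule, seed) {
  sched <- as.data.frame(schedule)
  ages <- seq(entry_age, params$max_age - 1)
  q_all <- sched$q_all[match(ages, sched$age)]
  p_t <- params$p_tnbc_death
  if (arm == "intervention") p_t <- 1 - (1 - p_t)^params$hr_treatment

  set.seed(seed)
  state <- rep.int(0L, n)  # 0 alive, 1 TNBC death, 2 other death
  ly <- rep.int(0, n)
  for (i in seq_along(ages)) {
    alive <- state == 0L
    if (!any(alive)) break
    p_o <- q_all[i]
    pt <- p_t * (1 - p_o / 2)
    po <- p_o * (1 - p_t / 2)
    u <- runif(sum(alive))
    dies_t <- u < pt
    dies_o <- !dies_t & u < pt + po
    idx <- which(alive)
    ly[idx] <- ly[idx] + ifelse(dies_t | dies_o, 0.5, 1)
    state[idx[dies_t]] <- 1L
    state[idx[dies_o]] <- 2L
  }
  list(ly = ly, mean_ly = mean(ly), se_ly = stats::sd(ly) / sqrt(n),
       frac_tnbc = mean(state == 1L), frac_other = mean(state == 2L),
       frac_alive = mean(state == 0L))
}
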