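# Shared fixtures: one synthetic schedule and its base-case run, computed
# once per test session.

SCH <- synthesize_schedule(seed = 1)
BASE <- run_base_case(SCH)

# flat schedule with constant mortality/utility, handy for hand-computable
# toy cases
flat_schedule <- function(q_all = 0.01, u_norm = 1, n_bc = 10,
                          prev_tnbc = 0.15) {
  validate_flat <- data.frame(age = 50:85, q_all = q_all, u_norm = u_norm,
                              n_bc = n_bc, prev_tnbc = prev_tnbc)
  structure(validate_flat, class = c("bbtnbc_schedule", "data.frame"))
}

# parameters with no utility adjustment and no costs, for identities
neutral_params <- function(...) {
  tnbc_parameters(u_decrement_tnbc = 0, u_decrement_terminal = 0,
                  c_drug_annual = 0, c_mgmt_by_year = rep(0, 5),
                  c_terminal_tnbc = 0, c_death_other = 0, ...)
}
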