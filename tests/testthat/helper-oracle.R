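# Independent enumerate-and-sum oracle for the cohort engine, written as a
# plain scalar ledger (separate arithmetic from the engine's implementation).

oracle_step <- function(no, ca, tr, ex, pc, pe, eff, pu, pr) {
  # exits first, independently of morbidity
  leavers <- no * pe + ca * pe + tr * pe
  no2 <- no - no * pe
  ca2 <- ca - ca * pe
  tr2 <- tr - tr * pe
  # morbidity flows among survivors
  new_cases <- no2 * pc * (1 - eff)
  cured <- ca2 * (1 - pu)
  back <- tr2 * pr
  c(
    no = no2 - new_cases,
    ca = ca2 + new_cases - cured + back,
    tr = tr2 + cured - back,
    ex = ex + leavers
  )
}

# Full-arm oracle under the DMFT-accrual effect mechanism: states evolve as
# do-nothing, DMFT entrants are scaled by (1 - eff).
oracle_run <- function(cohort, n_cycles, rate, pu, pr, growth,
                       pc, pe, dmft0, per_learner_cost, eff,
                       sugar_offset_per_learner = 0) {
  no <- cohort; ca <- 0; tr <- 0; ex <- 0
  total_cost <- 0; total_cost_u <- 0; total_dmft <- 0
  for (t in 0:(n_cycles - 1)) {
    d <- (1 + rate)^(-t)
    living <- no + ca + tr
    total_cost_u <- total_cost_u + living * per_learner_cost
    total_cost <- total_cost + living * per_learner_cost * d
    entrants <- no * (1 - pe[t + 1]) * pc[t + 1] * (1 - eff)
    inc <- entrants * dmft0[t + 1] * (1 + growth)^t
    inc <- inc - sugar_offset_per_learner * living
    if (inc < 0) inc <- 0
    total_dmft <- total_dmft + inc * d
    s <- oracle_step(no, ca, tr, ex, pc[t + 1], pe[t + 1], 0, pu, pr)
    no <- s[["no"]]; ca <- s[["ca"]]; tr <- s[["tr"]]; ex <- s[["ex"]]
  }
  list(
    total_cost = total_cost, total_cost_undiscounted = total_cost_u,
    total_dmft = total_dmft
  )
}

# small helper: a flat schedule for miniature instances
flat_schedule <- function(config, pc, pe, dmft) {
  age_schedule(
    ages = config$start_age + seq_len(config$n_cycles) - 1,
    prob_caries = rep(pc, config$n_cycles),
    prob_exit = rep(pe, config$n_cycles),
    baseline_dmft = rep(dmft, config$n_cycles)
  )
}

mini_config <- function(n_cycles = 2, cohort = 10, rate = 0.05, ...) {
  model_config(
    cohort_size = cohort, start_age = 5, exit_age = 5 + n_cycles,
    n_cycles = n_cycles, discount_rate = rate, ...
  )
}
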