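cfg <- model_config()

test_that("discounting follows the closed form with cycle 0 undiscounted", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(1, 0.05), 1 / 1.05)
  expect_equal(discount_factor(0:5, 0), rep(1, 6))
  expect_error(discount_factor(-1, 0.05))
})

test_that("one transition step matches the hand-worked ledger", {
  state <- state_occupancy(100, 50, 10, 0)
  row <- list(prob_caries = 0.2, prob_exit = 0, baseline_dmft = 1)
  nxt <- transition_step(state, row, effect = 0, cfg)
  # ledger: 20 new cases, 15 treated (30% of 50), 1.88 relapses (18.8% of 10)
  expect_equal(unclass(nxt), c(
    no_caries = 80, caries = 56.88, treated = 23.12, exited = 0
  ))
  expect_equal(sum(nxt), 160)
})

test_that("boundary transitions behave: full protection and absorbing flush", {
  row <- list(prob_caries = 0.3, prob_exit = 0.1, baseline_dmft = 1)
  s <- transition_step(state_occupancy(100), row, effect = 1, cfg)
  expect_equal(s[["no_caries"]], 90)
  expect_equal(s[["caries"]], 0)
  expect_equal(s[["exited"]], 10)

  row2 <- list(prob_caries = 0.3, prob_exit = 1, baseline_dmft = 1)
  s2 <- transition_step(state_occupancy(40, 30, 20, 10), row2, effect = 0, cfg)
  expect_equal(s2[["exited"]], 100)
  expect_equal(sum(s2[c("no_caries", "caries", "treated")]), 0)
})

test_that("transition step matches the oracle over random states and parameters", {
  set.seed(101)
  for (i in 1:50) {
    st <- runif(4, 0, 100)
    pc <- runif(1)
    pe <- runif(1)
    eff <- runif(1)
    got <- transition_step(
      state_occupancy(st[1], st[2], st[3], st[4]),
      list(prob_caries = pc, prob_exit = pe),
      eff, cfg
    )
    want <- oracle_step(st[1], st[2], st[3], st[4], pc, pe, eff,
      cfg$prob_untreated, cfg$prob_recurrence
    )
    expect_equal(unclass(got), want,
      ignore_attr = TRUE, tolerance = 1e-12
    )
    expect_equal(sum(got), sum(st), tolerance = 1e-12)
  }
})

test_that("DMFT accrual scales with growth, effect and the sugar slope", {
  state <- state_occupancy(100, 20, 5, 0)
  row <- list(prob_caries = 0.2, prob_exit = 0.05, baseline_dmft = 1.5)
  expect_equal(dmft_increment(state, row, effect = 1, 0, cfg), 0)
  i0 <- dmft_increment(state, row, 0, 0, cfg)
  i1 <- dmft_increment(state, row, 0, 1, cfg)
  expect_equal(i1 / i0, 1.0059)
  g0 <- model_config(dmft_growth = 0)
  expect_equal(
    dmft_increment(state, row, 0.3, 4, g0),
    dmft_increment(state, row, 0.3, 0, g0)
  )
  # linearity in (1 - effect)
  expect_equal(dmft_increment(state, row, 0.5, 0, cfg), 0.5 * i0)

  expect_equal(sugar_dmft_reduction(0, cfg), 0)
  expect_equal(sugar_dmft_reduction(30, cfg), 0.384)
  x <- runif(1, 0, 50)
  expect_equal(sugar_dmft_reduction(2 * x, cfg), 2 * sugar_dmft_reduction(x, cfg))
  expect_error(sugar_dmft_reduction(-1, cfg))
})

test_that("a 2-cycle miniature matches an independently hand-computed ledger", {
  mc <- model_config(
    cohort_size = 10, start_age = 5, exit_age = 7, n_cycles = 2,
    discount_rate = 0.05, dmft_growth = 0, screening_cost = 2
  )
  sched <- flat_schedule(mc, pc = 0.2, pe = 0.1, dmft = 1)
  spec <- intervention_spec("mini", 5, 25, 2.5, requires_screening = TRUE)
  run <- run_arm(spec, sched, mc)
  # ledger, cycle 0: 10 alive, cost 10*(5+2) = 70 undiscounted;
  #   at-risk after exits 9, entrants 9*0.2*0.75 = 1.35 DMFT
  # cycle 1: 9 alive, cost 63/1.05 = 60; caries-free now 7.2,
  #   entrants 7.2*0.9*0.2*0.75 = 0.972, discounted 0.972/1.05
  expect_equal(run$result$total_cost, 130)
  totals <- attr(run$trace, "totals")
  expect_equal(totals[["total_cost_undiscounted"]], 133)
  expect_equal(totals[["total_dmft"]], 1.35 + 0.972 / 1.05)
  # do-nothing ledger: 1.8 + 1.296/1.05 DMFT
  dn <- attr(run_arm(NULL, sched, mc)$trace, "totals")[["total_dmft"]]
  expect_equal(dn, 1.8 + 1.296 / 1.05)
  expect_equal(run$result$dmft_averted, dn - (1.35 + 0.972 / 1.05))
})

test_that("engine equals the enumerate-and-sum oracle on small instances", {
  set.seed(2024)
  for (i in 1:25) {
    n_cyc <- sample(1:3, 1)
    cohort <- sample(1:10, 1)
    mc <- model_config(
      cohort_size = cohort, start_age = 5, exit_age = 5 + n_cyc,
      n_cycles = n_cyc, discount_rate = runif(1, 0, 0.2),
      prob_untreated = runif(1), prob_recurrence = runif(1),
      dmft_growth = runif(1, 0, 0.05), screening_cost = runif(1, 0, 10)
    )
    pc <- runif(n_cyc)
    pe <- runif(n_cyc, 0, 0.5)
    d0 <- runif(n_cyc, 0.5, 3)
    sched <- age_schedule(5:(4 + n_cyc), pc, pe, d0)
    eff_pct <- runif(1, 0, 100)
    cost <- runif(1, 0, 200)
    spec <- intervention_spec("rand", cost, eff_pct, 1)
    run <- run_arm(spec, sched, mc)
    want <- oracle_run(
      cohort, n_cyc, mc$discount_rate, mc$prob_untreated, mc$prob_recurrence,
      mc$dmft_growth, pc, pe, d0,
      per_learner_cost = cost + mc$screening_cost, eff = eff_pct / 100
    )
    expect_equal(run$result$total_cost, want$total_cost, tolerance = 1e-9)
    totals <- attr(run$trace, "totals")
    expect_equal(totals[["total_dmft"]], want$total_dmft, tolerance = 1e-9)
    expect_equal(
      totals[["total_cost_undiscounted"]], want$total_cost_undiscounted,
      tolerance = 1e-9
    )
  }
})

test_that("occupancy is conserved at every cycle of full-scale runs", {
  sched <- generate_age_schedule(3)
  for (spec in c(list(NULL), default_config()$specs)) {
    tr <- run_arm(spec, sched, cfg)$trace
    sums <- rowSums(tr[, c("no_caries", "caries", "treated", "exited")])
    expect_true(all(abs(sums - cfg$cohort_size) <= 1e-9 * cfg$cohort_size))
  }
})

test_that("with no exits, total cost follows the annuity closed form", {
  sched <- flat_schedule(cfg, pc = 0.2, pe = 0, dmft = 1)
  spec <- intervention_spec("const", 100, 10, 1, requires_screening = FALSE)
  run <- run_arm(spec, sched, cfg)
  ann <- sum(1 / 1.05^(0:9))
  expect_equal(run$result$total_cost, cfg$cohort_size * 100 * ann, tolerance = 1e-12)
})

test_that("discounted totals never exceed undiscounted, equal only at rate 0", {
  sched <- generate_age_schedule(4)
  run <- run_arm(default_config()$specs[[1]], sched, cfg)
  t <- attr(run$trace, "totals")
  expect_lt(t[["total_cost"]], t[["total_cost_undiscounted"]])
  cfg0 <- model_config(discount_rate = 0)
  t0 <- attr(run_arm(default_config()$specs[[1]], sched, cfg0)$trace, "totals")
  expect_equal(t0[["total_cost"]], t0[["total_cost_undiscounted"]])
})

test_that("more effect never averts less; higher cost never costs less", {
  sched <- generate_age_schedule(8)
  base <- attr(run_arm(NULL, sched, cfg)$trace, "totals")[["total_dmft"]]
  effs <- seq(0, 1, by = 0.1)
  for (mech in c("dmft", "flow")) {
    mcfg <- model_config(effect_mechanism = mech)
    averted <- vapply(effs, function(e) {
      run_arm(intervention_spec("x", 10, 50, 1), sched, mcfg,
        effect_override = e, donothing_dmft = base
      )$result$dmft_averted
    }, numeric(1))
    expect_true(all(diff(averted) >= -1e-9))
  }
  costs <- vapply(c(0, 50, 100, 500), function(cst) {
    run_arm(intervention_spec("x", 10, 50, 1), sched, cfg,
      cost_override = cst, donothing_dmft = base
    )$result$total_cost
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
})

test_that("do-nothing and neutral interventions anchor the scale", {
  sched <- generate_age_schedule(2)
  dn <- run_arm(NULL, sched, cfg)$result
  expect_equal(dn$total_cost, 0)
  expect_equal(dn$dmft_averted, 0)
  neutral <- run_arm(
    intervention_spec("neutral", 0, 0, 1, requires_screening = FALSE),
    sched, cfg
  )$result
  expect_equal(neutral$total_cost, 0)
  expect_equal(neutral$dmft_averted, 0, tolerance = 1e-12)
  screened <- run_arm(
    intervention_spec("screen-only", 0, 0, 1, requires_screening = TRUE),
    sched, cfg
  )$result
  expect_equal(
    screened$total_cost,
    screening_cost_total(sched, cfg, discounted = TRUE)
  )
})

test_that("the sugar slope arm subtracts the dose-response offset, floored at zero", {
  mc <- model_config(
    cohort_size = 100, start_age = 5, exit_age = 7, n_cycles = 2,
    discount_rate = 0, dmft_growth = 0
  )
  sched <- flat_schedule(mc, pc = 0.5, pe = 0, dmft = 2)
  sugar <- intervention_spec("Sugar reduction", 1.25, 31.89, 0.18,
    requires_screening = FALSE, is_sugar_policy = TRUE
  )
  run <- run_arm(sugar, sched, mc)
  want <- oracle_run(100, 2, 0, mc$prob_untreated, mc$prob_recurrence, 0,
    c(0.5, 0.5), c(0, 0), c(2, 2),
    per_learner_cost = 1.25, eff = 0,
    sugar_offset_per_learner = 0.384
  )
  expect_equal(run$result$total_cost, want$total_cost)
  expect_equal(attr(run$trace, "totals")[["total_dmft"]], want$total_dmft)
  # an extreme slope cannot push cohort DMFT negative
  big <- model_config(
    cohort_size = 100, start_age = 5, exit_age = 7, n_cycles = 2,
    discount_rate = 0, dmft_growth = 0, sugar_slope = 10
  )
  run2 <- run_arm(sugar, sched, big)
  expect_equal(attr(run2$trace, "totals")[["total_dmft"]], 0)
})

test_that("trace exports tidily and mismatched schedules error", {
  sched <- generate_age_schedule(1)
  tr <- run_arm(NULL, sched, cfg)$trace
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  tidy <- read.csv(path)
  expect_equal(nrow(tidy), 4 * cfg$n_cycles)
  expect_setequal(unique(tidy$state), c("no_caries", "caries", "treated", "exited"))
  short <- sched[1:5, ]
  class(short) <- class(sched)
  expect_error(run_arm(NULL, short, cfg), class = "cariesCEA_validation_error")
})
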