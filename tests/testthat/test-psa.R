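cfg <- model_config()

test_that("gamma moment matching has the published closed form", {
  expect_equal(gamma_params(89.24, 8.924), c(shape = 100, scale = 0.8924))
  p <- gamma_params(548.33, 544.29)
  expect_equal(unname(p["shape"]), 1.01491, tolerance = 1e-4)
  expect_equal(unname(p["scale"]), 540.2794, tolerance = 1e-4)
  m <- 37.2
  expect_equal(gamma_params(m, m), c(shape = 1, scale = m))
  expect_error(gamma_params(0, 1))
  expect_error(gamma_params(1, -1))
})

test_that("beta moment matching has the published closed form and feasibility bound", {
  expect_equal(beta_params(50, 28.8675), c(alpha = 1, beta = 1), tolerance = 1e-3)
  p <- beta_params(21, 4)
  expect_equal(unname(p["alpha"]), 21.5644, tolerance = 1e-4)
  expect_equal(unname(p["beta"]), 81.1231, tolerance = 1e-4)
  expect_error(beta_params(60, 80), "infeasible")
  expect_error(beta_params(0, 5))
  expect_error(beta_params(110, 5))
})

test_that("moment-matched draws recover the requested mean and SD", {
  n <- 1e5
  set.seed(314)
  for (ms in list(c(89.24, 8.924), c(548.33, 544.29))) {
    g <- gamma_params(ms[1], ms[2])
    x <- rgamma(n, shape = g["shape"], scale = g["scale"])
    se_mean <- ms[2] / sqrt(n)
    expect_lt(abs(mean(x) - ms[1]), 3 * se_mean)
    expect_lt(abs(sd(x) - ms[2]) / ms[2], 0.03)
  }
  for (ms in list(c(21, 4), c(72, 25), c(31.89, 0.18))) {
    b <- beta_params(ms[1], ms[2])
    x <- 100 * rbeta(n, b["alpha"], b["beta"])
    expect_lt(abs(mean(x) - ms[1]), 3 * ms[2] / sqrt(n))
    expect_lt(abs(sd(x) - ms[2]) / ms[2], 0.03)
  }
})

test_that("PSA samples are a pure function of the seed", {
  d <- default_config()
  sched <- generate_age_schedule(1)
  a <- run_psa(d$config, d$specs, sched, n_iterations = 20, seed = 5)
  b <- run_psa(d$config, d$specs, sched, n_iterations = 20, seed = 5)
  expect_identical(a, b)
  c2 <- run_psa(d$config, d$specs, sched, n_iterations = 20, seed = 6)
  expect_false(identical(a$total_cost, c2$total_cost))
  # rectangular: every arm in every iteration
  expect_equal(nrow(a), 20 * (length(d$specs) + 1))
  expect_true(all(table(a$arm) == 20))
  # effectiveness draws live in [0, 1] by construction
  expect_true(all(a$effect >= 0 & a$effect <= 1))
})

test_that("with vanishing SDs the PSA collapses to the deterministic result", {
  d <- default_config()
  sched <- generate_age_schedule(1)
  tight <- lapply(d$specs, function(s) {
    intervention_spec(s$name, s$annual_cost_mean, s$effect_mean,
      effect_sd = 1e-4, annual_cost_sd = 1e-6 * max(s$annual_cost_mean, 1),
      requires_screening = s$requires_screening,
      is_sugar_policy = s$is_sugar_policy
    )
  })
  cfg_eff <- model_config(sugar_mechanism = "effect")
  det <- run_all_arms(cfg_eff, tight, sched)$results
  samp <- run_psa(cfg_eff, tight, sched, n_iterations = 1, seed = 2)
  for (r in det[-1]) {
    row <- samp[samp$arm == r$name, ]
    expect_equal(row$total_cost, r$total_cost, tolerance = 1e-3)
    expect_equal(row$dmft_averted, r$dmft_averted, tolerance = 1e-2)
  }
})

test_that("PSA sample means track the deterministic totals", {
  d <- default_config()
  sched <- generate_age_schedule(1)
  n <- 400
  samp <- run_psa(d$config, d$specs, sched, n_iterations = n, seed = 9)
  det <- run_all_arms(model_config(sugar_mechanism = "effect"), d$specs, sched)$results
  for (r in det[-1]) {
    x <- samp$total_cost[samp$arm == r$name]
    se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - r$total_cost), 4 * se + 1e-6)
  }
})

test_that("acceptability curves are normalized argmax frequencies", {
  d <- default_config()
  sched <- generate_age_schedule(1)
  samp <- run_psa(d$config, d$specs, sched, n_iterations = 50, seed = 3)
  grid <- seq(0, 40000, by = 2000)
  curve <- ceac(samp, grid)
  sums <- tapply(curve$probability, curve$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(grid)))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  # do-nothing is certain to be optimal when health gains are worthless
  expect_equal(curve$probability[curve$wtp == 0 & curve$arm == "Do nothing"], 1)

  # brute-force per-iteration argmax tally at one threshold
  w <- 10000
  arms <- unique(samp$arm)
  wins <- setNames(numeric(length(arms)), arms)
  for (i in unique(samp$iteration)) {
    sub <- samp[samp$iteration == i, ]
    bens <- w * sub$dmft_averted - sub$total_cost
    wins[sub$arm[which.max(bens)]] <- wins[sub$arm[which.max(bens)]] + 1
  }
  got <- curve$probability[curve$wtp == w]
  names(got) <- curve$arm[curve$wtp == w]
  expect_equal(got[arms], wins / length(unique(samp$iteration)))
})

test_that("degenerate samples give indicator curves", {
  samp <- data.frame(
    iteration = rep(1:4, each = 2),
    arm = rep(c("Do nothing", "winner"), 4),
    annual_cost = 0, effect = 0,
    total_cost = rep(c(0, 10), 4),
    dmft_averted = rep(c(0, 100), 4)
  )
  attr(samp, "n_iterations") <- 4L
  class(samp) <- c("psa_samples", "data.frame")
  curve <- ceac(samp, c(1, 50, 1000))
  expect_equal(curve$probability[curve$arm == "winner"], rep(1, 3))
  expect_error(ceac(samp, numeric(0)), "non-empty")
})

test_that("the PSA summary mirrors the ranked deterministic layout", {
  d <- default_config()
  sched <- generate_age_schedule(1)
  samp <- run_psa(d$config, d$specs, sched, n_iterations = 60, seed = 12)
  summ <- summarize_psa(samp, d$config$wtp)
  expect_setequal(
    names(summ),
    c(
      "name", "mean_cost", "mean_dmft_averted", "average_lifetime_cost",
      "icer_vs_donothing", "ranked_icer", "mean_nmb", "sd_cost", "sd_dmft"
    )
  )
  expect_true(!is.unsorted(summ$mean_dmft_averted))
  # mean NMB equals the NMB of the means (linearity of expectation)
  expect_equal(
    summ$mean_nmb,
    d$config$wtp * summ$mean_dmft_averted - summ$mean_cost
  )
  # and equals the mean of per-iteration NMBs
  for (a in summ$name) {
    x <- samp[samp$arm == a, ]
    expect_equal(
      summ$mean_nmb[summ$name == a],
      mean(d$config$wtp * x$dmft_averted - x$total_cost)
    )
  }
  # constant samples: SDs are zero and means are the constants
  const <- samp[samp$iteration == 1, ]
  const <- do.call(rbind, lapply(1:5, function(i) {
    z <- const
    z$iteration <- i
    z
  }))
  attr(const, "n_iterations") <- 5L
  attr(const, "cohort_size") <- d$config$cohort_size
  class(const) <- c("psa_samples", "data.frame")
  s2 <- summarize_psa(const, d$config$wtp)
  expect_equal(s2$sd_cost, rep(0, nrow(s2)))
  expect_equal(s2$sd_dmft, rep(0, nrow(s2)))
})

test_that("sampling failures name the offending arm and parameter", {
  d <- default_config()
  sched <- generate_age_schedule(1)
  bad <- list(intervention_spec("Tooth brushing", 548.33, 60, 49.5))
  expect_error(
    run_psa(d$config, bad, sched, n_iterations = 2, seed = 1),
    "Tooth brushing.*effectiveness"
  )
})
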