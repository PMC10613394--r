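#' Discount factor for an annual cycle
#'
#' @param cycle_index Cycle number, 0-based; cycle 0 is undiscounted.
#' @param rate Annual discount rate (proportion, >= 0).
#' @return `1 / (1 + rate)^cycle_index`.
#' @export
discount_factor <- function(cycle_index, rate) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  if (any(rate < 0)) stop("rate must be >= 0")
  1 / (1 + rate)^cycle_index
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' State occupancy of the cohort
#'
#' Learner counts (possibly fractional: this is an expected-value cohort
#' model) in the four health states: caries-free, caries, treated, exited.
#'
#' @param no_caries,caries,treated,exited Non-negative occupancies.
#' @return A named numeric vector of class `state_occupancy`.
#' @export
state_occupancy <- function(no_caries, caries = 0, treated = 0, exited = 0) {
  s <- c(
    no_caries = as.numeric(no_caries), caries = as.numeric(caries),
    treated = as.numeric(treated), exited = as.numeric(exited)
  )
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("state occupancies must be finite and >= 0")
  }
  structure(s, class = "state_occupancy")
}

check_conservation <- function(state, cohort_size, where = "transition") {
  if (abs(sum(state) - cohort_size) > 1e-9 * max(1, cohort_size)) {
    stop(sprintf(
      "internal consistency error in %s: occupancy sum %.12g != cohort size %.12g",
      where, sum(state), cohort_size
    ))
  }
  if (any(state < -1e-12 * max(1, cohort_size))) {
    stop("internal consistency error: negative occupancy after ", where)
  }
  invisible(state)
}

#' Advance the cohort one annual cycle
#'
#' One step of the four-state model. Exit is applied to every living state
#' (independently of morbidity, absorbing, no re-entry); then caries-free
#' learners develop caries with probability `prob_caries * (1 - effect)`,
#' learners with caries receive treatment with probability
#' `1 - prob_untreated`, and treated learners relapse with probability
#' `prob_recurrence`. Occupancy is conserved exactly.
#'
#' @param state A [state_occupancy()].
#' @param age_params One row of an [age_schedule()].
#' @param effect Effectiveness applied to the caries-entry flow, proportion
#'   in `[0, 1]` (0 under the DMFT-accrual mechanism).
#' @param config A [model_config()]; uses `prob_untreated`, `prob_recurrence`
#'   and `exit_first`.
#' @return The next cycle's [state_occupancy()].
#' @export
transition_step <- function(state, age_params, effect, config) {
  if (!is.numeric(effect) || effect < 0 || effect > 1) {
    stop("effect must be a proportion in [0, 1]")
  }
  cohort <- sum(state)
  pe <- age_params$prob_exit
  pc <- age_params$prob_caries
  no <- state[["no_caries"]]
  ca <- state[["caries"]]
  tr <- state[["treated"]]
  ex <- state[["exited"]]

  morbidity <- function(no, ca, tr) {
    entrants <- no * pc * (1 - effect)
    to_treated <- ca * (1 - config$prob_untreated)
    relapse <- tr * config$prob_recurrence
    c(
      no = no - entrants,
      ca = ca - to_treated + entrants + relapse,
      tr = tr - relapse + to_treated
    )
  }

  if (config$exit_first) {
    ex <- ex + (no + ca + tr) * pe
    m <- morbidity(no * (1 - pe), ca * (1 - pe), tr * (1 - pe))
  } else {
    m <- morbidity(no, ca, tr)
    ex <- ex + sum(m) * pe
    m <- m * (1 - pe)
  }
  out <- state_occupancy(m[["no"]], m[["ca"]], m[["tr"]], ex)
  check_conservation(out, cohort)
  out
}

#' DMFT accrued by the cohort in one cycle
#'
#' New caries cases in the cycle accrue the age's baseline mean DMFT, grown
#' by the assumed annual DMFT growth since the start of follow-up. The
#' increment scales linearly with `1 - effect` through the entrant flow.
#'
#' @param state Start-of-cycle [state_occupancy()].
#' @param age_params One row of an [age_schedule()].
#' @param effect Effectiveness as a proportion in `[0, 1]`.
#' @param cycle_index 0-based cycle number (drives the DMFT growth factor).
#' @param config A [model_config()]; uses `dmft_growth` and `exit_first`.
#' @return Undiscounted DMFT added to the cohort during the cycle (>= 0).
#' @export
dmft_increment <- function(state, age_params, effect, cycle_index, config) {
  at_risk <- state[["no_caries"]] *
    (if (config$exit_first) 1 - age_params$prob_exit else 1)
  entrants <- at_risk * age_params$prob_caries * (1 - effect)
  entrants * age_params$baseline_dmft * (1 + config$dmft_growth)^cycle_index
}

#' Annual DMFT reduction from lower sugar intake
#'
#' Linear sugar-caries dose response: each g/day of added sugar removed
#' averts `sugar_slope` DMFT per learner per year.
#'
#' @param reduction_g_per_day Reduction in added sugar intake, g/day (>= 0).
#' @param config A [model_config()]; uses `sugar_slope`.
#' @return DMFT averted per living learner per year.
#' @export
sugar_dmft_reduction <- function(reduction_g_per_day, config) {
  if (any(reduction_g_per_day < 0)) stop("sugar reduction must be >= 0")
  config$sugar_slope * reduction_g_per_day
}

#' Run one intervention arm through the Markov cohort
#'
#' Advances the closed cohort over all annual cycles for one arm. Learners
#' present at the start of each cycle accrue the arm's annual per-learner
#' cost, plus the screening cost when the arm bundles screening; costs and
#' DMFT increments are discounted at the model's rate (cycle 0 undiscounted).
#' The do-nothing comparator (`spec = NULL`) accrues no cost. The sugar
#' policy arm, under the `"slope"` mechanism, subtracts the linear
#' dose-response offset from each cycle's DMFT increment (floored at zero);
#' under the `"effect"` mechanism, or whenever `effect_override` is supplied
#' (as in the PSA), it behaves like the clinical arms.
#'
#' @param spec An [intervention_spec()], or `NULL` for do-nothing.
#' @param schedule An [age_schedule()] with one row per cycle.
#' @param config A [model_config()].
#' @param effect_override Optional effectiveness as a proportion in `[0, 1]`
#'   replacing the spec's mean (used by the PSA).
#' @param cost_override Optional annual per-learner cost replacing the spec's
#'   mean (used by the PSA).
#' @param donothing_dmft Optional precomputed do-nothing total DMFT on the
#'   same schedule; computed internally when absent.
#' @return A list with `trace` (a `cohort_trace` data frame: start-of-cycle
#'   occupancies and per-cycle discounted/undiscounted cost and DMFT, with a
#'   `totals` attribute) and `result` (an `arm_result`: `name`, `total_cost`,
#'   `total_dmft`, `dmft_averted`, `average_lifetime_cost`).
#' @export
run_arm <- function(spec, schedule, config,
                    effect_override = NULL, cost_override = NULL,
                    donothing_dmft = NULL) {
  validate_schedule(schedule, config)
  if (!is.null(effect_override) &&
      (effect_override < 0 || effect_override > 1)) {
    stop("effect_override must be a proportion in [0, 1]")
  }
  is_dn <- is.null(spec)
  if (is_dn) {
    name <- "Do nothing"
    per_learner_cost <- 0
    effect <- 0
    sugar_offset <- 0
  } else {
    name <- spec$name
    annual_cost <- cost_override %||% spec$annual_cost_mean
    per_learner_cost <- annual_cost +
      if (spec$requires_screening) config$screening_cost else 0
    slope_arm <- spec$is_sugar_policy &&
      config$sugar_mechanism == "slope" && is.null(effect_override)
    effect <- if (slope_arm) 0 else effect_override %||% (spec$effect_mean / 100)
    sugar_offset <- if (slope_arm) {
      sugar_dmft_reduction(config$sugar_reduction, config)
    } else {
      0
    }
  }
  eff_flow <- if (config$effect_mechanism == "flow") effect else 0

  n <- config$n_cycles
  state <- state_occupancy(config$cohort_size)
  occ <- matrix(NA_real_, nrow = n, ncol = 4,
    dimnames = list(NULL, c("no_caries", "caries", "treated", "exited"))
  )
  cost_u <- dmft_u <- disc <- numeric(n)
  for (t in seq_len(n) - 1L) {
    row <- schedule[t + 1L, ]
    occ[t + 1L, ] <- unclass(state)
    living <- sum(state[c("no_caries", "caries", "treated")])
    disc[t + 1L] <- discount_factor(t, config$discount_rate)
    cost_u[t + 1L] <- living * per_learner_cost
    inc <- dmft_increment(state, row, effect, t, config)
    dmft_u[t + 1L] <- max(0, inc - sugar_offset * living)
    state <- transition_step(state, row, eff_flow, config)
    check_conservation(state, config$cohort_size, where = paste("cycle", t))
  }
  trace <- structure(
    data.frame(
      cycle = seq_len(n) - 1L, occ,
      cost = cost_u * disc, cost_undiscounted = cost_u,
      dmft = dmft_u * disc, dmft_undiscounted = dmft_u
    ),
    class = c("cohort_trace", "data.frame")
  )
  attr(trace, "totals") <- c(
    total_cost = sum(cost_u * disc),
    total_cost_undiscounted = sum(cost_u),
    total_dmft = sum(dmft_u * disc),
    total_dmft_undiscounted = sum(dmft_u)
  )
  total_dmft <- sum(dmft_u * disc)
  if (is_dn) {
    averted <- 0
  } else {
    base <- donothing_dmft %||%
      attr(run_arm(NULL, schedule, config)$trace, "totals")[["total_dmft"]]
    averted <- base - total_dmft
  }
  result <- arm_result(
    name = name,
    total_cost = sum(cost_u * disc),
    dmft_averted = averted,
    cohort_size = config$cohort_size,
    total_dmft = total_dmft
  )
  list(trace = trace, result = result)
}

#' Arm-level cost-effectiveness inputs
#'
#' The per-arm summary the CEA layer consumes: total discounted cost, DMFT
#' averted versus do-nothing, and the average lifetime (per-learner) cost.
#' Can be built directly from externally supplied totals ("fixture mode"),
#' e.g. a published results table, independently of the cohort engine.
#'
#' @param name Arm label.
#' @param total_cost Total discounted cost, ZAR.
#' @param dmft_averted DMFT averted versus do-nothing.
#' @param cohort_size Cohort size used to derive the average lifetime cost.
#' @param total_dmft Optional total DMFT of the arm itself.
#' @return An object of class `arm_result`.
#' @export
arm_result <- function(name, total_cost, dmft_averted, cohort_size,
                       total_dmft = NA_real_) {
  structure(
    list(
      name = as.character(name),
      total_cost = as.numeric(total_cost),
      dmft_averted = as.numeric(dmft_averted),
      average_lifetime_cost = as.numeric(total_cost) / as.numeric(cohort_size),
      total_dmft = as.numeric(total_dmft),
      cohort_size = as.numeric(cohort_size)
    ),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf(
    "<arm_result> %s: total cost ZAR%.0f, DMFT averted %.1f, avg lifetime cost ZAR%.0f\n",
    x$name, x$total_cost, x$dmft_averted, x$average_lifetime_cost
  ))
  invisible(x)
}

#' Run every arm of an analysis
#'
#' Runs do-nothing plus every configured intervention on the same schedule,
#' computing each arm's DMFT averted against the shared do-nothing run.
#'
#' @param config A [model_config()].
#' @param specs List of [intervention_spec()].
#' @param schedule An [age_schedule()].
#' @return A list with `results` (list of `arm_result`, do-nothing first) and
#'   `traces` (named list of `cohort_trace`).
#' @export
run_all_arms <- function(config, specs, schedule) {
  validate_spec_list(specs)
  dn <- run_arm(NULL, schedule, config)
  base <- attr(dn$trace, "totals")[["total_dmft"]]
  runs <- lapply(specs, run_arm,
    schedule = schedule, config = config, donothing_dmft = base
  )
  results <- c(list(dn$result), lapply(runs, `[[`, "result"))
  traces <- c(list(dn$trace), lapply(runs, `[[`, "trace"))
  names(traces) <- vapply(results, `[[`, character(1), "name")
  list(results = results, traces = traces)
}

#' Export a cohort trace as tidy CSV
#'
#' Long format: one row per cycle and state with its occupancy, plus the
#' cycle's discounted cost and DMFT repeated per state block.
#'
#' @param trace A `cohort_trace` from [run_arm()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  states <- c("no_caries", "caries", "treated", "exited")
  tidy <- do.call(rbind, lapply(states, function(s) {
    data.frame(
      cycle = trace$cycle, state = s, occupancy = trace[[s]],
      cost = trace$cost, dmft = trace$dmft
    )
  }))
  tidy <- tidy[order(tidy$cycle, match(tidy$state, states)), ]
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}
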