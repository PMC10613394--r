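#' Age-indexed parameter schedule
#'
#' One row per modelled age carrying the annual probability of developing
#' caries, the annual probability of leaving the cohort (school drop-out,
#' relocation, transfer to private school), and the baseline mean DMFT
#' accrued per incident caries case at that age.
#'
#' @param ages Integer ages, `start_age ... exit_age - 1`.
#' @param prob_caries Annual probability of developing caries, per age.
#' @param prob_exit Annual probability of leaving the cohort, per age.
#' @param baseline_dmft Baseline mean DMFT per incident case, per age.
#' @return A data frame of class `age_schedule`.
#' @export
age_schedule <- function(ages, prob_caries, prob_exit, baseline_dmft) {
  sched <- structure(
    data.frame(
      age = as.numeric(ages),
      prob_caries = as.numeric(prob_caries),
      prob_exit = as.numeric(prob_exit),
      baseline_dmft = as.numeric(baseline_dmft)
    ),
    class = c("age_schedule", "data.frame")
  )
  validate_schedule(sched)
  sched
}

#' Validate an age schedule
#'
#' @param schedule An [age_schedule()].
#' @param config Optionally, a [model_config()]; if given, the schedule length
#'   must equal `config$n_cycles` and ages must run from `start_age`.
#' @return `schedule`, invisibly.
#' @export
validate_schedule <- function(schedule, config = NULL) {
  p <- character()
  need <- c("age", "prob_caries", "prob_exit", "baseline_dmft")
  miss <- setdiff(need, names(schedule))
  if (length(miss)) {
    validation_error(paste("missing column(s):", paste(miss, collapse = ", ")),
      what = "age schedule"
    )
  }
  if (nrow(schedule) < 1) p <- c(p, "schedule must have at least one row")
  if (!all(is_prob_vec(schedule$prob_caries))) p <- c(p, "prob_caries must be in [0, 1]")
  if (!all(is_prob_vec(schedule$prob_exit))) p <- c(p, "prob_exit must be in [0, 1]")
  if (any(!is.finite(schedule$baseline_dmft) | schedule$baseline_dmft < 0)) {
    p <- c(p, "baseline_dmft must be >= 0")
  }
  if (!is.null(config)) {
    if (nrow(schedule) != config$n_cycles) {
      p <- c(p, sprintf(
        "schedule has %d rows but the model needs one per cycle (%d)",
        nrow(schedule), config$n_cycles
      ))
    }
    if (nrow(schedule) && schedule$age[1] != config$start_age) {
      p <- c(p, sprintf(
        "schedule starts at age %g but the model starts at %g",
        schedule$age[1], config$start_age
      ))
    }
  }
  if (length(p)) validation_error(p, "age schedule")
  invisible(schedule)
}

is_prob_vec <- function(x) is.finite(x) & x >= 0 & x <= 1

#' Generate a synthetic age schedule
#'
#' The published analysis keeps its age-dependent inputs (annual caries
#' probability, exit probability, baseline DMFT) in an appendix that is not
#' reproduced here, so this generator produces plausible, fully seeded
#' stand-in schedules. Caries risk is either flat or non-decreasing with age
#' (caries experience is age dependent); the exit probability is held flat
#' across ages (drop-out is roughly constant through primary school); the
#' per-case baseline DMFT rises moderately with age.
#'
#' @param seed Integer seed; the schedule is a pure function of the seed and
#'   the remaining arguments.
#' @param level_caries Overall annual caries probability level, in `[0, 1]`.
#' @param level_exit Annual exit probability, in `[0, 1]`.
#' @param dmft_at_start Baseline mean DMFT per incident case at the start age.
#' @param shape `"increasing"` (default) ramps caries risk with age;
#'   `"flat"` holds every column exactly constant.
#' @param config A [model_config()] supplying ages and cycle count.
#' @return An [age_schedule()].
#' @export
generate_age_schedule <- function(seed,
                                  level_caries = 0.2,
                                  level_exit = 0.03,
                                  dmft_at_start = 1.2,
                                  shape = c("increasing", "flat"),
                                  config = model_config()) {
  shape <- match.arg(shape)
  if (!is_prob(level_caries)) validation_error("level_caries must be in [0, 1]", "generator arguments")
  if (!is_prob(level_exit)) validation_error("level_exit must be in [0, 1]", "generator arguments")
  if (!is.numeric(dmft_at_start) || dmft_at_start < 0) {
    validation_error("dmft_at_start must be >= 0", "generator arguments")
  }
  n <- config$n_cycles
  ages <- config$start_age + seq_len(n) - 1
  if (shape == "flat") {
    return(age_schedule(ages,
      prob_caries = rep(level_caries, n),
      prob_exit = rep(level_exit, n),
      baseline_dmft = rep(dmft_at_start, n)
    ))
  }
  jitter <- with_local_seed(as.integer(seed), stats::runif(n, -0.03, 0.03))
  ramp <- seq(0.7, 1.3, length.out = n)
  pc <- cummax(pmin(1, pmax(0, level_caries * (ramp + jitter))))
  dmft <- dmft_at_start * seq(1, 1.6, length.out = n)
  age_schedule(ages,
    prob_caries = pc,
    prob_exit = rep(level_exit, n),
    baseline_dmft = dmft
  )
}

# Run expr under a temporary RNG state so package internals never disturb the
# caller's random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

calibration_error <- function(msg, achievable = NULL) {
  stop(structure(
    class = c("cariesCEA_calibration_error", "error", "condition"),
    list(message = msg, call = NULL, achievable = achievable)
  ))
}

scale_column <- function(schedule, column, multiplier) {
  schedule[[column]] <- schedule[[column]] * multiplier
  if (any(schedule[[column]] > 1 + 1e-12)) {
    calibration_error(sprintf(
      "multiplier %g pushes %s above 1; refusing to clamp", multiplier, column
    ))
  }
  schedule[[column]] <- pmin(schedule[[column]], 1)
  schedule
}

# Monotone scalar root finding by bisection on g(m) = f(m) - target over
# [lo, hi]; f must be continuous and monotone on the bracket.
bisect_multiplier <- function(f, target, lo, hi, tol = 1e-6, max_iter = 200) {
  g_lo <- f(lo) - target
  g_hi <- f(hi) - target
  if (g_lo == 0) return(lo)
  if (g_hi == 0) return(hi)
  if (sign(g_lo) == sign(g_hi)) {
    calibration_error(
      sprintf(
        "target %.6g is outside the achievable range [%.6g, %.6g]",
        target, min(f(lo), f(hi)), max(f(lo), f(hi))
      ),
      achievable = sort(c(f(lo), f(hi)))
    )
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g_mid <- f(mid) - target
    if (g_mid == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(g_mid) == sign(g_lo)) {
      lo <- mid
      g_lo <- g_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Total screening cost of a schedule
#'
#' The 10-year screening programme cost implied by a schedule: the annual
#' per-learner screening cost accrued by every learner present at the start
#' of each cycle, summed over cycles, optionally discounted.
#'
#' @param schedule An [age_schedule()].
#' @param config A [model_config()].
#' @param discounted If `TRUE`, discount each cycle at `config$discount_rate`.
#' @return Total screening cost in ZAR.
#' @export
screening_cost_total <- function(schedule, config, discounted = FALSE) {
  probe <- intervention_spec("screening-only", 0, 0, 0, requires_screening = TRUE)
  run <- run_arm(probe, schedule, config)
  if (discounted) run$result$total_cost else attr(run$trace, "totals")[["total_cost_undiscounted"]]
}

#' Calibrate an age schedule to printed aggregates
#'
#' Fits a single multiplier on the schedule's exit probabilities, by bisection
#' on a bracketing interval, so that the model's 10-year screening-programme
#' cost matches a published aggregate within a relative tolerance. Optionally
#' fits a second multiplier on the caries probabilities so that the
#' do-nothing arm's total (discounted) DMFT matches a target. Multipliers are
#' reported as the `"multipliers"` attribute; a target outside what
#' probability bounds allow raises a calibration error reporting the
#' achievable range rather than clamping.
#'
#' @param schedule An [age_schedule()].
#' @param config A [model_config()].
#' @param target_screening_cost Published total screening cost, ZAR.
#' @param target_donothing_dmft Optional target for the do-nothing arm's
#'   total discounted DMFT.
#' @param tol_rel Required relative accuracy of the fitted aggregate
#'   (default 0.005, i.e. 0.5\%).
#' @param measure Whether the screening-cost target is an `"undiscounted"`
#'   implementation budget (default, as published) or a `"discounted"` total.
#' @param bisect_tol Bisection tolerance on the multiplier.
#' @param max_iter Bisection iteration cap.
#' @return The calibrated [age_schedule()], with attribute `multipliers`
#'   (named numeric: `exit`, and `caries` when a DMFT target is given).
#' @export
calibrate_schedule <- function(schedule, config, target_screening_cost,
                               target_donothing_dmft = NULL,
                               tol_rel = 0.005,
                               measure = c("undiscounted", "discounted"),
                               bisect_tol = 1e-6, max_iter = 200) {
  measure <- match.arg(measure)
  validate_schedule(schedule, config)
  if (!is.numeric(target_screening_cost) || target_screening_cost <= 0) {
    calibration_error("target_screening_cost must be positive")
  }
  discounted <- measure == "discounted"

  f_cost <- function(m) {
    screening_cost_total(scale_column(schedule, "prob_exit", m), config,
      discounted = discounted
    )
  }
  max_pe <- max(schedule$prob_exit)
  if (max_pe == 0) {
    # exits cannot move the aggregate; accept only if already on target
    now <- f_cost(1)
    if (abs(now - target_screening_cost) / target_screening_cost > tol_rel) {
      calibration_error(sprintf(
        "schedule has no exits, screening cost is fixed at %.6g (target %.6g)",
        now, target_screening_cost
      ), achievable = c(now, now))
    }
    m_exit <- 1
  } else {
    m_exit <- bisect_multiplier(
      f_cost, target_screening_cost,
      lo = 0, hi = 1 / max_pe, tol = bisect_tol, max_iter = max_iter
    )
  }
  out <- scale_column(schedule, "prob_exit", m_exit)
  achieved <- screening_cost_total(out, config, discounted = discounted)
  if (abs(achieved - target_screening_cost) / target_screening_cost > tol_rel) {
    calibration_error(sprintf(
      "calibrated screening cost %.6g misses target %.6g beyond tolerance %.3g",
      achieved, target_screening_cost, tol_rel
    ))
  }
  multipliers <- c(exit = m_exit)

  if (!is.null(target_donothing_dmft)) {
    if (!is.numeric(target_donothing_dmft) || target_donothing_dmft <= 0) {
      calibration_error("target_donothing_dmft must be positive")
    }
    f_dmft <- function(k) {
      tr <- run_arm(NULL, scale_column(out, "prob_caries", k), config)$trace
      attr(tr, "totals")[["total_dmft"]]
    }
    max_pc <- max(out$prob_caries)
    if (max_pc == 0) calibration_error("schedule has no caries risk to scale")
    k_caries <- bisect_multiplier(
      f_dmft, target_donothing_dmft,
      lo = 0, hi = 1 / max_pc, tol = bisect_tol, max_iter = max_iter
    )
    out <- scale_column(out, "prob_caries", k_caries)
    got <- f_dmft(1)
    if (abs(got - target_donothing_dmft) / target_donothing_dmft > tol_rel) {
      calibration_error(sprintf(
        "calibrated do-nothing DMFT %.6g misses target %.6g beyond tolerance %.3g",
        got, target_donothing_dmft, tol_rel
      ))
    }
    multipliers <- c(multipliers, caries = k_caries)
  }
  attr(out, "multipliers") <- multipliers
  out
}

#' Write an age schedule to CSV
#'
#' @param schedule An [age_schedule()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' Read an age schedule from CSV
#'
#' @param path CSV with columns `age, prob_caries, prob_exit, baseline_dmft`.
#' @param config Optional [model_config()] for length/age validation.
#' @return An [age_schedule()].
#' @export
read_schedule <- function(path, config = NULL) {
  df <- utils::read.csv(path)
  sched <- age_schedule(df$age, df$prob_caries, df$prob_exit, df$baseline_dmft)
  if (!is.null(config)) validate_schedule(sched, config)
  sched
}
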