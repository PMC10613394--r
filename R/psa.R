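#' Moment-matched gamma parameters
#'
#' Shape/scale of the gamma distribution with the requested mean and
#' standard deviation: `shape = mean^2 / sd^2`, `scale = sd^2 / mean`.
#'
#' @param mean,sd Positive mean and standard deviation (native scale).
#' @return Named numeric vector `c(shape, scale)`.
#' @export
gamma_params <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || mean <= 0 || sd <= 0) {
    stop("gamma moment matching needs mean > 0 and sd > 0")
  }
  c(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Moment-matched beta parameters
#'
#' Converts a percentage-scale mean and SD to proportions and moment-matches
#' a beta distribution: with `m = mean/100`, `s = sd/100`,
#' `nu = m(1-m)/s^2 - 1`, `alpha = m nu`, `beta = (1-m) nu`. An SD at or
#' beyond the feasible bound `sqrt(m(1-m))` is an error (no silent clipping):
#' the stated uncertainty cannot be represented by a beta distribution.
#'
#' @param mean_pct Mean percentage in (0, 100).
#' @param sd_pct Standard deviation, percentage points (> 0).
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
beta_params <- function(mean_pct, sd_pct) {
  m <- mean_pct / 100
  s <- sd_pct / 100
  if (!is.numeric(m) || m <= 0 || m >= 1) {
    stop("beta moment matching needs a mean strictly inside (0, 100)%")
  }
  if (!is.numeric(s) || s <= 0) stop("beta moment matching needs sd > 0")
  if (s^2 >= m * (1 - m)) {
    stop(sprintf(
      "infeasible beta variance: sd %.4g%% >= feasible bound %.4g%% for mean %.4g%%",
      sd_pct, 100 * sqrt(m * (1 - m)), mean_pct
    ))
  }
  nu <- m * (1 - m) / s^2 - 1
  c(alpha = m * nu, beta = (1 - m) * nu)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty through the cohort
#' engine: per iteration, each arm's annual per-learner cost is drawn from
#' its moment-matched gamma distribution and its effectiveness from its
#' moment-matched beta distribution, and the arm is re-run with those values.
#' Age schedules and structural probabilities are held fixed. One random
#' stream is used per run, in arm-major order (all of an arm's costs, then
#' all of its effectiveness draws), so results are a pure function of
#' `(inputs, seed)`. Sampled effectiveness enters every arm, including the
#' sugar policy, through the standard effect mechanism.
#'
#' @param config A [model_config()].
#' @param specs List of [intervention_spec()].
#' @param schedule An [age_schedule()].
#' @param n_iterations Number of Monte Carlo iterations (default 1000).
#' @param seed Integer seed.
#' @return A data frame of class `psa_samples` with one row per iteration and
#'   arm (do-nothing included): `iteration`, `arm`, `annual_cost`, `effect`
#'   (proportion), `total_cost`, `dmft_averted`. Attributes: `n_iterations`,
#'   `seed`, `cohort_size`.
#' @export
run_psa <- function(config, specs, schedule, n_iterations = 1000, seed = 1) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  validate_spec_list(specs)
  validate_schedule(schedule, config)
  n <- as.integer(n_iterations)
  draws <- with_local_seed(as.integer(seed), {
    lapply(specs, function(s) {
      g <- tryCatch(gamma_params(s$annual_cost_mean, s$annual_cost_sd),
        error = function(e) {
          stop(sprintf("arm '%s', cost: %s", s$name, conditionMessage(e)))
        }
      )
      b <- tryCatch(beta_params(s$effect_mean, s$effect_sd),
        error = function(e) {
          stop(sprintf("arm '%s', effectiveness: %s", s$name, conditionMessage(e)))
        }
      )
      list(
        cost = stats::rgamma(n, shape = g[["shape"]], scale = g[["scale"]]),
        effect = stats::rbeta(n, b[["alpha"]], b[["beta"]])
      )
    })
  })
  base <- attr(run_arm(NULL, schedule, config)$trace, "totals")[["total_dmft"]]
  rows <- vector("list", length(specs) + 1)
  rows[[1]] <- data.frame(
    iteration = seq_len(n), arm = "Do nothing",
    annual_cost = 0, effect = 0, total_cost = 0, dmft_averted = 0
  )
  for (a in seq_along(specs)) {
    tc <- da <- numeric(n)
    for (i in seq_len(n)) {
      res <- run_arm(specs[[a]], schedule, config,
        effect_override = draws[[a]]$effect[i],
        cost_override = draws[[a]]$cost[i],
        donothing_dmft = base
      )$result
      tc[i] <- res$total_cost
      da[i] <- res$dmft_averted
    }
    rows[[a + 1]] <- data.frame(
      iteration = seq_len(n), arm = specs[[a]]$name,
      annual_cost = draws[[a]]$cost, effect = draws[[a]]$effect,
      total_cost = tc, dmft_averted = da
    )
  }
  samples <- do.call(rbind, rows)
  attr(samples, "n_iterations") <- n
  attr(samples, "seed") <- as.integer(seed)
  attr(samples, "cohort_size") <- config$cohort_size
  class(samples) <- c("psa_samples", "data.frame")
  samples
}

#' Default willingness-to-pay grid
#'
#' ZAR 0 to 40,000 in steps of 500, covering the thresholds discussed for
#' this analysis (ZAR500 and ZAR38,500).
#'
#' @return Numeric vector of thresholds.
#' @export
default_wtp_grid <- function() seq(0, 40000, by = 500)

samples_matrices <- function(samples) {
  arms <- unique(samples$arm)
  n <- attr(samples, "n_iterations") %||% max(samples$iteration)
  cost <- eff <- matrix(NA_real_, n, length(arms), dimnames = list(NULL, arms))
  for (a in arms) {
    sub <- samples[samples$arm == a, ]
    sub <- sub[order(sub$iteration), ]
    cost[, a] <- sub$total_cost
    eff[, a] <- sub$dmft_averted
  }
  if (anyNA(cost) || anyNA(eff)) stop("psa_samples is not rectangular")
  list(cost = cost, effect = eff, arms = arms, n = n)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay threshold, each strategy's probability of
#' being cost-effective is the fraction of PSA iterations in which it attains
#' the strictly highest net monetary benefit among all mutually exclusive
#' strategies (do-nothing included); exact ties share the iteration equally.
#' Probabilities therefore sum to 1 across strategies at every threshold.
#' A `pairwise = TRUE` variant instead reports, per intervention, the
#' probability that its NMB exceeds do-nothing's.
#'
#' @param samples A `psa_samples` from [run_psa()].
#' @param wtp_grid Non-empty numeric vector of thresholds (default
#'   [default_wtp_grid()]).
#' @param pairwise Use the pairwise-versus-do-nothing convention.
#' @return A data frame of class `ceac_curve`: `wtp`, `arm`, `probability`.
#' @export
ceac <- function(samples, wtp_grid = default_wtp_grid(), pairwise = FALSE) {
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty")
  if (!nrow(samples)) stop("samples must be non-empty")
  m <- samples_matrices(samples)
  out <- lapply(wtp_grid, function(w) {
    b <- w * m$effect - m$cost
    if (pairwise) {
      ref <- b[, "Do nothing"]
      p <- colMeans(b > ref)
    } else {
      best <- apply(b, 1, max)
      is_best <- b == best
      p <- colMeans(is_best / rowSums(is_best))
    }
    data.frame(wtp = w, arm = m$arms, probability = as.numeric(p[m$arms]))
  })
  curve <- do.call(rbind, out)
  rownames(curve) <- NULL
  class(curve) <- c("ceac_curve", "data.frame")
  curve
}

#' Summarize a probabilistic sensitivity analysis
#'
#' Per-strategy Monte Carlo summary mirroring the deterministic table: mean
#' and SD of total cost and DMFT averted, average lifetime cost of the mean,
#' ICER of the means against do-nothing, ranked incremental ICER of the
#' means, and mean net monetary benefit at the threshold.
#'
#' @param samples A `psa_samples` from [run_psa()].
#' @param wtp Willingness-to-pay threshold, ZAR per DMFT averted.
#' @return A data frame, one row per strategy, ranked ascending by mean
#'   DMFT averted.
#' @export
summarize_psa <- function(samples, wtp) {
  if (!nrow(samples)) stop("samples must be non-empty")
  m <- samples_matrices(samples)
  cohort <- attr(samples, "cohort_size") %||% NA_real_
  mean_results <- lapply(m$arms, function(a) {
    arm_result(a, mean(m$cost[, a]), mean(m$effect[, a]), cohort)
  })
  tab <- cea_table(mean_results, wtp = wtp)
  names(tab)[names(tab) == "total_cost"] <- "mean_cost"
  names(tab)[names(tab) == "dmft_averted"] <- "mean_dmft_averted"
  names(tab)[names(tab) == "nmb"] <- "mean_nmb"
  sds <- data.frame(
    name = m$arms,
    sd_cost = apply(m$cost, 2, stats::sd),
    sd_dmft = apply(m$effect, 2, stats::sd)
  )
  out <- merge(tab, sds, by = "name", sort = FALSE)
  out <- out[order(out$mean_dmft_averted, out$mean_cost), ]
  rownames(out) <- NULL
  out
}
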