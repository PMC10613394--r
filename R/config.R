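#' Global model configuration
#'
#' Creates the validated set of global parameters for the caries Markov cohort
#' model: the closed cohort of school learners, the annual cycle structure,
#' discounting, the structural transition probabilities, the assumed annual
#' DMFT growth, the sugar-caries dose slope, the screening cost bundled with
#' clinical prevention arms, and the willingness-to-pay threshold used for net
#' monetary benefit.
#'
#' @param cohort_size Number of learners in the closed cohort.
#' @param start_age Age (years) at which learners enter the cohort.
#' @param exit_age Age (years) at which all remaining learners leave the model.
#' @param n_cycles Number of annual cycles; must equal `exit_age - start_age`.
#' @param discount_rate Annual discount rate applied to both costs and DMFT,
#'   as a proportion in `[0, 1)`.
#' @param prob_untreated Probability that a learner with caries remains
#'   untreated in a given year (the complement moves to the treated state).
#' @param prob_recurrence Annual probability of caries recurrence after
#'   treatment (treated back to caries).
#' @param dmft_growth Annual proportional growth of the per-case DMFT accrual
#'   over the follow-up period (0.0059 = 0.59\% per year).
#' @param sugar_slope DMFT increase per learner per year attributable to each
#'   additional g/day of added sugar intake.
#' @param sugar_reduction Modelled reduction in added sugar intake, g/day.
#' @param screening_cost Annual per-learner cost (ZAR) of the oral-health
#'   screening bundled with every clinical prevention arm.
#' @param wtp Willingness-to-pay threshold, ZAR per DMFT averted.
#' @param effect_mechanism How intervention effectiveness acts: `"dmft"`
#'   scales the cohort's DMFT accrual directly (state dynamics unchanged, so
#'   averted DMFT is exactly proportional to effectiveness); `"flow"` reduces
#'   the annual probability of developing caries instead.
#' @param sugar_mechanism How the sugar-reduction arm averts DMFT in the
#'   deterministic model: `"slope"` applies the linear dose slope
#'   (`sugar_slope * sugar_reduction` DMFT per living learner per year) as an
#'   absolute offset; `"effect"` treats the arm like the clinical arms,
#'   using its percentage effectiveness.
#' @param exit_first If `TRUE` (default) the annual exit probability is
#'   applied before the morbidity transitions within each cycle.
#'
#' @return An object of class `model_config` (a validated named list).
#' @seealso [intervention_spec()], [load_config()], [default_config()]
#' @export
model_config <- function(cohort_size = 10000,
                         start_age = 5,
                         exit_age = 15,
                         n_cycles = exit_age - start_age,
                         discount_rate = 0.05,
                         prob_untreated = 0.7,
                         prob_recurrence = 0.188,
                         dmft_growth = 0.0059,
                         sugar_slope = 0.0128,
                         sugar_reduction = 30,
                         screening_cost = 525.61,
                         wtp = 38500,
                         effect_mechanism = c("dmft", "flow"),
                         sugar_mechanism = c("slope", "effect"),
                         exit_first = TRUE) {
  effect_mechanism <- match.arg(effect_mechanism)
  sugar_mechanism <- match.arg(sugar_mechanism)
  cfg <- structure(
    list(
      cohort_size = as.numeric(cohort_size),
      start_age = as.numeric(start_age),
      exit_age = as.numeric(exit_age),
      n_cycles = as.integer(n_cycles),
      discount_rate = as.numeric(discount_rate),
      prob_untreated = as.numeric(prob_untreated),
      prob_recurrence = as.numeric(prob_recurrence),
      dmft_growth = as.numeric(dmft_growth),
      sugar_slope = as.numeric(sugar_slope),
      sugar_reduction = as.numeric(sugar_reduction),
      screening_cost = as.numeric(screening_cost),
      wtp = as.numeric(wtp),
      effect_mechanism = effect_mechanism,
      sugar_mechanism = sugar_mechanism,
      exit_first = isTRUE(exit_first)
    ),
    class = "model_config"
  )
  validate_config(cfg)
  cfg
}

#' Intervention arm specification
#'
#' One prevention strategy's per-learner annual cost and percentage
#' effectiveness (DMFT reduction), with the distribution metadata used by the
#' probabilistic sensitivity analysis: a gamma distribution for the cost and a
#' beta distribution for the effectiveness. A missing cost standard deviation
#' is imputed as 10\% of the mean.
#'
#' @param name Arm label.
#' @param annual_cost_mean Mean annual per-learner programme cost, ZAR.
#' @param annual_cost_sd Standard deviation of the annual cost, ZAR. If `NULL`,
#'   set to 10\% of `annual_cost_mean`.
#' @param effect_mean Mean percentage reduction of DMFT (0-100 scale).
#' @param effect_sd Standard deviation of the percentage reduction.
#' @param requires_screening Whether the screening programme (and its cost)
#'   is bundled with this arm.
#' @param is_sugar_policy Whether this arm is the population sugar-reduction
#'   policy, which can use the linear dose-slope mechanism.
#' @param cost_distribution,effect_distribution Distribution family tags used
#'   by the PSA; only `"gamma"` and `"beta"` are supported.
#'
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(name,
                              annual_cost_mean,
                              effect_mean,
                              effect_sd,
                              annual_cost_sd = NULL,
                              requires_screening = TRUE,
                              is_sugar_policy = FALSE,
                              cost_distribution = "gamma",
                              effect_distribution = "beta") {
  sd_imputed <- is.null(annual_cost_sd)
  if (sd_imputed) annual_cost_sd <- 0.1 * annual_cost_mean
  spec <- structure(
    list(
      name = as.character(name),
      annual_cost_mean = as.numeric(annual_cost_mean),
      annual_cost_sd = as.numeric(annual_cost_sd),
      effect_mean = as.numeric(effect_mean),
      effect_sd = as.numeric(effect_sd),
      requires_screening = isTRUE(requires_screening),
      is_sugar_policy = isTRUE(is_sugar_policy),
      cost_distribution = as.character(cost_distribution),
      effect_distribution = as.character(effect_distribution),
      sd_imputed = sd_imputed
    ),
    class = "intervention_spec"
  )
  validate_spec(spec)
  spec
}

validation_error <- function(problems, what = "configuration") {
  stop(structure(
    class = c("cariesCEA_validation_error", "error", "condition"),
    list(
      message = paste0(
        "invalid ", what, ":\n",
        paste0("  - ", problems, collapse = "\n")
      ),
      call = NULL,
      problems = problems
    )
  ))
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

#' Validate a model configuration
#'
#' Checks every invariant of [model_config()] and reports all violations at
#' once rather than stopping at the first.
#'
#' @param config A `model_config`.
#' @return `config`, invisibly, if valid; otherwise an error of class
#'   `cariesCEA_validation_error` listing every violated invariant.
#' @export
validate_config <- function(config) {
  p <- character()
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(config$cohort_size) || config$cohort_size <= 0) {
    p <- c(p, "cohort_size must be a positive number")
  }
  if (!is_prob(config$prob_untreated)) p <- c(p, "prob_untreated must be in [0, 1]")
  if (!is_prob(config$prob_recurrence)) p <- c(p, "prob_recurrence must be in [0, 1]")
  if (!num1(config$discount_rate) ||
      config$discount_rate < 0 || config$discount_rate >= 1) {
    p <- c(p, "discount_rate must be in [0, 1)")
  }
  if (!num1(config$n_cycles) || config$n_cycles < 1) {
    p <- c(p, "n_cycles must be a positive integer")
  } else if (config$n_cycles != config$exit_age - config$start_age) {
    p <- c(p, sprintf(
      "n_cycles (%s) must equal exit_age - start_age (%s)",
      config$n_cycles, config$exit_age - config$start_age
    ))
  }
  if (!num1(config$dmft_growth) || config$dmft_growth < 0) {
    p <- c(p, "dmft_growth must be >= 0")
  }
  if (!num1(config$sugar_slope) || config$sugar_slope < 0) {
    p <- c(p, "sugar_slope must be >= 0")
  }
  if (!num1(config$sugar_reduction) || config$sugar_reduction < 0) {
    p <- c(p, "sugar_reduction must be >= 0")
  }
  if (!num1(config$screening_cost) || config$screening_cost < 0) {
    p <- c(p, "screening_cost must be >= 0")
  }
  if (!num1(config$wtp) || config$wtp < 0) p <- c(p, "wtp must be >= 0")
  if (!config$effect_mechanism %in% c("dmft", "flow")) {
    p <- c(p, "effect_mechanism must be 'dmft' or 'flow'")
  }
  if (!config$sugar_mechanism %in% c("slope", "effect")) {
    p <- c(p, "sugar_mechanism must be 'slope' or 'effect'")
  }
  if (length(p)) validation_error(p, "model configuration")
  invisible(config)
}

#' Validate an intervention specification
#'
#' @param spec An `intervention_spec`.
#' @return `spec`, invisibly, if valid; otherwise a
#'   `cariesCEA_validation_error` listing every violation.
#' @export
validate_spec <- function(spec) {
  p <- character()
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!nzchar(spec$name)) p <- c(p, "name must be non-empty")
  if (!num1(spec$annual_cost_mean) || spec$annual_cost_mean < 0) {
    p <- c(p, sprintf("%s: annual_cost_mean must be >= 0", spec$name))
  }
  if (!num1(spec$annual_cost_sd) || spec$annual_cost_sd < 0) {
    p <- c(p, sprintf("%s: annual_cost_sd must be >= 0", spec$name))
  }
  if (!num1(spec$effect_mean) || spec$effect_mean < 0 || spec$effect_mean > 100) {
    p <- c(p, sprintf("%s: effect_mean must be a percentage in [0, 100]", spec$name))
  }
  if (!num1(spec$effect_sd) || spec$effect_sd < 0) {
    p <- c(p, sprintf("%s: effect_sd must be >= 0", spec$name))
  }
  if (!identical(spec$cost_distribution, "gamma")) {
    p <- c(p, sprintf("%s: cost_distribution must be 'gamma'", spec$name))
  }
  if (!identical(spec$effect_distribution, "beta")) {
    p <- c(p, sprintf("%s: effect_distribution must be 'beta'", spec$name))
  }
  if (length(p)) validation_error(p, "intervention specification")
  invisible(spec)
}

validate_spec_list <- function(specs) {
  lapply(specs, validate_spec)
  n_sugar <- sum(vapply(specs, function(s) s$is_sugar_policy, logical(1)))
  if (n_sugar > 1) {
    validation_error(
      "at most one intervention may set is_sugar_policy",
      "intervention list"
    )
  }
  invisible(specs)
}

#' Default analysis configuration
#'
#' The bundled parameter set for the five South African school-based caries
#' prevention strategies evaluated against do-nothing: per-learner annual
#' costs (ZAR, 2022 prices) and percentage DMFT reductions with their
#' uncertainty, plus the global model constants (10,000 learners, ages 5-14,
#' 10 annual cycles, 5\% discount rate, WTP ZAR38,500 per DMFT averted).
#'
#' @return A list with elements `config` (a [model_config()]) and `specs`
#'   (a list of [intervention_spec()]).
#' @export
default_config <- function() {
  list(
    config = model_config(),
    specs = list(
      intervention_spec("APF-Gel", 193.73, 21, 4),
      intervention_spec("Fissure sealant", 59.71, 50, 8),
      intervention_spec("ART", 89.24, 72, 25),
      intervention_spec("Tooth brushing", 548.33, 60, 47, annual_cost_sd = 544.29),
      intervention_spec("Sugar reduction", 1.25, 31.89, 0.18,
        requires_screening = FALSE, is_sugar_policy = TRUE
      )
    )
  )
}

config_field_names <- function() {
  setdiff(names(model_config()), character())
}

spec_file_fields <- c(
  "name", "annual_cost_mean", "annual_cost_sd", "effect_mean", "effect_sd",
  "requires_screening", "is_sugar_policy", "cost_distribution",
  "effect_distribution"
)

#' Read a model configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration file with a
#' flat `model` block and a list of `interventions` blocks, validates every
#' invariant, and applies the 10\%-of-mean rule to any intervention whose
#' cost standard deviation is absent. Explicitly given standard deviations
#' are never overwritten.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `config` ([model_config()]) and `specs`
#'   (list of [intervention_spec()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    stop("unsupported configuration format '.", ext, "' (use .yaml, .yml or .json)")
  )
  if (!is.list(raw) || is.null(raw$model)) {
    stop("malformed configuration: missing top-level key 'model'")
  }
  known <- names(formals(model_config))
  unknown <- setdiff(names(raw$model), known)
  if (length(unknown)) {
    stop(
      "malformed configuration: unknown key(s) in 'model': ",
      paste(unknown, collapse = ", ")
    )
  }
  config <- do.call(model_config, raw$model)

  ints <- raw$interventions
  if (is.null(ints) || length(ints) == 0) {
    warning("configuration contains no interventions")
    return(list(config = config, specs = list()))
  }
  specs <- lapply(seq_along(ints), function(i) {
    blk <- ints[[i]]
    unknown <- setdiff(names(blk), spec_file_fields)
    if (length(unknown)) {
      stop(
        "malformed configuration: unknown key(s) in interventions[", i, "]: ",
        paste(unknown, collapse = ", ")
      )
    }
    if (is.null(blk$name)) {
      stop("malformed configuration: interventions[", i, "] is missing key 'name'")
    }
    do.call(intervention_spec, blk)
  })
  validate_spec_list(specs)
  list(config = config, specs = specs)
}

#' Write a model configuration file
#'
#' Writes the configuration and intervention list to YAML or JSON (chosen by
#' file extension) so that [load_config()] on the result reproduces every
#' numeric field exactly.
#'
#' @param config A [model_config()].
#' @param specs A list of [intervention_spec()].
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, specs, path) {
  validate_config(config)
  validate_spec_list(specs)
  payload <- list(
    model = unclass(config),
    interventions = lapply(specs, function(s) {
      fields <- spec_file_fields
      # an imputed SD is a derived value: leave it out so the 10%-of-mean
      # rule re-applies on load and provenance survives the round trip
      if (isTRUE(s$sd_imputed)) fields <- setdiff(fields, "annual_cost_sd")
      unclass(s)[fields]
    })
  )
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch(
    {
      switch(ext,
        yaml = ,
        yml = yaml::write_yaml(payload, path, precision = 15),
        json = jsonlite::write_json(payload, path,
          auto_unbox = TRUE, digits = NA, pretty = TRUE
        ),
        stop("unsupported configuration format '.", ext, "'")
      )
      TRUE
    },
    error = function(e) stop("could not write configuration to ", path, ": ", conditionMessage(e))
  )
  invisible(path)
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf(
    "  cohort of %s learners, ages %g-%g (%d annual cycles), discount %.1f%%\n",
    format(x$cohort_size, big.mark = ","), x$start_age, x$exit_age - 1,
    x$n_cycles, 100 * x$discount_rate
  ))
  cat(sprintf(
    "  screening ZAR%.2f/learner/yr, WTP ZAR%s per DMFT averted\n",
    x$screening_cost, format(x$wtp, big.mark = ",")
  ))
  cat(sprintf(
    "  effect mechanism: %s; sugar mechanism: %s\n",
    x$effect_mechanism, x$sugar_mechanism
  ))
  invisible(x)
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat(sprintf(
    "<intervention_spec> %s: cost %.2f (SD %.2f%s) ZAR/learner/yr, effect %.2f%% (SD %.2f)%s%s\n",
    x$name, x$annual_cost_mean, x$annual_cost_sd,
    if (x$sd_imputed) ", imputed" else "",
    x$effect_mean, x$effect_sd,
    if (x$requires_screening) ", + screening" else "",
    if (x$is_sugar_policy) ", sugar policy" else ""
  ))
  invisible(x)
}
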