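pkg_version <- function() {
  as.character(utils::packageVersion("cariesCEA"))
}

config_hash <- function(config, specs) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, specs, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(outdir, config, specs, schedule_provenance,
                           seed = NULL, n_iterations = NULL,
                           multipliers = NULL, files = character()) {
  manifest <- list(
    tool = "cariesCEA",
    version = pkg_version(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = config_hash(config, specs),
    schedule = schedule_provenance,
    seed = seed,
    n_iterations = n_iterations,
    calibration_multipliers = as.list(multipliers),
    outputs = files
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Write the deterministic results tables
#'
#' Runs (or, in fixture mode, accepts) the per-arm totals and writes the two
#' deterministic results tables: `table2.csv` (total cost, DMFT averted,
#' average lifetime cost, ICER versus do-nothing) and `table3.csv` (ranked
#' incremental ICER and net monetary benefit), each in full precision plus a
#' `*_display.csv` variant using the published rounding, and a run manifest.
#'
#' Fixture mode decouples the CEA layer from the cohort engine: externally
#' supplied per-arm totals (e.g. a published results table) are analysed
#' directly.
#'
#' @param config A [model_config()].
#' @param specs List of [intervention_spec()].
#' @param schedule An [age_schedule()]; ignored in fixture mode.
#' @param outdir Output directory (created if needed).
#' @param fixture Optional data frame with columns `name`, `total_cost`,
#'   `dmft_averted` (a `Do nothing` row is added if absent).
#' @param schedule_provenance Free-text provenance recorded in the manifest.
#' @return Invisibly, the list of `arm_result`s analysed.
#' @export
write_deterministic_report <- function(config, specs, schedule, outdir,
                                       fixture = NULL,
                                       schedule_provenance = "supplied") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(fixture)) {
    results <- run_all_arms(config, specs, schedule)$results
  } else {
    results <- lapply(seq_len(nrow(fixture)), function(i) {
      arm_result(
        fixture$name[i], fixture$total_cost[i], fixture$dmft_averted[i],
        cohort_size = config$cohort_size
      )
    })
    if (!"Do nothing" %in% fixture$name) {
      results <- c(list(arm_result("Do nothing", 0, 0, config$cohort_size)), results)
    }
    schedule_provenance <- "fixture"
  }
  if (length(results) < 2) {
    warning("only the do-nothing arm is present; tables are degenerate")
    tab <- results_frame(results)
    tab$icer_vs_donothing <- NA_real_
    tab$ranked_icer <- NA_real_
    tab$nmb <- nmb(tab$total_cost, tab$dmft_averted, config$wtp)
    class(tab) <- c("cea_result", "data.frame")
  } else {
    tab <- cea_table(results, wtp = config$wtp)
  }
  t2_cols <- c(
    "name", "total_cost", "dmft_averted", "average_lifetime_cost",
    "icer_vs_donothing"
  )
  t3_cols <- c("name", "ranked_icer", "nmb")
  disp <- display_cea_table(tab)
  utils::write.csv(tab[, t2_cols], file.path(outdir, "table2.csv"), row.names = FALSE)
  utils::write.csv(disp[, t2_cols], file.path(outdir, "table2_display.csv"), row.names = FALSE)
  utils::write.csv(tab[, t3_cols], file.path(outdir, "table3.csv"), row.names = FALSE)
  utils::write.csv(disp[, t3_cols], file.path(outdir, "table3_display.csv"), row.names = FALSE)
  write_manifest(outdir, config, specs, schedule_provenance,
    multipliers = if (!is.null(schedule)) attr(schedule, "multipliers"),
    files = c(
      "table2.csv", "table2_display.csv", "table3.csv", "table3_display.csv"
    )
  )
  invisible(results)
}

#' Write the probabilistic sensitivity analysis outputs
#'
#' Runs the PSA and writes `samples.csv` (tidy per-iteration, per-arm cost
#' and effect draws with model outputs), `ceac.csv`, `summary.csv` (the
#' ranked Monte Carlo summary table), the CEAC and cost-effectiveness plane
#' figures, and a run manifest. Deterministic given the seed.
#'
#' @inheritParams write_deterministic_report
#' @param n_iterations Monte Carlo iterations.
#' @param seed Integer seed.
#' @param wtp_grid Thresholds for the CEAC (default [default_wtp_grid()]).
#' @return Invisibly, the `psa_samples`.
#' @export
write_psa_report <- function(config, specs, schedule, outdir,
                             n_iterations = 1000, seed = 1,
                             wtp_grid = default_wtp_grid(),
                             schedule_provenance = "supplied") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  samples <- run_psa(config, specs, schedule, n_iterations, seed)
  curve <- ceac(samples, wtp_grid)
  summ <- summarize_psa(samples, config$wtp)
  utils::write.csv(as.data.frame(samples), file.path(outdir, "samples.csv"),
    row.names = FALSE
  )
  utils::write.csv(as.data.frame(curve), file.path(outdir, "ceac.csv"),
    row.names = FALSE
  )
  utils::write.csv(summ, file.path(outdir, "summary.csv"), row.names = FALSE)
  ggplot2::ggsave(file.path(outdir, "ceac.png"), plot_ceac(curve),
    width = 8, height = 5, dpi = 150
  )
  ggplot2::ggsave(file.path(outdir, "ce_plane.png"), plot_ce_plane(samples),
    width = 8, height = 5, dpi = 150
  )
  write_manifest(outdir, config, specs, schedule_provenance,
    seed = seed, n_iterations = n_iterations,
    multipliers = attr(schedule, "multipliers"),
    files = c("samples.csv", "ceac.csv", "summary.csv", "ceac.png", "ce_plane.png")
  )
  invisible(samples)
}

#' Generate (and optionally calibrate) a schedule file
#'
#' Produces a seeded synthetic age schedule, optionally calibrates its exit
#' probabilities to a published total screening cost, and writes it as CSV
#' with a JSON metadata sidecar recording the generation arguments and any
#' calibration multipliers.
#'
#' @param path Output CSV path.
#' @param seed Integer seed.
#' @param config A [model_config()].
#' @param calibrate_screening Optional target total screening cost, ZAR.
#' @param ... Passed to [generate_age_schedule()].
#' @return The [age_schedule()], invisibly.
#' @export
write_schedule_file <- function(path, seed, config = model_config(),
                                calibrate_screening = NULL, ...) {
  sched <- generate_age_schedule(seed, config = config, ...)
  if (!is.null(calibrate_screening)) {
    sched <- calibrate_schedule(sched, config, calibrate_screening)
  }
  write_schedule(sched, path)
  meta <- list(
    tool = "cariesCEA", version = pkg_version(), seed = seed,
    calibrate_screening = calibrate_screening,
    multipliers = as.list(attr(sched, "multipliers")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(sched)
}
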