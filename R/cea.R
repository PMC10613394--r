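#' Incremental cost-effectiveness ratio
#'
#' Incremental cost divided by incremental effectiveness between two
#' strategies. The sign is preserved: a negative ICER (cheaper and more
#' effective, or costlier and less effective) is reported as is.
#'
#' @param cost_a,effect_a Total cost and effect (DMFT averted) of strategy A.
#' @param cost_b,effect_b Total cost and effect of strategy B.
#' @return ZAR per DMFT averted.
#' @export
icer <- function(cost_a, effect_a, cost_b, effect_b) {
  if (effect_a == effect_b) {
    stop(structure(
      class = c("cariesCEA_undefined_icer", "error", "condition"),
      list(
        message = sprintf(
          "ICER undefined: equal effectiveness (cost difference %.6g)",
          cost_a - cost_b
        ),
        call = NULL,
        cost_difference = cost_a - cost_b
      )
    ))
  }
  (cost_a - cost_b) / (effect_a - effect_b)
}

#' Net monetary benefit
#'
#' `wtp * effect - cost`: the monetary value of the health gain at the
#' willingness-to-pay threshold, net of the strategy's cost.
#'
#' @param cost Total cost, ZAR.
#' @param effect Health effect (DMFT averted).
#' @param wtp Willingness-to-pay threshold, ZAR per DMFT averted (>= 0).
#' @return ZAR.
#' @export
nmb <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * effect - cost
}

results_frame <- function(results) {
  data.frame(
    name = vapply(results, `[[`, character(1), "name"),
    total_cost = vapply(results, `[[`, numeric(1), "total_cost"),
    dmft_averted = vapply(results, `[[`, numeric(1), "dmft_averted"),
    average_lifetime_cost = vapply(results, `[[`, numeric(1), "average_lifetime_cost")
  )
}

#' Deterministic cost-effectiveness table
#'
#' Ranks all strategies (including the do-nothing comparator) in ascending
#' order of effectiveness (DMFT averted; ties broken by lower cost) and
#' computes, per strategy: the ICER against do-nothing, the ranked
#' incremental ICER against the previous strategy in the ordering, and the
#' net monetary benefit at the willingness-to-pay threshold. By convention
#' all strategies are kept and negative ranked ICERs reported as is; with
#' `frontier = TRUE` strictly dominated and extended-dominated strategies
#' are additionally flagged.
#'
#' @param results List of [arm_result()] including the comparator.
#' @param wtp Willingness-to-pay threshold for the NMB column; `NULL` omits
#'   the column.
#' @param frontier If `TRUE`, add `dominated` and `extended_dominated` flags.
#' @param reference Name of the comparator row (default `"Do nothing"`); if
#'   absent, the zero-cost zero-effect arm is used.
#' @return A data frame of class `cea_result`, one row per strategy, sorted
#'   ascending by `dmft_averted`. Reference cells of the ICER columns are `NA`.
#' @export
cea_table <- function(results, wtp = NULL, frontier = FALSE,
                      reference = "Do nothing") {
  if (length(results) < 2) stop("need at least two arms including the comparator")
  df <- results_frame(results)
  ref_i <- match(reference, df$name)
  if (is.na(ref_i)) {
    ref_i <- which(df$total_cost == 0 & df$dmft_averted == 0)[1]
    if (is.na(ref_i)) stop("no reference (do-nothing) arm found")
  }
  ord <- order(df$dmft_averted, df$total_cost)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  ref_row <- match(ref_i, ord)

  n <- nrow(df)
  df$icer_vs_donothing <- NA_real_
  df$ranked_icer <- NA_real_
  ref_cost <- df$total_cost[ref_row]
  ref_eff <- df$dmft_averted[ref_row]
  for (i in seq_len(n)) {
    if (i != ref_row && df$dmft_averted[i] != ref_eff) {
      df$icer_vs_donothing[i] <- icer(
        df$total_cost[i], df$dmft_averted[i], ref_cost, ref_eff
      )
    }
    if (i > 1 && df$dmft_averted[i] != df$dmft_averted[i - 1]) {
      df$ranked_icer[i] <- icer(
        df$total_cost[i], df$dmft_averted[i],
        df$total_cost[i - 1], df$dmft_averted[i - 1]
      )
    }
  }
  if (!is.null(wtp)) df$nmb <- nmb(df$total_cost, df$dmft_averted, wtp)
  if (frontier) {
    df$dominated <- vapply(seq_len(n), function(i) {
      any((df$total_cost < df$total_cost[i] & df$dmft_averted >= df$dmft_averted[i]) |
        (df$total_cost <= df$total_cost[i] & df$dmft_averted > df$dmft_averted[i]))
    }, logical(1))
    front <- frontier_arms(results)
    on_front <- df$name %in% front$name
    df$extended_dominated <- !on_front & !df$dominated
  }
  class(df) <- c("cea_result", "data.frame")
  df
}

#' Ranked incremental ICERs
#'
#' Convenience wrapper around [cea_table()] without the NMB column: the
#' effectiveness-ranked table with each strategy compared to the next most
#' effective one.
#'
#' @inheritParams cea_table
#' @return A `cea_result` data frame.
#' @export
ranked_icers <- function(results, frontier = FALSE, reference = "Do nothing") {
  cea_table(results, wtp = NULL, frontier = frontier, reference = reference)
}

#' Cost-effectiveness frontier
#'
#' The efficient frontier: starting from the least costly strategy,
#' repeatedly move to the strategy with the lowest incremental ICER among
#' the strictly more effective ones. Strategies off the frontier are either
#' strictly dominated or extended dominated; frontier ICERs are increasing.
#'
#' @param results List of [arm_result()].
#' @return A data frame of frontier strategies in increasing effectiveness,
#'   with `frontier_icer` (NA for the anchor).
#' @export
frontier_arms <- function(results) {
  df <- results_frame(results)
  # anchor: cheapest; among equally cheap, most effective
  anchor <- order(df$total_cost, -df$dmft_averted)[1]
  path <- anchor
  icers <- NA_real_
  current <- anchor
  repeat {
    better <- which(df$dmft_averted > df$dmft_averted[current])
    if (!length(better)) break
    r <- vapply(better, function(j) {
      icer(
        df$total_cost[j], df$dmft_averted[j],
        df$total_cost[current], df$dmft_averted[current]
      )
    }, numeric(1))
    k <- better[order(r, -df$dmft_averted[better])[1]]
    path <- c(path, k)
    icers <- c(icers, min(r))
    current <- k
  }
  out <- df[path, , drop = FALSE]
  out$frontier_icer <- icers
  rownames(out) <- NULL
  out
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' Two equivalent decision rules: `"nmb"` picks the strategy with the highest
#' net monetary benefit; `"frontier"` walks the cost-effectiveness frontier
#' and picks the most effective strategy whose frontier ICER does not exceed
#' the threshold.
#'
#' @param results List of [arm_result()].
#' @param wtp Willingness-to-pay threshold, ZAR per DMFT averted.
#' @param rule `"nmb"` or `"frontier"`.
#' @return The name of the optimal strategy.
#' @export
optimal_arm <- function(results, wtp, rule = c("nmb", "frontier")) {
  rule <- match.arg(rule)
  df <- results_frame(results)
  if (rule == "nmb") {
    b <- nmb(df$total_cost, df$dmft_averted, wtp)
    return(df$name[which.max(b)])
  }
  fr <- frontier_arms(results)
  ok <- which(is.na(fr$frontier_icer) | fr$frontier_icer <= wtp)
  fr$name[max(ok)]
}

#' Display rounding used by the published tables
#'
#' ICERs against do-nothing are rounded to the nearest integer, except to two
#' decimals when their magnitude is below 10; ranked ICERs are rounded to the
#' nearest integer; NMB to the nearest ZAR. Full precision is retained in
#' the unrounded table.
#'
#' @param x Numeric vector.
#' @param integer_only Round to integers regardless of magnitude (ranked
#'   ICER convention).
#' @return Rounded numeric vector.
#' @export
round_icer <- function(x, integer_only = FALSE) {
  if (integer_only) return(round(x))
  ifelse(abs(x) < 10, round(x, 2), round(x))
}

#' Display-rounded cost-effectiveness table
#'
#' @param tab A `cea_result` from [cea_table()].
#' @return The table with published-style rounding applied.
#' @export
display_cea_table <- function(tab) {
  out <- tab
  out$total_cost <- round(out$total_cost)
  out$dmft_averted <- round(out$dmft_averted)
  out$average_lifetime_cost <- round(out$average_lifetime_cost)
  out$icer_vs_donothing <- round_icer(out$icer_vs_donothing)
  out$ranked_icer <- round_icer(out$ranked_icer, integer_only = TRUE)
  if (!is.null(out$nmb)) out$nmb <- round(out$nmb)
  out
}
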