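# Published deterministic per-arm totals used as fixture-mode inputs
# (total discounted cost in ZAR and DMFT averted vs do nothing, cohort of
# 10,000 learners over 10 years).
published_totals <- function() {
  data.frame(
    name = c(
      "APF-Gel", "Sugar reduction", "Tooth brushing", "Fissure sealant", "ART"
    ),
    total_cost = c(54024439, 91380, 72779917, 44633687, 45057166),
    dmft_averted = c(42010, 63762, 74018, 100024, 144035)
  )
}

published_results <- function(cohort_size = 10000) {
  fx <- published_totals()
  c(
    list(arm_result("Do nothing", 0, 0, cohort_size)),
    lapply(seq_len(nrow(fx)), function(i) {
      arm_result(fx$name[i], fx$total_cost[i], fx$dmft_averted[i], cohort_size)
    })
  )
}
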