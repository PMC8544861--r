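#' Compare two strategies: incremental results, ICER, dominance
#'
#' Computes intervention-minus-comparator differences in life-years,
#' QALYs and cost on the discounted scale (undiscounted deltas are also
#' reported) and classifies the comparison: `"dominant"` (more QALYs at
#' lower cost), `"dominated"` (fewer QALYs at higher cost), or
#' `"ICER-reported"` otherwise, in which case the incremental
#' cost-effectiveness ratios per LY and per QALY are reported. A
#' zero-denominator ratio is reported as `NA` with the cost-difference
#' sign kept in the result rather than as +/-infinity.
#'
#' Both results must come from the same configuration; any difference in
#' a non-arm parameter is an error.
#'
#' @param intervention,comparator `strategy_result`s from [accumulate()],
#'   typically the monitored and unmonitored arm.
#' @return A `strategy_comparison` list with `delta_ly`, `delta_qaly`,
#'   `delta_cost`, `icer_per_ly`, `icer_per_qaly`, `classification`,
#'   undiscounted deltas, and the two arm labels.
#' @export
compare_strategies <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "strategy_result"),
            inherits(comparator, "strategy_result"))
  if (!identical(unclass(intervention$config), unclass(comparator$config))) {
    stop("strategies were run under different configurations", call. = FALSE)
  }
  d <- function(measure, disc) {
    result_total(intervention, measure, disc) -
      result_total(comparator, measure, disc)
  }
  delta_ly <- d("ly", TRUE); delta_qaly <- d("qaly", TRUE)
  delta_cost <- d("cost", TRUE)
  classification <- if (delta_qaly > 0 && delta_cost < 0) "dominant"
    else if (delta_qaly < 0 && delta_cost > 0) "dominated"
    else "ICER-reported"
  icer <- function(dben) {
    if (classification != "ICER-reported") return(NA_real_)
    if (dben == 0) return(NA_real_)
    delta_cost / dben
  }
  structure(list(
    delta_ly = delta_ly, delta_qaly = delta_qaly, delta_cost = delta_cost,
    delta_ly_undisc = d("ly", FALSE), delta_qaly_undisc = d("qaly", FALSE),
    delta_cost_undisc = d("cost", FALSE),
    icer_per_ly = icer(delta_ly), icer_per_qaly = icer(delta_qaly),
    icer_undefined = classification == "ICER-reported" &&
      (delta_qaly == 0 || delta_ly == 0),
    classification = classification,
    intervention_arm = intervention$arm, comparator_arm = comparator$arm,
    intervention = intervention, comparator = comparator),
    class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("<strategy_comparison> %s vs %s: %s\n", x$intervention_arm,
              x$comparator_arm, x$classification))
  print(tidy(x))
  invisible(x)
}

#' Tidy a strategy comparison
#'
#' @param x A `strategy_comparison` from [compare_strategies()].
#' @param ... Unused.
#' @return One-row tibble of incremental results and classification.
#' @method tidy strategy_comparison
#' @export
tidy.strategy_comparison <- function(x, ...) {
  tibble::tibble(
    delta_ly = x$delta_ly, delta_qaly = x$delta_qaly,
    delta_cost = x$delta_cost,
    delta_ly_undisc = x$delta_ly_undisc,
    delta_qaly_undisc = x$delta_qaly_undisc,
    delta_cost_undisc = x$delta_cost_undisc,
    icer_per_ly = x$icer_per_ly, icer_per_qaly = x$icer_per_qaly,
    classification = x$classification)
}

#' Run the full two-arm pipeline
#'
#' Runs the cohort engine for the monitored and unmonitored strategies
#' under one configuration, accumulates benefits and costs for each, and
#' compares them (monitored as the intervention).
#'
#' @inheritParams run_cohort
#' @return List with `monitored`, `unmonitored` (`strategy_result`s) and
#'   `comparison` (a `strategy_comparison`).
#' @export
run_cea <- function(config, models, life_table) {
  mon <- accumulate(run_cohort("monitored", config, models, life_table),
                    config)
  unm <- accumulate(run_cohort("unmonitored", config, models, life_table),
                    config)
  list(monitored = mon, unmonitored = unm,
       comparison = compare_strategies(mon, unm))
}
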