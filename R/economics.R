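#' Annual follow-up cost for a resource-use profile
#'
#' Dot product of per-year resource-use frequencies and unit costs over
#' the thirteen follow-up resource categories (specialist visits, imaging,
#' laboratory tests, transfusions). Hospital stay and molecular monitoring
#' are costed separately and are not part of this total.
#'
#' @param resource_use Named list/vector of uses per year (names from
#'   [followup_resources()]).
#' @param unit_costs Named list/vector of unit costs (CNY).
#' @return Annual follow-up cost in CNY.
#' @examples
#' fx <- make_base_fixture(seed = 1)
#' followup_cost_per_year(fx$config$resource_use[["CML-CP"]],
#'                        fx$config$unit_costs) # 6946.80
#' @export
followup_cost_per_year <- function(resource_use, unit_costs) {
  ru <- unlist(resource_use)
  uc <- unlist(unit_costs)
  missing <- setdiff(names(ru), names(uc))
  if (length(missing)) {
    stop("no unit cost for resource: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(ru * uc[names(ru)])
}

# annual drug (+ administration) cost for a line label, CNY/year
drug_cost_per_year <- function(line, config) {
  mult <- config$drug_cost_period_multiplier
  dc <- config$drug_costs
  if (line %in% c("none", "")) return(0)
  if (line == "BSC") {
    return((dc$imatinib + dc$interferon + config$ifn_admin_cost) * mult)
  }
  if (is.null(dc[[line]])) stop("unknown treatment line: ", line, call. = FALSE)
  dc[[line]] * mult
}

#' Annual cost of one cohort compartment
#'
#' Cost rate (CNY per year) attached to a (state, line, state-time)
#' compartment: drug acquisition (BSC = imatinib + interferon drug +
#' interferon administration; AP/BC uses the configured imatinib/dasatinib
#' treatment mix; TFR accrues no drug cost), follow-up resource use,
#' molecular monitoring (monitored arm only; TFR frequency drops after
#' the first year in TFR), and AP/BC hospitalisation days. Terminal care
#' is a one-off on death and is not part of this rate.
#'
#' @param state Health state.
#' @param line Treatment line (`"none"` for AP/BC and Death).
#' @param state_time Cycles spent in the state (drives the TFR
#'   monitoring-frequency tenure band).
#' @param config A [model_config()].
#' @param arm `"monitored"` or `"unmonitored"` (monitoring costs are zero
#'   without monitoring).
#' @return Tibble with columns `drug`, `followup`, `monitoring`,
#'   `hospital`, `total` (CNY/year), one row per input element.
#' @export
annual_state_cost <- function(state, line = "none", state_time = 0, config,
                              arm = c("monitored", "unmonitored")) {
  arm <- match.arg(arm)
  n <- max(length(state), length(line), length(state_time))
  state <- rep_len(state, n); line <- rep_len(line, n)
  state_time <- rep_len(state_time, n)
  bad <- setdiff(state, model_states())
  if (length(bad)) stop("unknown state: ", bad[1], call. = FALSE)

  fu_by_state <- vapply(model_states(), function(st) {
    if (st %in% names(config$resource_use)) {
      followup_cost_per_year(config$resource_use[[st]], config$unit_costs)
    } else 0
  }, numeric(1))

  apbc_drug <- sum(vapply(names(config$apbc_treatment_mix), function(ln) {
    config$apbc_treatment_mix[[ln]] * drug_cost_per_year(ln, config)
  }, numeric(1)))

  drug <- vapply(seq_len(n), function(i) {
    switch(state[i],
      "CML-CP" = drug_cost_per_year(line[i], config),
      "DMR" = drug_cost_per_year(line[i], config), # stays on same therapy
      "TFR" = 0,
      "AP/BC" = apbc_drug,
      "Death" = 0)
  }, numeric(1))

  mf <- config$monitoring_frequency
  freq <- ifelse(state == "CML-CP", mf[["CML-CP"]],
          ifelse(state == "DMR", mf[["DMR"]],
          ifelse(state == "TFR",
                 ifelse(state_time == 0, mf[["TFR_year1"]], mf[["TFR_later"]]),
                 0)))
  monitoring <- if (arm == "monitored") freq * config$monitoring_test_cost
                else rep(0, n)
  followup <- unname(fu_by_state[state])
  hospital <- ifelse(state == "AP/BC",
                     config$hospital_days_apbc * config$hospital_day_cost, 0)
  tibble::tibble(drug = drug, followup = followup, monitoring = monitoring,
                 hospital = hospital,
                 total = drug + followup + monitoring + hospital)
}

#' Accumulate life-years, QALYs and costs over a cohort trace
#'
#' Attaches utility weights and annual cost rates to every compartment of
#' the trace, then integrates over the horizon with a trapezoid half-cycle
#' correction: the value credited to cycle interval k -> k+1 is the mean
#' of the rates at its two bounding cycles. Discounting divides the
#' interval value by `(1 + r)^(k + 1)` (end-of-cycle convention, applied
#' after the half-cycle correction), with the benefit rate for LY/QALYs
#' and the cost rate for costs. One-off terminal-care costs attach to
#' incident deaths per interval without half-cycle correction (the
#' `terminal_care_trigger` config switch selects all deaths or AP/BC
#' deaths only).
#'
#' @param trace A [run_cohort()] trace.
#' @param config The [model_config()] the trace was run under.
#' @param arm `"monitored"` or `"unmonitored"`; defaults to the strategy
#'   recorded on the trace.
#' @return A `strategy_result`: list with `totals` (discounted and
#'   undiscounted LY, QALY, cost), `by_state` (LY/QALY plus drug and
#'   hospitalisation cost decomposed by health state), `categories`
#'   (follow-up, molecular monitoring, terminal care cost rows), `arm`,
#'   and the trace. Total cost always equals the sum of the state rows
#'   and category rows.
#' @export
accumulate <- function(trace, config, arm = NULL) {
  arm <- arm %||% attr(trace, "strategy")
  arm <- match.arg(arm, c("monitored", "unmonitored"))
  horizon <- max(trace$cycle)
  util <- if (arm == "monitored") config$utilities_monitored else
    config$utilities_unmonitored
  occupied <- setdiff(unique(trace$state[trace$occupancy > 0]), "Death")
  no_util <- setdiff(occupied, names(util))
  if (length(no_util)) {
    stop("no utility for occupied state: ", no_util[1], call. = FALSE)
  }

  comp <- annual_state_cost(trace$state, trace$line, trace$state_time,
                            config, arm)
  uvec <- vapply(trace$state, function(st) {
    if (st == "Death") 0 else util[[st]]
  }, numeric(1))

  per <- tibble::tibble(cycle = trace$cycle, state = trace$state,
                        ly = ifelse(trace$state == "Death", 0, trace$occupancy),
                        qaly = trace$occupancy * uvec,
                        cost_state = trace$occupancy *
                          (comp$drug + comp$hospital),
                        cost_followup = trace$occupancy * comp$followup,
                        cost_monitoring = trace$occupancy * comp$monitoring) |>
    dplyr::group_by(.data$cycle, .data$state) |>
    dplyr::summarise(dplyr::across(c("ly", "qaly", "cost_state",
                                     "cost_followup", "cost_monitoring"), sum),
                     .groups = "drop") |>
    tidyr::complete(cycle = 0:horizon, state = model_states(),
                    fill = list(ly = 0, qaly = 0, cost_state = 0,
                                cost_followup = 0, cost_monitoring = 0))

  rb <- config$discount_rate_benefits
  rc <- config$discount_rate_costs
  # trapezoid HCC over interval k -> k+1, discounted end-of-cycle
  hcc <- function(x, r) {
    if (horizon == 0) return(c(undiscounted = 0, discounted = 0))
    mid <- (x[-length(x)] + x[-1]) / 2
    df <- (1 + r)^-(seq_len(horizon))
    c(undiscounted = sum(mid), discounted = sum(mid * df))
  }

  by_state <- per |>
    dplyr::group_by(.data$state) |>
    dplyr::arrange(.data$cycle, .by_group = TRUE) |>
    dplyr::summarise(
      ly_undisc = hcc(.data$ly, rb)[["undiscounted"]],
      ly_disc = hcc(.data$ly, rb)[["discounted"]],
      qaly_undisc = hcc(.data$qaly, rb)[["undiscounted"]],
      qaly_disc = hcc(.data$qaly, rb)[["discounted"]],
      cost_undisc = hcc(.data$cost_state, rc)[["undiscounted"]],
      cost_disc = hcc(.data$cost_state, rc)[["discounted"]],
      .groups = "drop") |>
    dplyr::filter(.data$state != "Death")

  cat_stream <- per |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(followup = sum(.data$cost_followup),
                     monitoring = sum(.data$cost_monitoring),
                     .groups = "drop") |>
    dplyr::arrange(.data$cycle)

  # incident deaths per interval; terminal care one-off, no HCC
  inflow <- attr(trace, "death_inflow")
  if (is.null(inflow)) {
    death_occ <- state_occupancy(trace) |>
      dplyr::filter(.data$state == "Death") |>
      dplyr::arrange(.data$cycle)
    docc <- rep(0, horizon + 1)
    docc[death_occ$cycle + 1] <- death_occ$occupancy
    d_tot <- if (horizon > 0) diff(docc) else numeric(0)
    d_apbc <- d_tot # source attribution needs the trace's inflow metadata
  } else {
    d_tot <- inflow$total
    d_apbc <- inflow$from_apbc
  }
  deaths <- if (config$terminal_care_trigger == "apbc_only") d_apbc else d_tot
  dfc <- (1 + rc)^-(seq_len(max(horizon, 1)))[seq_len(horizon)]
  terminal <- c(undiscounted = sum(deaths) * config$terminal_care_cost,
                discounted = sum(deaths * dfc) * config$terminal_care_cost)

  categories <- tibble::tibble(
    category = c("followup", "monitoring", "terminal"),
    cost_undisc = c(hcc(cat_stream$followup, rc)[["undiscounted"]],
                    hcc(cat_stream$monitoring, rc)[["undiscounted"]],
                    terminal[["undiscounted"]]),
    cost_disc = c(hcc(cat_stream$followup, rc)[["discounted"]],
                  hcc(cat_stream$monitoring, rc)[["discounted"]],
                  terminal[["discounted"]]))

  totals <- tibble::tibble(
    measure = c("ly", "qaly", "cost"),
    undiscounted = c(sum(by_state$ly_undisc), sum(by_state$qaly_undisc),
                     sum(by_state$cost_undisc) + sum(categories$cost_undisc)),
    discounted = c(sum(by_state$ly_disc), sum(by_state$qaly_disc),
                   sum(by_state$cost_disc) + sum(categories$cost_disc)))

  structure(list(totals = totals, by_state = by_state,
                 categories = categories, arm = arm, config = config,
                 trace = trace),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat("<strategy_result>", x$arm, "arm\n")
  print(x$totals)
  invisible(x)
}

#' Tidy a strategy result
#'
#' @param x A `strategy_result` from [accumulate()].
#' @param ... Unused.
#' @return `tidy()`: the per-state and per-category decomposition as one
#'   long tibble; `glance()`: one row of discounted/undiscounted totals.
#' @method tidy strategy_result
#' @export
tidy.strategy_result <- function(x, ...) {
  st <- tidyr::pivot_longer(x$by_state, -"state", names_to = "measure",
                            values_to = "value")
  ct <- tidyr::pivot_longer(x$categories, -"category", names_to = "measure",
                            values_to = "value")
  dplyr::bind_rows(
    dplyr::mutate(st, component = .data$state, .keep = "unused"),
    dplyr::mutate(ct, component = .data$category, .keep = "unused"))[,
      c("component", "measure", "value")]
}

#' @rdname tidy.strategy_result
#' @method glance strategy_result
#' @export
glance.strategy_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$totals, names_from = "measure",
                             values_from = c("undiscounted", "discounted"))
  dplyr::mutate(wide, arm = x$arm, .before = 1)
}

result_total <- function(res, measure, discounted = TRUE) {
  col <- if (discounted) "discounted" else "undiscounted"
  res$totals[[col]][res$totals$measure == measure]
}
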