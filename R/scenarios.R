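#' Scenario specifications
#'
#' A scenario is a named set of configuration overrides: `set` entries
#' replace a config value at a `.`-separated path; `mul` entries multiply
#' the existing value(s) at a path (probabilities are clamped to \[0, 1\]
#' after multiplication). Overrides are validated against the full config
#' invariants before any simulation runs.
#'
#' @param name Scenario label.
#' @param set Named list: path -> replacement value.
#' @param mul Named list: path -> multiplicative factor.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, set = list(), mul = list()) {
  structure(list(name = name, set = set, mul = mul), class = "scenario_spec")
}

get_path <- function(config, path) {
  Reduce(function(x, nm) {
    if (is.null(x[[nm]])) {
      stop("config path does not resolve: ", path, call. = FALSE)
    }
    x[[nm]]
  }, strsplit(path, ".", fixed = TRUE)[[1]], init = config)
}

set_path <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  get_path(config, path) # existence check
  rec <- function(x, keys) {
    if (length(keys) == 1) { x[[keys]] <- value; return(x) }
    x[[keys[1]]] <- rec(x[[keys[1]]], keys[-1])
    x
  }
  rec(config, keys)
}

#' Apply a scenario to a configuration
#'
#' @param config Base [model_config()].
#' @param spec A [scenario_spec()].
#' @return A new validated `model_config`; the base config is untouched.
#' @export
apply_scenario <- function(config, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  cfg <- config
  for (path in names(spec$set)) cfg <- set_path(cfg, path, spec$set[[path]])
  for (path in names(spec$mul)) {
    cur <- get_path(cfg, path)
    f <- spec$mul[[path]]
    newval <- if (is.list(cur)) lapply(cur, function(v) scale_clamped(v, f))
              else scale_clamped(cur, f)
    cfg <- set_path(cfg, path, newval)
  }
  validate_config(cfg)
}

# multiplicative adjustment; probability-like values stay in [0, 1]
scale_clamped <- function(v, f) {
  out <- v * f
  if (all(v >= 0 & v <= 1)) out <- pmin(pmax(out, 0), 1)
  out
}

#' The packaged scenario library
#'
#' The twenty alternative-input scenarios run alongside the base case:
#' demographics (all male), discounting at 0% and 5%, a shifted
#' first-line treatment mix, alternative imatinib-to-nilotinib routing
#' (30/40/50%; the 50% row equals the base case and is kept as an
#' explicit identity), nilotinib-to-dasatinib routing at 90%,
#' multiplicative reductions in DMR achievement (x0.9/x0.8/x0.7, applied
#' to the per-cycle achievement probabilities), DMR maintenance x0.9 to
#' x1.1, a 10% utility reduction in both arms, an intensified
#' TFR monitoring schedule per ELN guidance (monthly for the first six
#' months of TFR, 8-weekly for months 6-12, 12-weekly thereafter:
#' 9.25 tests in TFR year 1, 52/12 per year after), and drug-price
#' discounts of 10/20/30%.
#'
#' @return Named list of [scenario_spec()]s.
#' @export
scenario_library <- function() {
  sp <- scenario_spec
  specs <- list(
    sp("all males", set = list(male_fraction = 1)),
    sp("no discounting", set = list(discount_rate_costs = 0,
                                    discount_rate_benefits = 0)),
    sp("5% discount", set = list(discount_rate_costs = 0.05,
                                 discount_rate_benefits = 0.05)),
    sp("first-line imatinib 30% / nilotinib 40% / dasatinib 30%",
       set = list(first_line_distribution = list(
         imatinib = 0.3, nilotinib = 0.4, dasatinib = 0.3))),
    sp("imatinib to nilotinib 40%",
       set = list(`line_sequencing.imatinib` = list(nilotinib = 0.4,
                                                    dasatinib = 0.6))),
    sp("imatinib to nilotinib 50% (base-case identity)",
       set = list(`line_sequencing.imatinib` = list(nilotinib = 0.5,
                                                    dasatinib = 0.5))),
    sp("imatinib to nilotinib 30%",
       set = list(`line_sequencing.imatinib` = list(nilotinib = 0.3,
                                                    dasatinib = 0.7))),
    sp("nilotinib to dasatinib 90%",
       set = list(`line_sequencing.nilotinib` = list(dasatinib = 0.9,
                                                     BSC = 0.1))),
    sp("10% reduction in achieving DMR",
       set = list(dmr_achievement_multiplier = 0.9)),
    sp("20% reduction in achieving DMR",
       set = list(dmr_achievement_multiplier = 0.8)),
    sp("30% reduction in achieving DMR",
       set = list(dmr_achievement_multiplier = 0.7)),
    sp("10% less DMR maintenance", mul = list(dmr_maintain_prob = 0.9)),
    sp("20% less DMR maintenance", mul = list(dmr_maintain_prob = 0.8)),
    sp("30% less DMR maintenance", mul = list(dmr_maintain_prob = 0.7)),
    sp("10% higher DMR maintenance", mul = list(dmr_maintain_prob = 1.1)),
    sp("10% less utility", mul = list(utilities_monitored = 0.9,
                                      utilities_unmonitored = 0.9)),
    sp("ELN monitoring frequency",
       set = list(`monitoring_frequency.TFR_year1` = 9.25,
                  `monitoring_frequency.TFR_later` = 52 / 12)),
    sp("10% discount on drug costs", mul = list(drug_costs = 0.9)),
    sp("20% discount on drug costs", mul = list(drug_costs = 0.8)),
    sp("30% discount on drug costs", mul = list(drug_costs = 0.7))
  )
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

#' Run one scenario through the two-arm pipeline
#'
#' @param base Base [model_config()].
#' @param spec A [scenario_spec()].
#' @inheritParams run_cohort
#' @return The scenario's `strategy_comparison` with the scenario name
#'   attached; the base config is never mutated.
#' @export
run_scenario <- function(base, spec, models, life_table) {
  cfg <- apply_scenario(base, spec) # errors here happen before any run
  res <- run_cea(cfg, models, life_table)
  cmp <- res$comparison
  cmp$scenario <- spec$name
  cmp
}

#' Run the whole scenario library
#'
#' @param base Base [model_config()].
#' @param specs List of [scenario_spec()]s (default: the packaged
#'   [scenario_library()], preceded by the base case).
#' @inheritParams run_cohort
#' @return Tibble with one row per scenario: per-arm discounted cost, LY
#'   and QALY, incremental results and classification.
#' @export
run_scenarios <- function(base, models, life_table,
                          specs = scenario_library()) {
  all_specs <- c(list(`base case` = scenario_spec("base case")), specs)
  rows <- lapply(all_specs, function(sp) {
    cfg <- apply_scenario(base, sp)
    res <- run_cea(cfg, models, life_table)
    tibble::tibble(
      scenario = sp$name,
      cost_monitored = result_total(res$monitored, "cost"),
      ly_monitored = result_total(res$monitored, "ly"),
      qaly_monitored = result_total(res$monitored, "qaly"),
      cost_unmonitored = result_total(res$unmonitored, "cost"),
      ly_unmonitored = result_total(res$unmonitored, "ly"),
      qaly_unmonitored = result_total(res$unmonitored, "qaly"),
      delta_cost = res$comparison$delta_cost,
      delta_ly = res$comparison$delta_ly,
      delta_qaly = res$comparison$delta_qaly,
      classification = res$comparison$classification)
  })
  dplyr::bind_rows(rows)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each listed scalar parameter individually by `+/-rel` (default
#' 25%) of its base-case value, re-runs the full two-arm pipeline at each
#' bound, and records the chosen incremental outcome. Probability and
#' utility parameters are clamped to \[0, 1\] after perturbation (with a
#' message). Entries are sorted by descending bar width, the tornado
#' order.
#'
#' @param base Base [model_config()].
#' @param parameters Character vector of `.`-separated config paths to
#'   scalar numeric parameters (default [default_owsa_parameters()]).
#' @inheritParams run_cohort
#' @param outcome Outcome axis: discounted `"delta_qaly"`, `"delta_cost"`
#'   or `"delta_ly"`.
#' @param rel Relative perturbation (0.25 = +/-25%).
#' @return Tibble of class `owsa_result`: `parameter`, `low_result`,
#'   `high_result`, `bar_width`, plus the base-case outcome as an
#'   attribute.
#' @export
run_owsa <- function(base, models, life_table,
                     parameters = default_owsa_parameters(),
                     outcome = c("delta_qaly", "delta_cost", "delta_ly"),
                     rel = 0.25) {
  outcome <- match.arg(outcome)
  base_cmp <- run_cea(base, models, life_table)$comparison
  base_out <- base_cmp[[outcome]]
  prob_like <- c("utilities_monitored", "utilities_unmonitored",
                 "dmr_maintain_prob", "male_fraction",
                 "discount_rate_costs", "discount_rate_benefits")
  one <- function(path, f) {
    v <- get_path(base, path)
    if (!is.numeric(v) || length(v) != 1) {
      stop("OWSA parameter is not scalar numeric: ", path, call. = FALSE)
    }
    nv <- v * f
    root <- strsplit(path, ".", fixed = TRUE)[[1]][1]
    if (root %in% prob_like && (nv < 0 || nv > 1)) {
      clamped <- min(max(nv, 0), 1)
      message(sprintf("OWSA: %s clamped from %.4f to %.4f", path, nv, clamped))
      nv <- clamped
    }
    cfg <- validate_config(set_path(base, path, nv))
    run_cea(cfg, models, life_table)$comparison[[outcome]]
  }
  rows <- lapply(parameters, function(p) {
    lo <- one(p, 1 - rel); hi <- one(p, 1 + rel)
    tibble::tibble(parameter = p, low_result = lo, high_result = hi,
                   bar_width = abs(hi - lo))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$bar_width))
  structure(out, base_result = base_out, outcome = outcome,
            class = c("owsa_result", class(out)))
}

#' Default one-way sensitivity parameter set
#'
#' The parameters examined in the tornado analysis: health-state
#' utilities for CML-CP and AP/BC in both arms and for DMR/TFR in the
#' monitored arm, the DMR maintenance probabilities for nilotinib and
#' dasatinib, mean starting age, and the benefit discount rate.
#'
#' @return Character vector of config paths.
#' @export
default_owsa_parameters <- function() {
  c("utilities_monitored.CML-CP", "utilities_unmonitored.CML-CP",
    "utilities_monitored.AP/BC", "utilities_unmonitored.AP/BC",
    "utilities_monitored.TFR", "utilities_monitored.DMR",
    "dmr_maintain_prob.nilotinib", "dmr_maintain_prob.dasatinib",
    "start_age_years", "discount_rate_benefits")
}
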