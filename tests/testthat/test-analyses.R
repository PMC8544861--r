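scenario_runs <- function() {
  if (is.null(.cache$scenario_runs)) {
    fx <- base_fixture()
    models <- base_models()
    specs <- c(list(`base case` = scenario_spec("base case")),
               scenario_library())
    .cache$scenario_runs <- lapply(specs, function(sp) {
      cfg <- apply_scenario(fx$config, sp)
      res <- run_cea(cfg, models, fx$life_table)
      list(name = sp$name, config = cfg, result = res)
    })
  }
  .cache$scenario_runs
}

test_that("the scenario library covers the study's scenario set", {
  specs <- scenario_library()
  expect_length(specs, 20)
  expect_setequal(
    names(specs),
    c("all males", "no discounting", "5% discount",
      "first-line imatinib 30% / nilotinib 40% / dasatinib 30%",
      "imatinib to nilotinib 40%", "imatinib to nilotinib 50% (base-case identity)",
      "imatinib to nilotinib 30%", "nilotinib to dasatinib 90%",
      "10% reduction in achieving DMR", "20% reduction in achieving DMR",
      "30% reduction in achieving DMR", "10% less DMR maintenance",
      "20% less DMR maintenance", "30% less DMR maintenance",
      "10% higher DMR maintenance", "10% less utility",
      "ELN monitoring frequency", "10% discount on drug costs",
      "20% discount on drug costs", "30% discount on drug costs"))
})

test_that("scenario overrides are validated before any simulation", {
  fx <- base_fixture()
  bad <- scenario_spec("broken mix",
                       set = list(first_line_distribution = list(
                         imatinib = 0.5, nilotinib = 0.5, dasatinib = 0.5)))
  expect_error(run_scenario(fx$config, bad, base_models(), fx$life_table),
               class = "cmlcea_normalization_error")
  expect_error(apply_scenario(fx$config,
                              scenario_spec("nope", set = list(
                                no_such_field.at_all = 1))),
               regexp = "does not resolve")
})

test_that("the base configuration is never mutated by scenario runs", {
  fx <- base_fixture()
  before <- serialize_cfg(fx$config)
  invisible(scenario_runs())
  expect_identical(serialize_cfg(fx$config), before)
  expect_identical(serialize_cfg(base_fixture()$config), before)
})

test_that("the no-discounting scenario equals the base undiscounted columns", {
  runs <- scenario_runs()
  base <- runs[["base case"]]$result$comparison
  nod <- runs[["no discounting"]]$result$comparison
  expect_equal(nod$delta_ly, base$delta_ly_undisc, tolerance = 1e-12)
  expect_equal(nod$delta_qaly, base$delta_qaly_undisc, tolerance = 1e-12)
  expect_equal(nod$delta_cost, base$delta_cost_undisc, tolerance = 1e-12)
})

test_that("a utility-only scenario rescales QALYs but not LYs", {
  runs <- scenario_runs()
  base <- runs[["base case"]]$result$comparison
  less <- runs[["10% less utility"]]$result$comparison
  expect_equal(less$delta_ly, base$delta_ly, tolerance = 1e-12)
  expect_equal(less$delta_cost, base$delta_cost, tolerance = 1e-12)
  # all utilities scale by 0.9, so incremental QALYs scale by exactly 0.9
  expect_equal(less$delta_qaly, 0.9 * base$delta_qaly, tolerance = 1e-9)
})

test_that("the imatinib-routing 50% scenario is the base-case identity", {
  runs <- scenario_runs()
  base <- runs[["base case"]]$result$comparison
  ident <- runs[["imatinib to nilotinib 50% (base-case identity)"]]$result$comparison
  expect_equal(tidy(ident), tidy(base), tolerance = 1e-12)
})

test_that("run_scenarios tabulates every scenario with the base case first", {
  fx <- base_fixture()
  # small spec subset keeps this interface test light
  tab <- run_scenarios(fx$config, base_models(), fx$life_table,
                       specs = scenario_library()[c("no discounting",
                                                    "all males")])
  expect_equal(tab$scenario[1], "base case")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$classification == "dominant"))
  expect_true(all(tab$cost_monitored < tab$cost_unmonitored))
})

test_that("OWSA: inert parameters yield zero-width bars", {
  fx <- base_fixture()
  cfg <- toy_config(
    horizon = 10,
    first_line_distribution = list(imatinib = 1),
    line_sequencing = list(imatinib = list(dasatinib = 1),
                           nilotinib = list(dasatinib = 1),
                           dasatinib = list(BSC = 1)))
  models <- toy_models(ttd = 0.12, pfs = 0.04, dmr = 0.10, relapse = 0.25,
                       apbc_os = 0.5)
  # nilotinib is never prescribed under this routing, so its price is inert
  ow <- run_owsa(cfg, models, fx$life_table,
                 parameters = c("drug_costs.nilotinib",
                                "monitoring_test_cost"),
                 outcome = "delta_cost")
  expect_equal(ow$bar_width[ow$parameter == "drug_costs.nilotinib"], 0,
               tolerance = 1e-9)
  expect_gt(ow$bar_width[ow$parameter == "monitoring_test_cost"], 0)
})

test_that("OWSA: linear cost parameters move the outcome symmetrically", {
  fx <- base_fixture()
  cfg <- toy_config(horizon = 10)
  models <- toy_models(ttd = 0.12, pfs = 0.04, dmr = 0.10, relapse = 0.25,
                       apbc_os = 0.5)
  base <- run_cea(cfg, models, fx$life_table)$comparison$delta_cost
  ow <- run_owsa(cfg, models, fx$life_table,
                 parameters = "monitoring_test_cost", outcome = "delta_cost")
  expect_equal(ow$high_result - base, -(ow$low_result - base),
               tolerance = 1e-9)
  expect_equal(attr(ow, "base_result"), base, tolerance = 1e-12)
})

test_that("OWSA: the benefit discount rate moves QALYs but not undiscounted LYs", {
  fx <- base_fixture()
  cfg <- toy_config(horizon = 10)
  models <- toy_models(ttd = 0.12, pfs = 0.04, dmr = 0.10, relapse = 0.25,
                       apbc_os = 0.5)
  ow <- run_owsa(cfg, models, fx$life_table,
                 parameters = "discount_rate_benefits",
                 outcome = "delta_qaly")
  expect_gt(ow$bar_width, 0)
  for (f in c(0.75, 1.25)) {
    pert <- apply_scenario(cfg, scenario_spec("r", set = list(
      discount_rate_benefits = cfg$discount_rate_benefits * f)))
    cmp <- run_cea(pert, models, fx$life_table)$comparison
    base <- run_cea(cfg, models, fx$life_table)$comparison
    expect_equal(cmp$delta_ly_undisc, base$delta_ly_undisc,
                 tolerance = 1e-12)
  }
})

test_that("utility parameters clamp at 1 with a message", {
  fx <- base_fixture()
  cfg <- toy_config(horizon = 5)
  models <- toy_models(dmr = 0.2, relapse = 0.1)
  expect_message(
    ow <- run_owsa(cfg, models, fx$life_table,
                   parameters = "utilities_monitored.TFR",
                   outcome = "delta_qaly"),
    regexp = "clamped")
  # +25% of a utility of 1 clamps back to the base value: bar is one-sided
  expect_equal(ow$high_result, attr(ow, "base_result"), tolerance = 1e-12)
})

test_that("the tornado is widest for the CML-CP utility on the fixture", {
  fx <- base_fixture()
  ow <- .cache$owsa <- run_owsa(fx$config, base_models(), fx$life_table)
  expect_equal(nrow(ow), length(default_owsa_parameters()))
  # tornado order: bars sorted by descending width
  expect_true(all(diff(ow$bar_width) <= 1e-12))
  expect_match(ow$parameter[1], "CML-CP")
  expect_match(ow$parameter[1], "^utilities_")
})

test_that("plot methods return ggplot objects", {
  p1 <- ggplot2::autoplot(base_cea()$monitored$trace)
  expect_s3_class(p1, "ggplot")
  if (!is.null(.cache$owsa)) {
    expect_s3_class(ggplot2::autoplot(.cache$owsa), "ggplot")
  }
  cv <- base_fixture()$curves[["TTD:imatinib"]]
  expect_s3_class(plot_curve_fit(cv, base_models()[["TTD:imatinib"]]),
                  "ggplot")
})
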