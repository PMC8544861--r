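#' Generate a synthetic digitized Kaplan-Meier curve
#'
#' Stands in for coordinates digitized from a published figure: evaluates
#' a known parametric survival curve at evenly spaced times over
#' `(0, censor_time]`, adds Gaussian digitization noise, clips to
#' \[0, 1\], and anchors the origin at (0, 1). The generating truth is
#' kept as an attribute so downstream fitting can be scored against it.
#' Output is deterministic given `seed`; the global RNG state is left
#' untouched.
#'
#' @param family,params,knots Generating model, as in
#'   [parametric_survival()].
#' @param n_points Number of points including the (0, 1) anchor (>= 3).
#' @param noise_sd Digitization noise SD on the survival scale (>= 0).
#' @param censor_time Last digitized time, years (> 0).
#' @param seed Integer seed.
#' @param role,treatment Curve labels (see [digitized_curve()]).
#' @return A [digitized_curve()] with attributes `truth` (the generating
#'   [parametric_survival()]) and `noise_sd`.
#' @export
generate_km_curve <- function(family, params, n_points = 50,
                              noise_sd = 0.005, censor_time, seed = 1,
                              role = "PFS", treatment = "all", knots = NULL) {
  if (censor_time <= 0) stop("censor_time must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (n_points < 3) stop("need at least 3 points", call. = FALSE)
  truth <- parametric_survival(family, params, knots)
  times <- seq(0, censor_time, length.out = n_points)
  s <- survival_at(truth, times)
  noise <- withr::with_seed(seed, stats::rnorm(n_points - 1, 0, noise_sd))
  s[-1] <- pmin(pmax(s[-1] + noise, 0), 1)
  cv <- digitized_curve(times, s, role = role, treatment = treatment)
  attr(cv, "truth") <- truth
  attr(cv, "noise_sd") <- noise_sd
  cv
}

#' Generate a synthetic all-cause life table
#'
#' Gompertz-Makeham annual death probabilities per sex:
#' `qx = 1 - exp(-(A + B * exp(C * age)))`, a standard stand-in for an
#' adult all-cause life table. Defaults are chosen to resemble a
#' contemporary national life table (male mortality above female at all
#' adult ages; q rising from roughly 2 per 1,000 at age 41 to a few per
#' 100 at age 80).
#'
#' @param makeham_male,makeham_female Coefficients `c(A, B, C)` per sex.
#' @param ages Integer age range.
#' @return A `life_table` tibble (age, sex, qx).
#' @export
generate_life_table <- function(makeham_male = c(5e-4, 3e-5, 0.09),
                                makeham_female = c(3e-4, 1.5e-5, 0.095),
                                ages = 0:100) {
  qx <- function(coef) 1 - exp(-(coef[1] + coef[2] * exp(coef[3] * ages)))
  qm <- qx(makeham_male); qf <- qx(makeham_female)
  if (any(!is.finite(c(qm, qf))) || any(c(qm, qf) < 0 | c(qm, qf) > 1)) {
    stop("Makeham coefficients produce qx outside [0, 1]", call. = FALSE)
  }
  as_life_table(data.frame(
    age = rep(ages, 2), sex = rep(c("male", "female"), each = length(ages)),
    qx = c(qm, qf)))
}

# generating truths for the synthetic digitized-curve set; each entry:
# key, family, params, censor_time, n-offset used to derive its sub-seed
fixture_curve_specs <- function() {
  list(
    list(key = "TTD:imatinib", family = "Weibull",
         params = c(shape = 0.9, scale = 9), censor = 10),
    list(key = "TTD:nilotinib", family = "Weibull",
         params = c(shape = 0.9, scale = 11), censor = 10),
    list(key = "TTD:dasatinib", family = "Weibull",
         params = c(shape = 0.9, scale = 10), censor = 10),
    list(key = "PFS:imatinib", family = "exponential",
         params = c(rate = 0.030), censor = 10),
    list(key = "PFS:nilotinib", family = "exponential",
         params = c(rate = 0.022), censor = 10),
    list(key = "PFS:dasatinib", family = "exponential",
         params = c(rate = 0.025), censor = 10),
    list(key = "PFS:BSC", family = "exponential",
         params = c(rate = 0.10), censor = 8),
    list(key = "MR4.5:imatinib", family = "Weibull",
         params = c(shape = 1.1, scale = 16), censor = 10),
    list(key = "MR4.5:nilotinib", family = "Weibull",
         params = c(shape = 1.2, scale = 7), censor = 10),
    list(key = "MR4.5:dasatinib", family = "Weibull",
         params = c(shape = 1.2, scale = 9), censor = 10),
    list(key = "TFR:all", family = "log-logistic",
         params = c(shape = 0.7, scale = 4), censor = 8),
    list(key = "OS:AP/BC", family = "Weibull",
         params = c(shape = 1.2, scale = 1.8), censor = 5)
  )
}

#' Build the packaged base-case fixture
#'
#' Assembles the complete model input set: a configuration embedding
#' every printed base-case clinical and cost input (first-line mix
#' 75/13/12%, DMR maintenance 57/77/72%, utilities
#' 0.854/0.940/1.000/0.595, monitoring frequencies 2.87/2.5/9/2 per year,
#' all resource-use frequencies and unit costs, 36 hospital days at
#' ¥300/day, ¥250 per molecular test, drug list prices
#' ¥586/¥11,364/¥7,500/¥912.88 per period with 12 periods/year, 3%
#' discounting, 50-year horizon, start age 41, 62% male), a synthetic
#' digitized-curve set for every role the model needs (TTD, PFS including
#' the hydroxyurea+interferon stand-in used for BSC, time to MR4.5, TFR
#' relapse-free survival, AP/BC overall survival), and a synthetic
#' Gompertz-Makeham life table. The curve shapes are an approximate
#' calibration chosen so the monitored arm dominates, mirroring the
#' qualitative base-case finding; their generating truths ride along in
#' `truth` for recovery testing. Parameters carry provenance tags
#' (source table, `"assumption"`, or `"synthetic"`).
#'
#' @param seed Integer seed driving the digitization noise.
#' @param n_points Points per synthetic curve.
#' @param noise_sd Digitization noise SD (survival scale).
#' @return List with `config` ([model_config()]), `curves` (named list of
#'   [digitized_curve()]s), `life_table`, and `truth` (named list of
#'   generating [parametric_survival()] models).
#' @export
make_base_fixture <- function(seed = 20211025, n_points = 50,
                              noise_sd = 0.005) {
  specs <- fixture_curve_specs()
  curves <- list()
  truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    role <- sub(":.*$", "", sp$key)
    trt <- sub("^.*:", "", sp$key)
    cv <- generate_km_curve(sp$family, sp$params, n_points = n_points,
                            noise_sd = noise_sd, censor_time = sp$censor,
                            seed = (seed + i * 101) %% 2147483647,
                            role = if (role == "OS") "OS" else role,
                            treatment = trt)
    curves[[sp$key]] <- cv
    truth[[sp$key]] <- attr(cv, "truth")
  }

  resources <- followup_resources()
  profile <- function(v) stats::setNames(as.list(v), resources)
  cp_prof <- profile(c(1.52, 6.88, 0, 0, 7.88, 2.96, 1.20, 2.24, 4.36,
                       7.52, 0.04, 0, 0.20))
  dmr_prof <- profile(c(1.16, 3.72, 0, 0, 4.52, 2.32, 0.12, 0.88, 2.00,
                        4.52, 0.04, 0, 0))
  apbc_prof <- profile(c(2.04, 14.52, 3.96, 0.96, 17.52, 3.60, 3.60, 0.52,
                         8.76, 12.60, 7.92, 1.20, 0.48))

  fields <- list(
    time_horizon_years = 50L,
    cycle_length_years = 1,
    discount_rate_costs = 0.03,
    discount_rate_benefits = 0.03,
    male_fraction = 0.62,
    start_age_years = 41,
    first_line_distribution = list(imatinib = 0.75, nilotinib = 0.13,
                                   dasatinib = 0.12),
    dmr_maintain_prob = list(imatinib = 0.57, nilotinib = 0.77,
                             dasatinib = 0.72),
    apbc_treatment_mix = list(imatinib = 0.5, dasatinib = 0.5),
    line_sequencing = list(
      imatinib = list(nilotinib = 0.5, dasatinib = 0.5),
      nilotinib = list(dasatinib = 1),
      dasatinib = list(BSC = 1)),
    utilities_monitored = list(`CML-CP` = 0.854, DMR = 0.940, TFR = 1.000,
                               `AP/BC` = 0.595),
    utilities_unmonitored = list(`CML-CP` = 0.854, `AP/BC` = 0.595),
    monitoring_frequency = list(`CML-CP` = 2.87, DMR = 2.5, TFR_year1 = 9,
                                TFR_later = 2),
    resource_use = list(`CML-CP` = cp_prof, DMR = dmr_prof, TFR = dmr_prof,
                        `AP/BC` = apbc_prof),
    unit_costs = profile(c(30, 40, 70, 170, 20, 490, 100, 800, 100, 350,
                           450, 1420, 100)),
    drug_costs = list(imatinib = 586, nilotinib = 11364, dasatinib = 7500,
                      interferon = 912.88),
    ifn_admin_cost = 1095.75,
    drug_cost_period_multiplier = 12,
    hospital_days_apbc = 36,
    hospital_day_cost = 300,
    monitoring_test_cost = 250,
    terminal_care_cost = 8000,
    terminal_care_trigger = "all_deaths",
    dmr_achievement_multiplier = 1,
    curve_refs = list()
  )
  provenance <- list(
    male_fraction = "base-case clinical inputs table",
    start_age_years = "base-case clinical inputs table",
    discount_rate_costs = "base-case clinical inputs table",
    discount_rate_benefits = "base-case clinical inputs table",
    first_line_distribution = "base-case clinical inputs table",
    dmr_maintain_prob = "base-case clinical inputs table",
    apbc_treatment_mix = "base-case clinical inputs table",
    line_sequencing = "base-case clinical inputs table",
    utilities_monitored = "base-case clinical inputs table",
    utilities_unmonitored = "base-case clinical inputs table",
    monitoring_frequency = "base-case clinical inputs table",
    resource_use = "base-case clinical inputs table",
    unit_costs = "base-case cost inputs table",
    drug_costs = "base-case cost inputs table",
    ifn_admin_cost = "base-case cost inputs table",
    drug_cost_period_multiplier = "assumption",
    hospital_days_apbc = "base-case clinical inputs table",
    hospital_day_cost = "base-case cost inputs table",
    monitoring_test_cost = "base-case cost inputs table",
    terminal_care_cost = "assumption",
    terminal_care_trigger = "assumption",
    curves = "synthetic",
    life_table = "synthetic"
  )
  list(config = model_config(fields, provenance = provenance),
       curves = curves,
       life_table = generate_life_table(),
       truth = truth)
}

#' Write a fixture bundle to disk
#'
#' Serializes the config (YAML, with `curve_refs` pointing at the curve
#' files), every digitized curve (headered CSV) and the life table (CSV)
#' into a directory, so the whole pipeline can be driven from files.
#'
#' @param fixture A [make_base_fixture()] list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- list()
  for (key in names(fixture$curves)) {
    fn <- paste0("curve_", gsub("[:/.]", "_", key), ".csv")
    write_curve(fixture$curves[[key]], file.path(dir, fn))
    refs[[key]] <- fn
  }
  utils::write.csv(as.data.frame(fixture$life_table),
                   file.path(dir, "life_table.csv"), row.names = FALSE)
  cfg <- fixture$config
  cfg$curve_refs <- refs
  write_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a fixture bundle back
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with `config`, `curves`, `life_table` (no `truth`: the
#'   on-disk bundle is the digitized data only).
#' @export
read_fixture_bundle <- function(dir) {
  config <- load_config(file.path(dir, "config.yaml"))
  curves <- lapply(stats::setNames(nm = names(config$curve_refs)),
                   function(key) {
    role <- sub(":.*$", "", key)
    read_curve(file.path(dir, config$curve_refs[[key]]), role = role,
               treatment = sub("^.*:", "", key))
  })
  list(config = config, curves = curves,
       life_table = read_life_table(file.path(dir, "life_table.csv")))
}
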