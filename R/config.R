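#' Model states, treatment lines, and follow-up resources
#'
#' The fixed health-state set of the cohort model, the treatment-line
#' labels, and the thirteen follow-up resource categories costed per year.
#'
#' @return Character vectors of labels.
#' @export
model_states <- function() c("CML-CP", "DMR", "TFR", "AP/BC", "Death")

#' @rdname model_states
#' @export
treatment_lines <- function() c("imatinib", "nilotinib", "dasatinib", "BSC")

#' @rdname model_states
#' @export
followup_resources <- function() {
  c("nurse_led_visit", "haematologist_led_visit", "xray", "ct_scan",
    "full_blood_count", "cytogenetic_analysis", "bone_marrow_aspiration",
    "fish_test", "blood_film_exam", "blood_chemistry", "blood_transfusion",
    "platelet_transfusion", "cytochemistry_analysis")
}

#' Assemble a model configuration
#'
#' Collects every scalar and tabular input of the cost-effectiveness model
#' into one validated named list of class `model_config`: horizon and
#' discounting, cohort demographics, first-line treatment mix,
#' deep-molecular-response maintenance probabilities, treatment-line
#' sequencing, health-state utilities per arm, molecular-monitoring
#' frequencies, follow-up resource-use profiles and unit costs, drug list
#' prices (interpreted as per cost period, with
#' `drug_cost_period_multiplier` periods per year, default monthly),
#' progression hospitalisation, and terminal care.
#'
#' @param ... Fields overriding the entries of `fields` (a full field list
#'   must result; see [make_base_fixture()] for a complete example).
#' @param fields Complete named list of configuration fields.
#' @param provenance Named list tagging parameters with their provenance
#'   (a source-table citation, `"assumption"`, or `"synthetic"`).
#' @return A validated `model_config` object.
#' @export
model_config <- function(fields, provenance = list()) {
  cfg <- structure(fields, class = "model_config",
                   provenance = provenance)
  validate_config(cfg)
}

config_fields <- function() {
  c("time_horizon_years", "cycle_length_years", "discount_rate_costs",
    "discount_rate_benefits", "male_fraction", "start_age_years",
    "first_line_distribution", "dmr_maintain_prob", "apbc_treatment_mix",
    "line_sequencing", "utilities_monitored", "utilities_unmonitored",
    "monitoring_frequency", "resource_use", "unit_costs", "drug_costs",
    "ifn_admin_cost", "drug_cost_period_multiplier", "hospital_days_apbc",
    "hospital_day_cost", "monitoring_test_cost", "terminal_care_cost",
    "terminal_care_trigger", "dmr_achievement_multiplier", "curve_refs")
}

cfg_error <- function(field, msg, class = "cmlcea_validation_error") {
  rlang::abort(sprintf("config field '%s': %s", field, msg), class = class)
}

check_sums_to_one <- function(x, field) {
  if (abs(sum(unlist(x)) - 1) > 1e-9) {
    cfg_error(field, sprintf("fractions sum to %.10f, not 1 (no silent renormalization)",
                             sum(unlist(x))),
              class = "cmlcea_normalization_error")
  }
}

check_fraction <- function(x, field) {
  v <- unlist(x)
  if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
    cfg_error(field, "values must lie in [0, 1]")
  }
}

check_nonneg <- function(x, field) {
  v <- unlist(x)
  if (any(!is.finite(v)) || any(v < 0)) cfg_error(field, "values must be >= 0")
}

#' Validate a model configuration
#'
#' Checks the structural invariants: all required fields present; the
#' first-line mix, AP/BC treatment mix, and every line-sequencing row sum
#' to 1 (to 1e-9 — mis-specified distributions are errors, never silently
#' renormalized); fractions and utilities in \[0, 1\]; costs, frequencies
#' and ages non-negative; and every state named in utilities or resource
#' use belongs to the fixed state set.
#'
#' @param config A `model_config` (or plain list with the same fields).
#' @return The config, invisibly usable in a pipe (returned visibly).
#' @export
validate_config <- function(config) {
  missing <- setdiff(config_fields(), names(config))
  if (length(missing)) {
    cfg_error(missing[1], "required field is missing")
  }
  with(config, {
    check_nonneg(time_horizon_years, "time_horizon_years")
    if (time_horizon_years != floor(time_horizon_years)) {
      cfg_error("time_horizon_years", "must be an integer count of cycles")
    }
    check_nonneg(cycle_length_years, "cycle_length_years")
    check_fraction(discount_rate_costs, "discount_rate_costs")
    check_fraction(discount_rate_benefits, "discount_rate_benefits")
    check_fraction(male_fraction, "male_fraction")
    check_nonneg(start_age_years, "start_age_years")
    check_fraction(first_line_distribution, "first_line_distribution")
    check_sums_to_one(first_line_distribution, "first_line_distribution")
    check_fraction(dmr_maintain_prob, "dmr_maintain_prob")
    check_fraction(apbc_treatment_mix, "apbc_treatment_mix")
    check_sums_to_one(apbc_treatment_mix, "apbc_treatment_mix")
    for (ln in names(line_sequencing)) {
      row <- line_sequencing[[ln]]
      check_fraction(row, paste0("line_sequencing.", ln))
      check_sums_to_one(row, paste0("line_sequencing.", ln))
      if (!all(names(row) %in% treatment_lines())) {
        cfg_error(paste0("line_sequencing.", ln), "unknown destination line")
      }
    }
    for (fld in c("utilities_monitored", "utilities_unmonitored")) {
      u <- config[[fld]]
      check_fraction(u, fld)
      if (!all(names(u) %in% model_states())) {
        cfg_error(fld, paste("unknown state:",
                             setdiff(names(u), model_states())[1]))
      }
    }
    check_nonneg(monitoring_frequency, "monitoring_frequency")
    if (!all(c("CML-CP", "DMR", "TFR_year1", "TFR_later") %in%
             names(monitoring_frequency))) {
      cfg_error("monitoring_frequency",
                "needs CML-CP, DMR, TFR_year1, TFR_later entries")
    }
    if (!all(names(resource_use) %in% model_states())) {
      cfg_error("resource_use", "unknown state")
    }
    for (st in names(resource_use)) {
      check_nonneg(resource_use[[st]], paste0("resource_use.", st))
    }
    check_nonneg(unit_costs, "unit_costs")
    check_nonneg(drug_costs, "drug_costs")
    check_nonneg(ifn_admin_cost, "ifn_admin_cost")
    check_nonneg(drug_cost_period_multiplier, "drug_cost_period_multiplier")
    check_nonneg(hospital_days_apbc, "hospital_days_apbc")
    check_nonneg(hospital_day_cost, "hospital_day_cost")
    check_nonneg(monitoring_test_cost, "monitoring_test_cost")
    check_nonneg(terminal_care_cost, "terminal_care_cost")
    if (!terminal_care_trigger %in% c("all_deaths", "apbc_only")) {
      cfg_error("terminal_care_trigger", "must be 'all_deaths' or 'apbc_only'")
    }
    check_nonneg(dmr_achievement_multiplier, "dmr_achievement_multiplier")
  })
  config
}

#' Load / save a model configuration
#'
#' The on-disk format is YAML (or JSON, chosen by file extension) matching
#' the field list of [model_config()], with a `schema_version` header and
#' an optional `provenance` block tagging each parameter's source.
#' Loading validates strictly; a distribution that does not sum to 1 is a
#' normalization error, never silently rescaled.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return `load_config()` returns a validated `model_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  prov <- raw$provenance %||% list()
  raw$provenance <- NULL
  raw$schema_version <- NULL
  missing <- setdiff(config_fields(), names(raw))
  if (length(missing)) {
    cfg_error(missing[1], "missing from config file")
  }
  if (is.null(raw$curve_refs)) raw$curve_refs <- list()
  model_config(raw[config_fields()], provenance = prov)
}

#' @rdname load_config
#' @param config A `model_config`.
#' @export
write_config <- function(config, path) {
  payload <- c(list(schema_version = 1L), unclass(config))
  prov <- attr(config, "provenance")
  if (length(prov)) payload$provenance <- prov
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' Parameter provenance tags
#'
#' @param config A `model_config`.
#' @return Tibble with columns `parameter`, `provenance`.
#' @export
config_provenance <- function(config) {
  prov <- attr(config, "provenance") %||% list()
  tibble::tibble(parameter = names(prov),
                 provenance = unlist(prov, use.names = FALSE))
}

#' Read an age-by-sex life table
#'
#' Headered CSV with columns `age`, `sex` (`male`/`female`), `qx`
#' (annual death probability). Ages must be contiguous within each sex;
#' lookups beyond the table clamp to the last row.
#'
#' @param path CSV file.
#' @return A tibble of class `life_table`.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  as_life_table(df)
}

as_life_table <- function(df) {
  stopifnot(all(c("age", "sex", "qx") %in% names(df)))
  if (any(df$qx < 0 | df$qx > 1)) {
    stop("life table qx must lie in [0, 1]", call. = FALSE)
  }
  if (!all(df$sex %in% c("male", "female"))) {
    stop("life table sex must be 'male' or 'female'", call. = FALSE)
  }
  for (sx in unique(df$sex)) {
    ages <- sort(df$age[df$sex == sx])
    if (length(ages) > 1 && any(diff(ages) != 1)) {
      stop("life table ages must be contiguous for sex ", sx, call. = FALSE)
    }
  }
  out <- tibble::as_tibble(df[c("age", "sex", "qx")])
  structure(out, class = c("life_table", class(out)))
}

#' Sex-blended background mortality
#'
#' Annual all-cause death probability at a given age, blended across sexes:
#' `male_fraction * q_male(age) + (1 - male_fraction) * q_female(age)`.
#' Ages beyond the table clamp to its last row; non-integer ages use the
#' floor age row.
#'
#' @param life_table A [read_life_table()] tibble.
#' @param age Attained age(s) in years (>= 0).
#' @param male_fraction Fraction of the cohort that is male.
#' @return Blended annual death probability in \[0, 1\].
#' @export
blended_mortality <- function(life_table, age, male_fraction) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  stopifnot(male_fraction >= 0, male_fraction <= 1)
  lookup <- function(sex) {
    sub <- life_table[life_table$sex == sex, ]
    sub <- sub[order(sub$age), ]
    idx <- pmin(pmax(floor(age) - min(sub$age) + 1, 1), nrow(sub))
    sub$qx[idx]
  }
  male_fraction * lookup("male") + (1 - male_fraction) * lookup("female")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
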