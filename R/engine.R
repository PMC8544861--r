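#' Run the semi-Markov cohort simulation for one strategy
#'
#' Propagates a cohort of newly diagnosed chronic-phase CML patients
#' through the health states CML-CP (on a treatment line), DMR (a
#' one-cycle deep-molecular-response tunnel), TFR (treatment-free
#' remission), AP/BC (progressed, absorbing until death) and Death, over
#' `time_horizon_years` annual cycles.
#'
#' Clocks are semi-Markov: TTD, PFS and MR4.5 curves are indexed by time
#' since the current line started; the TFR relapse-free curve by time
#' since TFR entry; AP/BC overall survival by time since progression;
#' background mortality by attained cohort age. Within a cycle, competing
#' events are applied as a conditional cascade in the fixed order
#' death, progression, DMR achievement, treatment discontinuation: each
#' event's per-cycle probability applies to the survivors of the previous
#' events, which guarantees occupancy conservation. If the raw
#' (un-cascaded) per-cycle probabilities from any compartment sum beyond 1
#' the engine stops with an error naming the compartment and cycle — that
#' signals a pathological curve and is never silently rescaled.
#'
#' Under the unmonitored strategy DMR achievement is switched off
#' (response status is unobservable without molecular monitoring), so DMR
#' and TFR are unreachable; the same TTD/PFS curves drive line switching
#' and progression in both arms. Patients discontinuing the last TKI move
#' to best supportive care (BSC), which cannot achieve DMR. TFR relapse
#' and DMR loss both restart the same treatment line with a fresh line
#' clock. AP/BC mortality is the fitted AP/BC overall-survival hazard
#' floored at the age-specific background death probability.
#'
#' @param strategy `"monitored"` or `"unmonitored"`.
#' @param config A validated [model_config()].
#' @param models Named list of fitted [parametric_survival()] models with
#'   keys `"TTD:<line>"`, `"PFS:<line>"` (including `"PFS:BSC"`),
#'   `"MR4.5:<line>"`, `"TFR:all"`, `"OS:AP/BC"` (see [fit_models()]).
#' @param life_table A [read_life_table()] tibble.
#' @return A `cohort_trace` tibble with columns `cycle`, `state`, `line`,
#'   `state_time`, `occupancy`, `age`; one block of rows per cycle
#'   0..horizon, each summing to 1.
#' @export
run_cohort <- function(strategy = c("monitored", "unmonitored"), config,
                       models, life_table) {
  strategy <- match.arg(strategy)
  horizon <- as.integer(config$time_horizon_years)
  probs <- precompute_probs(config, models, life_table)
  fl <- config$first_line_distribution
  fl <- fl[unlist(fl) > 0]
  occ <- tibble::tibble(state = "CML-CP", line = names(fl), state_time = 0L,
                        occupancy = unname(unlist(fl)))
  rows <- vector("list", horizon + 1L)
  rows[[1]] <- dplyr::mutate(occ, cycle = 0L)
  inflow <- tibble::tibble(cycle = seq_len(horizon), total = 0, from_apbc = 0)
  if (horizon > 0) {
    for (k in seq_len(horizon) - 1L) {
      occ <- step_core(occ, probs, config, k,
                       monitored = strategy == "monitored")
      di <- attr(occ, "death_inflow")
      inflow$total[k + 1L] <- di[["total"]]
      inflow$from_apbc[k + 1L] <- di[["from_apbc"]]
      rows[[k + 2L]] <- dplyr::mutate(occ, cycle = k + 1L)
    }
  }
  trace <- dplyr::bind_rows(rows)
  trace$age <- config$start_age_years + trace$cycle * config$cycle_length_years
  trace <- trace[, c("cycle", "state", "line", "state_time", "occupancy", "age")]
  structure(trace, strategy = strategy, death_inflow = inflow,
            class = c("cohort_trace", class(tibble::tibble())))
}

# per-cycle transition probabilities for every curve, plus background qx
precompute_probs <- function(config, models, life_table) {
  horizon <- max(as.integer(config$time_horizon_years), 1L)
  delta <- config$cycle_length_years
  lines <- treatment_lines()
  need <- c(paste0("PFS:", lines), "TFR:all", "OS:AP/BC",
            paste0("TTD:", setdiff(lines, "BSC")),
            paste0("MR4.5:", setdiff(lines, "BSC")))
  missing <- setdiff(need, names(models))
  if (length(missing)) {
    stop("missing fitted curves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mat <- function(role, lns) {
    m <- matrix(0, nrow = length(lines), ncol = horizon,
                dimnames = list(lines, NULL))
    for (ln in lns) {
      m[ln, ] <- cycle_probabilities(models[[paste0(role, ":", ln)]],
                                     horizon, delta)
    }
    m
  }
  tkis <- setdiff(lines, "BSC")
  p_dmr <- mat("MR4.5", tkis)
  p_dmr <- pmin(pmax(p_dmr * config$dmr_achievement_multiplier, 0), 1)
  ages <- config$start_age_years + (seq_len(horizon) - 1L) * delta
  list(
    p_ttd = mat("TTD", intersect(names(config$line_sequencing), tkis)),
    p_pfs = mat("PFS", lines),
    p_dmr = p_dmr,
    p_relapse = cycle_probabilities(models[["TFR:all"]], horizon, delta),
    p_apbc = cycle_probabilities(models[["OS:AP/BC"]], horizon, delta),
    q_bg = blended_mortality(life_table, ages, config$male_fraction),
    horizon = horizon
  )
}

step_core <- function(occ, probs, config, cycle, monitored) {
  q <- probs$q_bg[[cycle + 1L]]
  o_state <- character(0); o_line <- character(0)
  o_time <- integer(0); o_occ <- numeric(0)
  death_in <- c(total = 0, from_apbc = 0)
  add <- function(state, line, state_time, occupancy) {
    keep <- occupancy > 0
    if (!any(keep)) return(invisible(NULL))
    o_state <<- c(o_state, rep_len(state, length(occupancy))[keep])
    o_line <<- c(o_line, line[keep])
    o_time <<- c(o_time, as.integer(state_time[keep]))
    o_occ <<- c(o_occ, occupancy[keep])
  }

  cp <- occ[occ$state == "CML-CP", ]
  if (nrow(cp)) {
    idx <- cp$state_time + 1L
    pick <- function(m) m[cbind(match(cp$line, rownames(m)), idx)]
    p_pfs <- pick(probs$p_pfs)
    p_dmr <- if (monitored) pick(probs$p_dmr) else rep(0, nrow(cp))
    p_ttd <- pick(probs$p_ttd)
    raw <- q + p_pfs + p_dmr + p_ttd
    if (any(raw > 1 + 1e-9)) {
      i <- which.max(raw)
      stop(sprintf(
        "competing per-cycle probabilities sum to %.4f (> 1) for CML-CP/%s at state_time %d, cycle %d",
        raw[i], cp$line[i], cp$state_time[i], cycle), call. = FALSE)
    }
    d <- cp$occupancy * q
    prog <- cp$occupancy * (1 - q) * p_pfs
    dmr <- cp$occupancy * (1 - q) * (1 - p_pfs) * p_dmr
    disc <- cp$occupancy * (1 - q) * (1 - p_pfs) * (1 - p_dmr) * p_ttd
    stay <- cp$occupancy - d - prog - dmr - disc
    death_in[["total"]] <- death_in[["total"]] + sum(d)
    add("Death", rep("none", nrow(cp)), rep(0L, nrow(cp)), d)
    add("AP/BC", rep("none", nrow(cp)), rep(0L, nrow(cp)), prog)
    add("DMR", cp$line, rep(0L, nrow(cp)), dmr)
    for (ln in names(config$line_sequencing)) {
      sel <- cp$line == ln
      if (!any(sel)) next
      for (nxt in names(config$line_sequencing[[ln]])) {
        frac <- config$line_sequencing[[ln]][[nxt]]
        add("CML-CP", rep(nxt, sum(sel)), rep(0L, sum(sel)), disc[sel] * frac)
      }
    }
    add("CML-CP", cp$line, cp$state_time + 1L, stay)
  }

  dm <- occ[occ$state == "DMR", ]
  if (nrow(dm)) {
    m <- unlist(config$dmr_maintain_prob)[dm$line]
    d <- dm$occupancy * q
    keep_ <- dm$occupancy * (1 - q) * m
    lose <- dm$occupancy * (1 - q) * (1 - m)
    death_in[["total"]] <- death_in[["total"]] + sum(d)
    add("Death", rep("none", nrow(dm)), rep(0L, nrow(dm)), d)
    add("TFR", dm$line, rep(0L, nrow(dm)), keep_)
    add("CML-CP", dm$line, rep(0L, nrow(dm)), lose)
  }

  tf <- occ[occ$state == "TFR", ]
  if (nrow(tf)) {
    p_rel <- probs$p_relapse[tf$state_time + 1L]
    d <- tf$occupancy * q
    rel <- tf$occupancy * (1 - q) * p_rel
    stay <- tf$occupancy - d - rel
    death_in[["total"]] <- death_in[["total"]] + sum(d)
    add("Death", rep("none", nrow(tf)), rep(0L, nrow(tf)), d)
    add("CML-CP", tf$line, rep(0L, nrow(tf)), rel)
    add("TFR", tf$line, tf$state_time + 1L, stay)
  }

  ab <- occ[occ$state == "AP/BC", ]
  if (nrow(ab)) {
    p_die <- pmax(probs$p_apbc[ab$state_time + 1L], q)
    d <- ab$occupancy * p_die
    death_in[["total"]] <- death_in[["total"]] + sum(d)
    death_in[["from_apbc"]] <- death_in[["from_apbc"]] + sum(d)
    add("Death", rep("none", nrow(ab)), rep(0L, nrow(ab)), d)
    add("AP/BC", ab$line, ab$state_time + 1L, ab$occupancy - d)
  }

  de <- occ[occ$state == "Death", ]
  if (nrow(de)) add("Death", de$line, de$state_time, de$occupancy)

  key <- paste(o_state, o_line, o_time, sep = "\r")
  agg <- rowsum(o_occ, key, reorder = FALSE)
  first <- !duplicated(key)
  nxt <- tibble::tibble(state = o_state[first], line = o_line[first],
                        state_time = o_time[first],
                        occupancy = as.numeric(agg[, 1L]))
  attr(nxt, "death_inflow") <- death_in
  nxt
}

#' Advance one cycle of the cohort (single-step interface)
#'
#' One transition of the cohort engine, exposed for inspection and
#' testing; [run_cohort()] is the main entry point. `occupancy` is a
#' tibble with columns `state`, `line`, `state_time`, `occupancy` summing
#' to 1; the cycle index (for the age-dependent background mortality and
#' the semi-Markov curve clocks) is taken from `cycle`.
#'
#' @inheritParams run_cohort
#' @param occupancy Current-cycle occupancy tibble.
#' @param cycle 0-based index of the cycle being stepped over.
#' @return The next cycle's occupancy tibble (same columns, sums to 1).
#' @export
step_monitored <- function(occupancy, config, models, life_table, cycle = 0) {
  probs <- precompute_probs(config, models, life_table)
  step_core(occupancy, probs, config, cycle, monitored = TRUE)
}

#' @rdname step_monitored
#' @export
step_unmonitored <- function(occupancy, config, models, life_table,
                             cycle = 0) {
  probs <- precompute_probs(config, models, life_table)
  step_core(occupancy, probs, config, cycle, monitored = FALSE)
}

#' Per-cycle state occupancy of a trace
#'
#' @param trace A [run_cohort()] trace.
#' @return Tibble `cycle` x `state` occupancy (long form).
#' @export
state_occupancy <- function(trace) {
  dplyr::summarise(dplyr::group_by(trace, .data$cycle, .data$state),
                   occupancy = sum(.data$occupancy), .groups = "drop")
}
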