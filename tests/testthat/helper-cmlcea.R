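# Shared fixtures and independent oracles for the test suite.
# The base fixture and its fitted curve set are expensive (~3 s), so they
# are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

base_fixture <- function() {
  if (is.null(.cache$fixture)) .cache$fixture <- make_base_fixture()
  .cache$fixture
}

base_models <- function() {
  if (is.null(.cache$models)) .cache$models <- fit_models(base_fixture()$curves)
  .cache$models
}

base_cea <- function() {
  if (is.null(.cache$cea)) {
    fx <- base_fixture()
    .cache$cea <- run_cea(fx$config, base_models(), fx$life_table)
  }
  .cache$cea
}

# flat life table: constant annual death probability q at every age
flat_life_table <- function(q = 0) {
  a <- if (q > 0) -log(1 - q) else 0
  generate_life_table(makeham_male = c(a, 0, 0.01),
                      makeham_female = c(a, 0, 0.01))
}

# exponential curve set for every role the engine needs; rates default to 0
# (flat S = 1, i.e. the event never happens)
toy_models <- function(ttd = 0, pfs = 0, dmr = 0, relapse = 0, apbc_os = 0) {
  expo <- function(r) parametric_survival("exponential", r)
  keys <- list(
    "TTD:imatinib" = ttd, "TTD:nilotinib" = ttd, "TTD:dasatinib" = ttd,
    "PFS:imatinib" = pfs, "PFS:nilotinib" = pfs, "PFS:dasatinib" = pfs,
    "PFS:BSC" = pfs, "MR4.5:imatinib" = dmr, "MR4.5:nilotinib" = dmr,
    "MR4.5:dasatinib" = dmr, "TFR:all" = relapse, "OS:AP/BC" = apbc_os)
  lapply(keys, expo)
}

# a small config derived from the base fixture (short horizon by default)
toy_config <- function(horizon = 5, ...) {
  cfg <- base_fixture()$config
  cfg$time_horizon_years <- horizon
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_config(cfg)
}

occupancy_at <- function(trace, cyc) {
  out <- trace[trace$cycle == cyc, c("state", "line", "state_time", "occupancy")]
  out[order(out$state, out$line, out$state_time), ]
}

# ---------------------------------------------------------------------------
# Oracle 1: exhaustive transition-tree enumeration. Walks every path a
# patient can take, multiplying branch probabilities computed directly from
# survival-function ratios. Independent of the engine's matrix propagation.
# ---------------------------------------------------------------------------
enumerate_oracle <- function(config, models, life_table, strategy, horizon) {
  monitored <- strategy == "monitored"
  S <- function(key, t) survival_at(models[[key]], t)
  condp <- function(key, u) {
    s0 <- S(key, u); if (s0 <= 0) return(1)
    1 - S(key, u + 1) / s0
  }
  occ <- list()
  record <- function(cycle, state, line, stime, mass) {
    key <- paste(cycle, state, line, stime)
    occ[[key]] <<- (occ[[key]] %||% 0) + mass
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x

  walk <- function(state, line, stime, mass, cycle) {
    record(cycle, state, line, stime, mass)
    if (cycle == horizon || mass == 0) return(invisible(NULL))
    q <- blended_mortality(life_table, config$start_age_years + cycle,
                           config$male_fraction)
    if (state == "CML-CP") {
      p_pfs <- condp(paste0("PFS:", line), stime)
      p_dmr <- if (monitored && line != "BSC") {
        min(condp(paste0("MR4.5:", line), stime) *
              config$dmr_achievement_multiplier, 1)
      } else 0
      p_ttd <- if (line %in% names(config$line_sequencing)) {
        condp(paste0("TTD:", line), stime)
      } else 0
      walk("Death", "none", 0, mass * q, cycle + 1)
      walk("AP/BC", "none", 0, mass * (1 - q) * p_pfs, cycle + 1)
      walk("DMR", line, 0, mass * (1 - q) * (1 - p_pfs) * p_dmr, cycle + 1)
      disc <- mass * (1 - q) * (1 - p_pfs) * (1 - p_dmr) * p_ttd
      for (nxt in names(config$line_sequencing[[line]])) {
        walk("CML-CP", nxt, 0,
             disc * config$line_sequencing[[line]][[nxt]], cycle + 1)
      }
      stay <- mass * (1 - q) * (1 - p_pfs) * (1 - p_dmr) * (1 - p_ttd)
      walk("CML-CP", line, stime + 1, stay, cycle + 1)
    } else if (state == "DMR") {
      m <- config$dmr_maintain_prob[[line]]
      walk("Death", "none", 0, mass * q, cycle + 1)
      walk("TFR", line, 0, mass * (1 - q) * m, cycle + 1)
      walk("CML-CP", line, 0, mass * (1 - q) * (1 - m), cycle + 1)
    } else if (state == "TFR") {
      p_rel <- condp("TFR:all", stime)
      walk("Death", "none", 0, mass * q, cycle + 1)
      walk("CML-CP", line, 0, mass * (1 - q) * p_rel, cycle + 1)
      walk("TFR", line, stime + 1, mass * (1 - q) * (1 - p_rel), cycle + 1)
    } else if (state == "AP/BC") {
      p_die <- max(condp("OS:AP/BC", stime), q)
      walk("Death", "none", 0, mass * p_die, cycle + 1)
      walk("AP/BC", line, stime + 1, mass * (1 - p_die), cycle + 1)
    } else { # Death
      walk("Death", line, stime, mass, cycle + 1)
    }
  }
  for (ln in names(config$first_line_distribution)) {
    m0 <- config$first_line_distribution[[ln]]
    if (m0 > 0) walk("CML-CP", ln, 0, m0, 0)
  }
  parts <- strsplit(names(occ), " ", fixed = TRUE)
  tibble::tibble(
    cycle = as.integer(vapply(parts, `[`, "", 1)),
    state = vapply(parts, `[`, "", 2),
    line = vapply(parts, `[`, "", 3),
    state_time = as.integer(vapply(parts, `[`, "", 4)),
    occupancy = unlist(occ, use.names = FALSE))
}

# ---------------------------------------------------------------------------
# Oracle 2: seeded microsimulation. N individual random walks through the
# same transition rules, sampled with sequential uniform draws (one per
# competing event), aggregated to state occupancy per cycle.
# ---------------------------------------------------------------------------
microsim_oracle <- function(config, models, life_table, strategy, n_walkers,
                            n_cycles, seed) {
  monitored <- strategy == "monitored"
  lines <- c("imatinib", "nilotinib", "dasatinib", "BSC")
  condp_vec <- function(key, n) {
    s <- survival_at(models[[key]], 0:n)
    p <- ifelse(s[-length(s)] <= 0, 1, 1 - s[-1] / s[-length(s)])
    pmin(pmax(p, 0), 1)
  }
  p_pfs <- sapply(lines, function(ln) condp_vec(paste0("PFS:", ln), n_cycles))
  p_ttd <- sapply(lines, function(ln) {
    if (ln %in% names(config$line_sequencing)) {
      condp_vec(paste0("TTD:", ln), n_cycles)
    } else rep(0, n_cycles)
  })
  p_dmr <- sapply(lines, function(ln) {
    if (ln != "BSC") {
      pmin(condp_vec(paste0("MR4.5:", ln), n_cycles) *
             config$dmr_achievement_multiplier, 1)
    } else rep(0, n_cycles)
  })
  p_rel <- condp_vec("TFR:all", n_cycles)
  p_os <- condp_vec("OS:AP/BC", n_cycles)
  seq_next <- lapply(config$line_sequencing, function(row) {
    list(to = match(names(row), lines), p = cumsum(unlist(row)))
  })
  maintain <- unlist(config$dmr_maintain_prob)[lines[1:3]]

  withr::with_seed(seed, {
    fl <- unlist(config$first_line_distribution)[lines[1:3]]
    fl[is.na(fl)] <- 0
    line <- sample.int(3, n_walkers, replace = TRUE, prob = fl)
    state <- rep(1L, n_walkers) # 1 CML-CP, 2 DMR, 3 TFR, 4 AP/BC, 5 Death
    stime <- rep(0L, n_walkers)
    states_trace <- matrix(0L, nrow = n_cycles + 1, ncol = 5)
    tally <- function(k) {
      for (s in 1:5) states_trace[k + 1, s] <<- sum(state == s)
    }
    tally(0)
    for (k in seq_len(n_cycles) - 1L) {
      q <- blended_mortality(life_table, config$start_age_years + k,
                             config$male_fraction)
      new_state <- state; new_line <- line; new_stime <- stime
      u_death <- stats::runif(n_walkers)
      u1 <- stats::runif(n_walkers); u2 <- stats::runif(n_walkers)
      u3 <- stats::runif(n_walkers); u4 <- stats::runif(n_walkers)

      cp <- which(state == 1L)
      if (length(cp)) {
        i <- cbind(stime[cp] + 1L, line[cp])
        died <- u_death[cp] < q
        prog <- !died & u1[cp] < p_pfs[i]
        dmr <- !died & !prog &
          (if (monitored) u2[cp] < p_dmr[i] else FALSE)
        disc <- !died & !prog & !dmr & u3[cp] < p_ttd[i]
        stay <- !died & !prog & !dmr & !disc
        new_state[cp[died]] <- 5L
        new_state[cp[prog]] <- 4L; new_stime[cp[prog]] <- 0L
        new_state[cp[dmr]] <- 2L; new_stime[cp[dmr]] <- 0L
        for (w in cp[disc]) {
          nx <- seq_next[[lines[line[w]]]]
          new_line[w] <- nx$to[which(u4[w] <= nx$p)[1]]
          new_stime[w] <- 0L
        }
        new_stime[cp[stay]] <- stime[cp[stay]] + 1L
      }
      dm <- which(state == 2L)
      if (length(dm)) {
        died <- u_death[dm] < q
        keep <- !died & u1[dm] < maintain[line[dm]]
        new_state[dm[died]] <- 5L
        new_state[dm[keep]] <- 3L; new_stime[dm[keep]] <- 0L
        lost <- !died & !keep
        new_state[dm[lost]] <- 1L; new_stime[dm[lost]] <- 0L
      }
      tf <- which(state == 3L)
      if (length(tf)) {
        died <- u_death[tf] < q
        rel <- !died & u1[tf] < p_rel[stime[tf] + 1L]
        new_state[tf[died]] <- 5L
        new_state[tf[rel]] <- 1L; new_stime[tf[rel]] <- 0L
        stay <- !died & !rel
        new_stime[tf[stay]] <- stime[tf[stay]] + 1L
      }
      ab <- which(state == 4L)
      if (length(ab)) {
        died <- u_death[ab] < pmax(p_os[stime[ab] + 1L], q)
        new_state[ab[died]] <- 5L
        stay <- !died
        new_stime[ab[stay]] <- stime[ab[stay]] + 1L
      }
      state <- new_state; line <- new_line; stime <- new_stime
      tally(k + 1L)
    }
    colnames(states_trace) <- c("CML-CP", "DMR", "TFR", "AP/BC", "Death")
    states_trace / n_walkers
  })
}

# --- small helpers shared by test files (defined here so ordering is moot) ---

config_fields_for_test <- function() {
  setdiff(names(unclass(base_fixture()$config)), "curve_refs")
}

as_life_table_for_test <- function(q_male, q_female, ages = 40:60) {
  cmlcea:::as_life_table(data.frame(
    age = rep(ages, 2), sex = rep(c("male", "female"), each = length(ages)),
    qx = rep(c(q_male, q_female), each = length(ages))))
}

serialize_cfg <- function(cfg) {
  paste(utils::capture.output(utils::str(unclass(cfg), digits.d = 15)),
        collapse = "\n")
}

select_best_keeping <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  winner <- select_best(fits)
  for (f in conv) if (identical(f$model, winner)) return(f)
  winner
}
attr_family <- function(x) x$family
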