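#' Digitized Kaplan-Meier curve
#'
#' Wraps (time, survival) coordinate pairs read off a published
#' Kaplan-Meier figure into a tibble with a curve role and treatment label.
#' Times must be strictly increasing; survival probabilities must lie in
#' \[0, 1\]. Small digitization jitter may break monotonicity; a
#' pool-adjacent-violators (isotonic, non-increasing) repair is applied at
#' fit time, not here.
#'
#' @param time_years,survival_probability Coordinate vectors.
#' @param role Curve role: `"TTD"` (time to treatment discontinuation),
#'   `"PFS"`, `"MR4.5"` (time to deep molecular response), `"TFR"`
#'   (relapse-free survival in treatment-free remission), or `"OS"`
#'   (overall survival in AP/BC).
#' @param treatment Treatment-line label the curve belongs to.
#' @return A tibble of class `digitized_curve` with columns
#'   `time_years`, `survival_probability`.
#' @export
digitized_curve <- function(time_years, survival_probability,
                            role = c("TTD", "PFS", "MR4.5", "TFR", "OS"),
                            treatment = "all") {
  role <- match.arg(role)
  stopifnot(length(time_years) == length(survival_probability))
  if (is.unsorted(time_years, strictly = TRUE)) {
    stop("time_years must be strictly increasing", call. = FALSE)
  }
  if (any(time_years < 0)) stop("time_years must be non-negative", call. = FALSE)
  if (any(survival_probability < 0 | survival_probability > 1)) {
    stop("survival_probability must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(time_years = as.numeric(time_years),
                        survival_probability = as.numeric(survival_probability))
  structure(out, role = role, treatment = treatment,
            class = c("digitized_curve", class(out)))
}

#' Read / write a digitized curve as headered CSV
#'
#' File format: two columns `time_years`, `survival_probability`.
#'
#' @param path CSV file path.
#' @param role,treatment Labels attached to the curve (see
#'   [digitized_curve()]).
#' @return `read_curve()` returns a `digitized_curve`;
#'   `write_curve()` returns `path` invisibly.
#' @export
read_curve <- function(path, role, treatment = "all") {
  df <- utils::read.csv(path)
  if (!all(c("time_years", "survival_probability") %in% names(df))) {
    stop("curve file must have columns time_years, survival_probability",
         call. = FALSE)
  }
  digitized_curve(df$time_years, df$survival_probability, role, treatment)
}

#' @rdname read_curve
#' @param curve A `digitized_curve`.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[c("time_years", "survival_probability")],
                   path, row.names = FALSE)
  invisible(path)
}

# non-increasing isotonic (PAVA) repair; returns list(s, magnitude)
repair_monotone <- function(time_years, s) {
  fit <- stats::isoreg(time_years, -s)
  repaired <- pmin(pmax(-fit$yf, 0), 1)
  list(s = repaired, magnitude = max(abs(repaired - s)))
}

#' Fit one parametric family to a digitized curve
#'
#' Digitized coordinates are not individual-level data, so a Kaplan-Meier
#' likelihood is unavailable; fitting is nonlinear least squares on the
#' survival scale, with the Gaussian pseudo-likelihood information
#' criterion `AIC = n * log(RSS / n) + 2p` used for model comparison.
#' Points are first made non-increasing by a pool-adjacent-violators
#' repair. Optimization runs Levenberg-Marquardt from five deterministic
#' data-derived starting points per family (no randomness), keeping the
#' best; fits are reproducible without seeds.
#'
#' A fit is reported as non-converged (and thus excluded from selection by
#' [select_best()]) when the optimizer fails, parameters are invalid, the
#' input has no events (all survival at 1), or the fitted S(t) is not
#' non-increasing over `[0, monotone_horizon]` — the latter mainly guards
#' the spline families against non-monotone extrapolation.
#'
#' @param curve A [digitized_curve()] (or plain data frame with the same
#'   columns).
#' @param family One of [surv_families()].
#' @param monotone_horizon Horizon (years) over which fitted survival must
#'   be non-increasing to count as converged.
#' @return A `fit_result`: list with `model` ([parametric_survival()] or
#'   `NULL`), `aic`, `rss`, `converged`, `n`, `n_params`,
#'   `repair_magnitude`, `family`.
#' @examples
#' cv <- digitized_curve(0:10, exp(-0.2 * (0:10)), role = "PFS")
#' fit_curve(cv, "exponential")$model$params
#' @export
fit_curve <- function(curve, family, monotone_horizon = 60) {
  family <- match.arg(family, surv_families())
  t <- curve$time_years
  s <- curve$survival_probability
  np <- family_n_params(family)
  if (length(t) < max(3L, np + 1L)) {
    stop("need at least max(3, n_params + 1) points to fit", call. = FALSE)
  }
  rep_ <- repair_monotone(t, s)
  s <- rep_$s

  failed <- function() {
    structure(list(model = NULL, aic = Inf, rss = Inf, converged = FALSE,
                   n = length(t), n_params = np,
                   repair_magnitude = rep_$magnitude, family = family),
              class = "fit_result")
  }
  # no observed events: every positive-hazard family is degenerate
  if (max(1 - s) < 1e-9) return(failed())

  knots <- NULL
  if (is_rcs_family(family)) {
    lt <- log(t[t > 0])
    qs <- stats::quantile(lt, c(0.33, 0.67), names = FALSE)
    knots <- c(min(lt), qs, max(lt))
    if (is.unsorted(knots, strictly = TRUE) == FALSE &&
        any(diff(knots) <= 1e-8)) {
      return(failed())
    }
  }

  starts <- fit_starts(family, t, s)
  best <- NULL
  for (theta0 in starts) {
    resid_fn <- function(theta) {
      m <- try(theta_to_model(family, theta, knots), silent = TRUE)
      if (inherits(m, "try-error")) return(rep(1e3, length(t)))
      pred <- try(survival_at(m, t), silent = TRUE)
      if (inherits(pred, "try-error") || any(!is.finite(pred))) {
        return(rep(1e3, length(t)))
      }
      pred - s
    }
    fit <- try(minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) best <- list(theta = fit$par, rss = rss)
  }
  if (is.null(best)) return(failed())

  model <- try(theta_to_model(family, best$theta, knots), silent = TRUE)
  if (inherits(model, "try-error")) return(failed())
  grid <- seq(0, monotone_horizon, length.out = 400)
  sg <- survival_at(model, grid)
  if (any(diff(sg) > 1e-8)) return(failed())

  n <- length(t)
  rss <- max(best$rss, 1e-300)
  structure(list(model = model, aic = n * log(rss / n) + 2 * np, rss = best$rss,
                 converged = TRUE, n = n, n_params = np,
                 repair_magnitude = rep_$magnitude, family = family),
            class = "fit_result")
}

# unconstrained theta <-> constrained params
theta_to_model <- function(family, theta, knots = NULL) {
  params <- switch(family,
    "exponential" = exp(theta),
    "gamma" = exp(theta),
    "generalized-gamma" = c(theta[1], exp(theta[2]), theta[3]),
    "log-normal" = c(theta[1], exp(theta[2])),
    "log-logistic" = exp(theta),
    "Gompertz" = c(theta[1], exp(theta[2])),
    "Weibull" = exp(theta),
    theta # RCS: all free
  )
  parametric_survival(family, params, knots)
}

model_to_theta <- function(model) {
  p <- unname(model$params)
  switch(model$family,
    "exponential" = log(p),
    "gamma" = log(p),
    "generalized-gamma" = c(p[1], log(p[2]), p[3]),
    "log-normal" = c(p[1], log(p[2])),
    "log-logistic" = log(p),
    "Gompertz" = c(p[1], log(p[2])),
    "Weibull" = log(p),
    p
  )
}

# five deterministic data-derived starting points (unconstrained scale)
fit_starts <- function(family, t, s) {
  pos <- t > 0 & s > 0 & s < 1
  if (any(pos)) {
    tl <- max(t[pos]); sl <- s[t == tl][1]
    r0 <- -log(max(min(sl, 0.999), 1e-6)) / tl
  } else {
    r0 <- 0.1
  }
  r0 <- max(r0, 1e-6)
  # crude median time
  below <- which(s <= 0.5)
  tmed <- if (length(below)) {
    i <- below[1]
    if (i == 1) max(t[1], 1e-3) else {
      t[i - 1] + (t[i] - t[i - 1]) * (s[i - 1] - 0.5) /
        max(s[i - 1] - s[i], 1e-12)
    }
  } else log(2) / r0
  tmed <- max(tmed, 1e-3)
  shapes <- c(0.5, 0.75, 1, 1.5, 2.5)
  mk <- function(...) lapply(seq_len(5), ...)
  switch(family,
    "exponential" = mk(function(i) log(r0 * c(0.25, 0.5, 1, 2, 4)[i])),
    "Weibull" = mk(function(i) {
      k <- shapes[i]; log(c(k, tmed / log(2)^(1 / k)))
    }),
    "gamma" = mk(function(i) log(c(shapes[i], shapes[i] * r0))),
    "log-normal" = mk(function(i) c(log(tmed),
                                    log(c(0.25, 0.5, 1, 1.5, 2.5)[i]))),
    "log-logistic" = mk(function(i) log(c(shapes[i], tmed))),
    "Gompertz" = mk(function(i) c(c(-0.1, -0.02, 0.001, 0.05, 0.15)[i],
                                  log(r0))),
    "generalized-gamma" = mk(function(i) c(log(tmed), log(1),
                                           c(-1, 0, 0.5, 1, 2)[i])),
    mk(function(i) { # RCS families: Weibull-equivalent starts
      k <- shapes[i]; sc <- tmed / log(2)^(1 / k)
      c(-k * log(sc), k, 0, 0)
    })
  )
}

#' Select the best fit by AIC
#'
#' Among converged fits, picks the one with minimal pseudo-AIC; ties are
#' broken by fewer parameters, then by the canonical family order of
#' [surv_families()].
#'
#' @param fits A list of `fit_result` objects (e.g. from [fit_curve()] over
#'   [surv_families()]).
#' @return The winning [parametric_survival()] model.
#' @export
select_best <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop("no converged fit to select from", call. = FALSE)
  aic <- vapply(conv, function(f) f$aic, numeric(1))
  npar <- vapply(conv, function(f) f$n_params, numeric(1))
  ford <- match(vapply(conv, function(f) f$family, character(1)),
                surv_families())
  conv[[order(aic, npar, ford)[1]]]$model
}

#' Fit all candidate families and select the best
#'
#' @inheritParams fit_curve
#' @param families Candidate family labels (default: all nine).
#' @return A list with `best` (the selected [parametric_survival()]) and
#'   `fits` (all `fit_result`s, named by family).
#' @export
fit_best <- function(curve, families = surv_families(),
                     monotone_horizon = 60) {
  fits <- lapply(families, function(f) fit_curve(curve, f, monotone_horizon))
  names(fits) <- families
  list(best = select_best(fits), fits = fits)
}

#' Fit a whole set of digitized curves
#'
#' @param curves Named list of [digitized_curve()]s (names like
#'   `"TTD:imatinib"`).
#' @inheritParams fit_best
#' @return Named list of selected [parametric_survival()] models.
#' @export
fit_models <- function(curves, families = surv_families(),
                       monotone_horizon = 60) {
  lapply(curves, function(cv) fit_best(cv, families, monotone_horizon)$best)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a survival-curve fit
#'
#' @param x A `fit_result` from [fit_curve()].
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`);
#'   `glance()`: one row of fit diagnostics.
#' @method tidy fit_result
#' @export
tidy.fit_result <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$model$params),
                 estimate = unname(x$model$params))
}

#' @rdname tidy.fit_result
#' @method glance fit_result
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(family = x$family, aic = x$aic, rss = x$rss,
                 converged = x$converged, n_params = x$n_params, n = x$n,
                 repair_magnitude = x$repair_magnitude)
}

#' Serialize fitted models to JSON
#'
#' @param models Named list of [parametric_survival()] models.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(family = m$family, params = as.list(m$params),
         knots = if (is.null(m$knots)) NULL else as.numeric(m$knots))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(m) {
    parametric_survival(m$family, unlist(m$params),
                        knots = if (length(m$knots)) m$knots else NULL)
  })
}
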