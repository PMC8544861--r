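#' Parametric survival families
#'
#' The nine candidate time-to-event families used to extrapolate digitized
#' Kaplan-Meier coordinates: exponential, gamma, generalized gamma,
#' log-normal, log-logistic, Gompertz, Weibull, and two Royston-Parmar
#' restricted-cubic-spline (RCS) models with two interior knots on log time
#' (proportional-hazards "RCS-Weibull" and proportional-odds
#' "RCS-log-logistic" scales).
#'
#' Parameterizations (all scales/rates strictly positive):
#' \describe{
#'   \item{exponential}{`rate`; S(t) = exp(-rate * t).}
#'   \item{weibull}{`shape`, `scale`; S(t) = exp(-(t/scale)^shape).}
#'   \item{gamma}{`shape`, `rate`; S(t) = 1 - pgamma(t, shape, rate).}
#'   \item{generalized-gamma}{`mu`, `sigma`, `Q`; Prentice form, as in
#'     [flexsurv::pgengamma()]. Nests Weibull (Q = 1), log-normal (Q = 0)
#'     and gamma (Q = sigma).}
#'   \item{log-normal}{`meanlog`, `sdlog`.}
#'   \item{log-logistic}{`shape`, `scale`; S(t) = 1 / (1 + (t/scale)^shape).}
#'   \item{gompertz}{`shape` (real), `rate`; as in [flexsurv::pgompertz()].}
#'   \item{RCS-Weibull / RCS-log-logistic}{spline coefficients
#'     `gamma0..gamma3` with knot vector on log time; cumulative hazard
#'     (resp. odds) is a natural cubic spline in log t, as in
#'     [flexsurv::psurvspline()]. Nest Weibull resp. log-logistic when the
#'     two interior-knot coefficients are zero.}
#' }
#'
#' @return `surv_families()` returns the family labels in their canonical
#'   order (used as the final tie-break in model selection).
#' @export
surv_families <- function() {
  c("exponential", "gamma", "generalized-gamma", "log-normal",
    "log-logistic", "Gompertz", "Weibull", "RCS-Weibull", "RCS-log-logistic")
}

# number of free parameters per family (RCS: 2 + n interior knots)
family_n_params <- function(family) {
  switch(family,
    "exponential" = 1L,
    "gamma" = 2L, "generalized-gamma" = 3L, "log-normal" = 2L,
    "log-logistic" = 2L, "Gompertz" = 2L, "Weibull" = 2L,
    "RCS-Weibull" = 4L, "RCS-log-logistic" = 4L,
    stop("unknown survival family: ", family, call. = FALSE)
  )
}

family_par_names <- function(family) {
  switch(family,
    "exponential" = "rate",
    "gamma" = c("shape", "rate"),
    "generalized-gamma" = c("mu", "sigma", "Q"),
    "log-normal" = c("meanlog", "sdlog"),
    "log-logistic" = c("shape", "scale"),
    "Gompertz" = c("shape", "rate"),
    "Weibull" = c("shape", "scale"),
    "RCS-Weibull" = paste0("gamma", 0:3),
    "RCS-log-logistic" = paste0("gamma", 0:3)
  )
}

is_rcs_family <- function(family) family %in% c("RCS-Weibull", "RCS-log-logistic")

#' Construct a parametric survival model
#'
#' @param family One of [surv_families()].
#' @param params Named (or positional) numeric parameter vector in the
#'   family's parameterization; see [surv_families()].
#' @param knots For the RCS families, the full knot vector on log time
#'   (boundary knots first/last, interior knots between); ignored otherwise.
#' @return An object of class `parametric_survival`.
#' @examples
#' m <- parametric_survival("Weibull", c(shape = 1.5, scale = 8))
#' survival_at(m, c(0, 4, 8))
#' @export
parametric_survival <- function(family, params, knots = NULL) {
  family <- match.arg(family, surv_families())
  params <- as.numeric(params)
  np <- family_n_params(family)
  if (length(params) != np) {
    stop(sprintf("family '%s' takes %d parameters, got %d", family, np,
                 length(params)), call. = FALSE)
  }
  names(params) <- family_par_names(family)
  validate_surv_params(family, params)
  if (is_rcs_family(family)) {
    if (is.null(knots) || length(knots) != 4L || is.unsorted(knots, strictly = TRUE)) {
      stop("RCS families need 4 strictly increasing log-time knots", call. = FALSE)
    }
  }
  structure(list(family = family, params = params, knots = knots),
            class = "parametric_survival")
}

validate_surv_params <- function(family, params) {
  bad <- function(msg) stop("invalid parameters for ", family, ": ", msg,
                            call. = FALSE)
  if (any(!is.finite(params))) bad("non-finite value")
  # exponential permits rate 0 (a flat no-event curve, useful in toy models)
  if (family == "exponential" && params[["rate"]] < 0) bad("rate must be >= 0")
  positive <- switch(family,
    "gamma" = c("shape", "rate"),
    "generalized-gamma" = "sigma",
    "log-normal" = "sdlog",
    "log-logistic" = c("shape", "scale"),
    "Gompertz" = "rate",
    "Weibull" = c("shape", "scale"),
    character(0)
  )
  if (length(positive) && any(params[positive] <= 0)) {
    bad(paste(paste(positive, collapse = "/"), "must be positive"))
  }
  invisible(TRUE)
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat("<parametric_survival> family:", x$family, "\n")
  print(round(x$params, 6))
  if (!is.null(x$knots)) cat("knots (log t):", round(x$knots, 4), "\n")
  invisible(x)
}

#' Evaluate the survival function S(t)
#'
#' @param model A [parametric_survival()] object.
#' @param t Non-negative time(s) in years.
#' @return S(t), a value in \[0, 1\] per element of `t`; S(0) is exactly 1.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and non-negative", call. = FALSE)
  }
  p <- model$params
  s <- switch(model$family,
    "exponential" = exp(-p[["rate"]] * t),
    "gamma" = stats::pgamma(t, shape = p[["shape"]], rate = p[["rate"]],
                            lower.tail = FALSE),
    "generalized-gamma" = flexsurv::pgengamma(t, mu = p[["mu"]],
      sigma = p[["sigma"]], Q = p[["Q"]], lower.tail = FALSE),
    "log-normal" = stats::plnorm(t, meanlog = p[["meanlog"]],
                                 sdlog = p[["sdlog"]], lower.tail = FALSE),
    "log-logistic" = flexsurv::pllogis(t, shape = p[["shape"]],
                                       scale = p[["scale"]], lower.tail = FALSE),
    "Gompertz" = flexsurv::pgompertz(t, shape = p[["shape"]],
                                     rate = p[["rate"]], lower.tail = FALSE),
    "Weibull" = exp(-(t / p[["scale"]])^p[["shape"]]),
    "RCS-Weibull" = psurvspline_safe(t, p, model$knots, "hazard"),
    "RCS-log-logistic" = psurvspline_safe(t, p, model$knots, "odds")
  )
  s[t == 0] <- 1
  pmin(pmax(as.numeric(s), 0), 1)
}

psurvspline_safe <- function(t, gamma, knots, scale) {
  out <- numeric(length(t))
  pos <- t > 0
  out[!pos] <- 1
  if (any(pos)) {
    out[pos] <- flexsurv::psurvspline(t[pos], gamma = as.numeric(gamma),
                                      knots = knots, scale = scale,
                                      lower.tail = FALSE)
  }
  out
}

#' Per-cycle transition probability from a survival model
#'
#' Converts a time-to-event curve into the conditional probability that the
#' event occurs during cycle `cycle_index` (0-based) of length
#' `cycle_length`, given event-free survival to the start of the cycle:
#' `1 - S((k + 1) * delta) / S(k * delta)`.
#'
#' When the curve is numerically depleted (`S(k * delta) == 0`) the
#' probability is returned as 1 and a `"cmlcea_depleted"` warning is raised.
#'
#' @param model A [parametric_survival()] object.
#' @param cycle_index 0-based cycle number(s).
#' @param cycle_length Cycle length in years (model default 1).
#' @return Probability in \[0, 1\] per cycle index.
#' @export
cycle_probability <- function(model, cycle_index, cycle_length = 1) {
  stopifnot(cycle_length > 0, all(cycle_index >= 0),
            all(cycle_index == floor(cycle_index)))
  s0 <- survival_at(model, cycle_index * cycle_length)
  s1 <- survival_at(model, (cycle_index + 1) * cycle_length)
  p <- ifelse(s0 <= 0, 1, 1 - s1 / s0)
  if (any(s0 <= 0)) {
    rlang::warn("survival curve depleted: conditional probability set to 1",
                class = "cmlcea_depleted")
  }
  pmin(pmax(p, 0), 1)
}

# vectorised, warning-free variant used by the cohort engine
cycle_probabilities <- function(model, n_cycles, cycle_length = 1) {
  k <- seq_len(n_cycles) - 1
  s0 <- survival_at(model, k * cycle_length)
  s1 <- survival_at(model, (k + 1) * cycle_length)
  pmin(pmax(ifelse(s0 <= 0, 1, 1 - s1 / s0), 0), 1)
}
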