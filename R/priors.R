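# Priors over the quantile-space parameters (q1, med, gamma, delta).
# Scaled-Beta convention (sequential scaling, ordering holds by construction):
#   delta ~ Uniform(l, u)
#   q1  = delta + B1 * (max_age - delta),  B1 ~ Beta(q1 shapes)
#   med = q1    + B2 * (max_age - q1),     B2 ~ Beta(med shapes)
#   gamma ~ Beta(gamma shapes)

#' Construct a prior set over quantile-space parameters
#'
#' @param q1 Beta shape pair for the first-quartile fraction.
#' @param med Beta shape pair for the median fraction.
#' @param gamma Beta shape pair for the asymptote.
#' @param delta Uniform bounds (lower, upper) in years for the threshold.
#' @param max_age Age-grid upper bound (default 94).
#' @return An object of class `prior_set`.
#' @seealso [default_priors()], [sample_prior()], [log_prior_density()]
#' @export
prior_set <- function(q1 = c(6, 3), med = c(2, 2), gamma = c(1, 1),
                      delta = c(5, 30), max_age = 94) {
  shapes_ok <- function(s) length(s) == 2L && all(is.finite(s)) && all(s > 0)
  if (!shapes_ok(q1) || !shapes_ok(med) || !shapes_ok(gamma))
    stop("Beta shape parameters must be positive pairs")
  if (length(delta) != 2L || delta[1] < 0 || delta[2] <= delta[1] ||
      delta[2] >= max_age)
    stop("delta bounds must satisfy 0 <= lower < upper < max_age")
  structure(list(q1 = as.numeric(q1), med = as.numeric(med),
                 gamma = as.numeric(gamma), delta = as.numeric(delta),
                 max_age = as.integer(max_age)),
            class = "prior_set")
}

#' Default uninformative priors
#'
#' First quartile: scaled Beta(6, 3); median: scaled Beta(2, 2); asymptote:
#' Beta(1, 1) (uniform on (0,1)); threshold: Uniform(5, 30) years. Suitable
#' for exploratory analysis when little is known about the penetrance
#' curve's shape.
#'
#' @param max_age Age-grid upper bound (default 94).
#' @return A [prior_set()].
#' @export
default_priors <- function(max_age = 94) prior_set(max_age = max_age)

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf(paste0(
    "prior_set: q1 ~ scaled Beta(%g, %g), med ~ scaled Beta(%g, %g), ",
    "gamma ~ Beta(%g, %g), delta ~ Uniform(%g, %g)\n"),
    x$q1[1], x$q1[2], x$med[1], x$med[2], x$gamma[1], x$gamma[2],
    x$delta[1], x$delta[2]))
  invisible(x)
}

#' Sample from the prior
#'
#' Draws under the sequential-scaling convention, which guarantees
#' `delta < q1 < med < max_age` by construction.
#'
#' @param ps A [prior_set()].
#' @param n Number of draws.
#' @return A data frame with columns `q1, med, gamma, delta` (`n` rows).
#' @export
sample_prior <- function(ps, n = 1L) {
  stopifnot(inherits(ps, "prior_set"))
  delta <- runif(n, ps$delta[1], ps$delta[2])
  b1 <- rbeta(n, ps$q1[1], ps$q1[2])
  q1 <- delta + b1 * (ps$max_age - delta)
  b2 <- rbeta(n, ps$med[1], ps$med[2])
  med <- q1 + b2 * (ps$max_age - q1)
  gamma <- rbeta(n, ps$gamma[1], ps$gamma[2])
  data.frame(q1 = q1, med = med, gamma = gamma, delta = delta)
}

# one prior draw as a quantile_params object (clamped off the open boundaries)
sample_prior_qp <- function(ps) {
  d <- sample_prior(ps, 1L)
  eps <- 1e-6
  quantile_params(q1 = d$q1, med = min(d$med, ps$max_age - eps),
                  gamma = min(max(d$gamma, eps), 1 - eps),
                  delta = d$delta, max_age = ps$max_age)
}

#' Prior log-density
#'
#' Sum of component log-densities including the Jacobians of the interval
#' scalings; `-Inf` outside the support.
#'
#' @param ps A [prior_set()].
#' @param q A [quantile_params()] object, or a data frame / named list with
#'   elements `q1, med, gamma, delta` (vectorized over rows).
#' @return Numeric vector of log-densities.
#' @export
log_prior_density <- function(ps, q) {
  stopifnot(inherits(ps, "prior_set"))
  q1 <- q$q1; med <- q$med; gamma <- q$gamma; delta <- q$delta
  n <- length(q1)
  out <- rep(-Inf, n)
  ok <- is.finite(q1) & is.finite(med) & is.finite(gamma) & is.finite(delta) &
    delta >= ps$delta[1] & delta <= ps$delta[2] &
    delta < q1 & q1 < med & med < ps$max_age & gamma > 0 & gamma < 1
  if (!any(ok)) return(out)
  b1 <- (q1[ok] - delta[ok]) / (ps$max_age - delta[ok])
  b2 <- (med[ok] - q1[ok]) / (ps$max_age - q1[ok])
  out[ok] <- dunif(delta[ok], ps$delta[1], ps$delta[2], log = TRUE) +
    dbeta(b1, ps$q1[1], ps$q1[2], log = TRUE) - log(ps$max_age - delta[ok]) +
    dbeta(b2, ps$med[1], ps$med[2], log = TRUE) - log(ps$max_age - q1[ok]) +
    dbeta(gamma[ok], ps$gamma[1], ps$gamma[2], log = TRUE)
  out
}

# Monte-Carlo prior standard deviations (used to scale the initial proposal)
prior_component_sds <- function(ps, n = 4000L) {
  d <- sample_prior(ps, n)
  vapply(d[c("q1", "med", "gamma", "delta")], sd, 0)
}

# ---- moment matching helpers ------------------------------------------------

beta_from_mean_var <- function(m, v) {
  stopifnot(m > 0, m < 1)
  v <- min(v, 0.95 * m * (1 - m))  # keep shapes positive
  nu <- m * (1 - m) / v - 1
  c(m * nu, (1 - m) * nu)
}

beta_from_mean_ess <- function(m, ess) c(m * ess, (1 - m) * ess)

# ---- elicitation from published summaries -----------------------------------

#' Elicit an asymptote prior from a relative-risk estimate
#'
#' Translates a published relative risk (e.g. an odds ratio treated as a
#' risk ratio for a rare disease) with its confidence interval into a Beta
#' prior for the asymptote: the implied carrier lifetime risk is
#' `min(rr * baseline_lifetime, 0.99)`, and the standard deviation follows
#' from the CI width of `log(rr)` by the delta method. Other components are
#' left at their defaults.
#'
#' @param rr Relative-risk point estimate, > 0.
#' @param ci Confidence interval for `rr` as `c(lower, upper)` (95% by
#'   default; see `level`).
#' @param baseline_lifetime Population lifetime risk in (0, 1).
#' @param level Confidence level of `ci`.
#' @param priors Prior set to modify (defaults to [default_priors()]).
#' @return A [prior_set()] with the `gamma` component replaced.
#' @export
elicit_from_relative_risk <- function(rr, ci = NULL, baseline_lifetime,
                                      level = 0.95, priors = default_priors()) {
  if (!is.numeric(rr) || length(rr) != 1L || !is.finite(rr) || rr <= 0)
    stop("rr must be a single positive number")
  stopifnot(baseline_lifetime > 0, baseline_lifetime < 1)
  r <- min(rr * baseline_lifetime, 0.99)
  if (is.null(ci)) {
    sd_r <- 0.25 * r  # vague default when no interval is reported
  } else {
    stopifnot(length(ci) == 2L, all(ci > 0), ci[1] <= rr, rr <= ci[2])
    z <- -qnorm((1 - level) / 2)
    sd_log_rr <- (log(ci[2]) - log(ci[1])) / (2 * z)
    sd_r <- r * sd_log_rr  # delta method on r = baseline * exp(log rr)
  }
  m <- min(max(r, 1e-4), 0.99)
  shapes <- if (sd_r <= 0) beta_from_mean_ess(m, 1e6) else beta_from_mean_var(m, sd_r^2)
  out <- priors
  out$gamma <- shapes
  out
}

#' Elicit quartile and asymptote priors from age-specific risk data
#'
#' Supports two published-summary formats. (i) A *quartile summary*: the
#' reported first-quartile and median onset ages with the study's follow-up
#' limit and size. (ii) A table of `(age, cumulative risk)` points, as read
#' off a Kaplan-Meier curve: with exactly two points these are interpreted
#' as the labeled quartile points (first = Q1 age, second = median age;
#' asymptote = twice the median-point risk); with three or more points the
#' last point is taken as the terminal plateau risk and quartile ages are
#' interpolated where the curve crosses a quarter and half of it.
#'
#' Beta shapes are chosen so the scaled prior mean equals the reported age
#' (scaling intervals anchored at the prior mean threshold) and the
#' effective sample size equals the study size, floored at the default
#' prior's ESS and capped at 1000. The asymptote prior carries binomial
#' uncertainty at the study size. The threshold prior is left at its
#' default.
#'
#' @param points Data frame with columns `age` and `risk` (cumulative),
#'   ordered in age; or `NULL` when `q1_age`/`med_age` are given directly.
#' @param n Study size (number of carriers followed).
#' @param q1_age,med_age Reported quartile onset ages (quartile-summary
#'   form).
#' @param followup Upper age limit of follow-up (informational).
#' @param priors Prior set to modify (defaults to [default_priors()]).
#' @return A [prior_set()] with `q1`, `med` and `gamma` replaced.
#' @export
elicit_from_risk_points <- function(points = NULL, n, q1_age = NULL,
                                    med_age = NULL, followup = NULL,
                                    priors = default_priors()) {
  stopifnot(is.numeric(n), n >= 1)
  if (is.null(q1_age)) {
    if (is.null(points) || nrow(points) < 2L)
      stop("need >= 2 (age, cumulative risk) points or an explicit quartile summary")
    age <- points$age; risk <- points$risk
    if (any(diff(age) <= 0)) stop("risk-point ages must be strictly increasing")
    if (any(diff(risk) < 0)) stop("cumulative risk points must be nondecreasing")
    if (any(risk < 0 | risk > 1)) stop("risks must lie in [0, 1]")
    if (nrow(points) == 2L) {
      q1_age <- age[1]; med_age <- age[2]
      gamma_hat <- min(2 * risk[2], 0.99)
    } else {
      gamma_hat <- min(risk[length(risk)], 0.99)
      q1_age <- approx(risk, age, xout = gamma_hat / 4, ties = "ordered")$y
      med_age <- approx(risk, age, xout = gamma_hat / 2, ties = "ordered")$y
      if (is.na(q1_age) || is.na(med_age))
        stop("risk points must bracket a quarter and half of the terminal risk")
    }
  } else {
    if (is.null(med_age)) stop("med_age required with q1_age")
    gamma_hat <- NULL
  }
  if (!(q1_age < med_age)) stop("first-quartile age must precede the median age")
  max_age <- priors$max_age
  delta_bar <- mean(priors$delta)
  if (q1_age <= delta_bar || med_age >= max_age)
    stop("quartile ages must lie between the prior mean threshold and max_age")
  ess_default <- max(sum(priors$q1), sum(priors$med))
  ess <- min(max(n, ess_default), 1000)
  m1 <- (q1_age - delta_bar) / (max_age - delta_bar)
  m2 <- (med_age - q1_age) / (max_age - q1_age)
  out <- priors
  out$q1 <- beta_from_mean_ess(m1, ess)
  out$med <- beta_from_mean_ess(m2, ess)
  if (!is.null(gamma_hat)) {
    g <- min(max(gamma_hat, 1e-3), 0.99)
    # binomial uncertainty at the study size, floored at the default's ESS
    out$gamma <- beta_from_mean_ess(g, min(max(n, sum(priors$gamma)), 1000))
  }
  out
}
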