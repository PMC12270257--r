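# Carrier onset model: a modified Weibull CDF with threshold and asymptote,
#   F(t) = gamma * (1 - exp(-((t - delta) / alpha)^beta))  for t > delta, else 0.
# Estimation happens in quantile space (q1, med, gamma, delta); the closed-form
# map to (alpha, beta) and its inverse live here.

#' Carrier penetrance parameters (modified Weibull)
#'
#' Construct and validate the carrier onset parameter vector
#' \eqn{\theta = (\alpha, \beta, \gamma, \delta)}: scale and shape of a
#' standard Weibull, an asymptote \eqn{\gamma \in (0,1)} giving the lifetime
#' disease probability among carriers, and a threshold \eqn{\delta \ge 0}
#' below which onset probability is zero.
#'
#' @param alpha Scale, years, > 0.
#' @param beta Shape, dimensionless, > 0.
#' @param gamma Asymptote (lifetime risk among carriers), in (0, 1).
#' @param delta Threshold (minimum onset age), years, >= 0 and < `max_age`.
#' @param max_age Upper end of the annual age grid (default 94).
#' @return An object of class `weibull_params`.
#' @seealso [penetrance_cdf()], [quantiles_to_weibull()]
#' @export
#' @examples
#' th <- weibull_params(30, 3, 0.8, 20)
#' penetrance_cdf(th, c(20, 50))
weibull_params <- function(alpha, beta, gamma, delta, max_age = 94) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            is.numeric(delta), length(alpha) == 1L, length(beta) == 1L,
            length(gamma) == 1L, length(delta) == 1L)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha (scale) must be > 0")
  if (!is.finite(beta) || beta <= 0) stop("beta (shape) must be > 0")
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1)
    stop("gamma (asymptote) must lie strictly in (0, 1)")
  if (!is.finite(delta) || delta < 0) stop("delta (threshold) must be >= 0")
  if (delta >= max_age) stop("delta (threshold) must be below max_age")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 max_age = max_age),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf(
    "Modified Weibull penetrance: alpha=%.3f beta=%.3f gamma=%.3f delta=%.1f (max_age=%d)\n",
    x$alpha, x$beta, x$gamma, x$delta, as.integer(x$max_age)))
  invisible(x)
}

#' Cumulative carrier penetrance
#'
#' Probability that a carrier develops the disease by `age`:
#' \eqn{F(t) = \gamma (1 - e^{-((t-\delta)/\alpha)^\beta})} for
#' \eqn{t > \delta}, and 0 at or below the threshold. Nondecreasing in age
#' with supremum \eqn{\gamma}.
#'
#' @param theta A [weibull_params()] object.
#' @param age Numeric vector of ages (years), >= 0.
#' @return Numeric vector of cumulative onset probabilities.
#' @export
penetrance_cdf <- function(theta, age) {
  stopifnot(inherits(theta, "weibull_params"), is.numeric(age))
  if (any(age < 0, na.rm = TRUE)) stop("age must be nonnegative")
  out <- numeric(length(age))
  above <- !is.na(age) & age > theta$delta
  out[above] <- theta$gamma *
    (1 - exp(-((age[above] - theta$delta) / theta$alpha)^theta$beta))
  out[is.na(age)] <- NA_real_
  out
}

#' Annual onset probabilities for carriers
#'
#' Discretizes the carrier penetrance onto the annual grid: entry `a` is
#' `penetrance_cdf(theta, a) - penetrance_cdf(theta, a - 1)` for
#' `a = 1, ..., max_age`. The cumulative sum at `max_age` equals the CDF
#' there; the residual `1 - F(max_age)` is the lifetime never-onset mass.
#'
#' @inheritParams penetrance_cdf
#' @param max_age Grid upper bound; defaults to the value stored in `theta`.
#' @return Numeric vector of length `max_age`, nonnegative.
#' @export
annual_onset_prob <- function(theta, max_age = theta$max_age) {
  diff(penetrance_cdf(theta, 0:max_age))
}

#' Quantile-space penetrance parameters
#'
#' The estimation parameterization: the age `q1` by which a quarter of the
#' eventually-affected carriers have onset, the median onset age `med`, the
#' asymptote `gamma`, and the threshold `delta`. Must satisfy
#' `delta < q1 < med < max_age` and `0 < gamma < 1`.
#'
#' @param q1 First-quartile onset age (years).
#' @param med Median onset age (years).
#' @param gamma Asymptote, in (0, 1).
#' @param delta Threshold (years).
#' @param max_age Age-grid upper bound (default 94).
#' @return An object of class `quantile_params`.
#' @export
quantile_params <- function(q1, med, gamma, delta, max_age = 94) {
  stopifnot(length(q1) == 1L, length(med) == 1L, length(gamma) == 1L,
            length(delta) == 1L)
  vals <- c(q1, med, gamma, delta)
  if (any(!is.finite(vals))) stop("quantile parameters must be finite")
  if (!(delta < q1 && q1 < med && med < max_age))
    stop("quantile parameters must satisfy delta < q1 < med < max_age")
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie strictly in (0, 1)")
  structure(list(q1 = q1, med = med, gamma = gamma, delta = delta,
                 max_age = max_age),
            class = "quantile_params")
}

#' @export
print.quantile_params <- function(x, ...) {
  cat(sprintf(
    "Quantile-space penetrance: q1=%.2f med=%.2f gamma=%.3f delta=%.1f (max_age=%d)\n",
    x$q1, x$med, x$gamma, x$delta, as.integer(x$max_age)))
  invisible(x)
}

#' Map quantile-space parameters to modified Weibull parameters
#'
#' Solves `F(q1)/gamma = 1/4` and `F(med)/gamma = 1/2` in closed form:
#' `beta = log(log(4/3)/log(2)) / log((q1 - delta)/(med - delta))` and
#' `alpha = (med - delta) / log(2)^(1/beta)`; `gamma` and `delta` pass
#' through unchanged.
#'
#' @param q A [quantile_params()] object.
#' @return A [weibull_params()] object.
#' @export
quantiles_to_weibull <- function(q) {
  stopifnot(inherits(q, "quantile_params"))
  if ((q$med - q$q1) < 1e-6)
    stop("degenerate quantile spacing: med - q1 must exceed 1e-6 years")
  beta <- log(log(4 / 3) / log(2)) / log((q$q1 - q$delta) / (q$med - q$delta))
  alpha <- (q$med - q$delta) / log(2)^(1 / beta)
  weibull_params(alpha, beta, q$gamma, q$delta, max_age = q$max_age)
}

#' Map modified Weibull parameters to quantile space
#'
#' Inverse of [quantiles_to_weibull()]:
#' `q1 = delta + alpha * log(4/3)^(1/beta)` and
#' `med = delta + alpha * log(2)^(1/beta)`.
#'
#' @param theta A [weibull_params()] object.
#' @return A [quantile_params()] object.
#' @export
weibull_to_quantiles <- function(theta) {
  stopifnot(inherits(theta, "weibull_params"))
  q1 <- theta$delta + theta$alpha * log(4 / 3)^(1 / theta$beta)
  med <- theta$delta + theta$alpha * log(2)^(1 / theta$beta)
  quantile_params(q1, med, theta$gamma, theta$delta, max_age = theta$max_age)
}

# ---- baseline (noncarrier) risk ---------------------------------------------

#' Baseline (noncarrier) cumulative risk by sex
#'
#' Population age-specific cumulative disease probability on the annual grid
#' `1..max_age`, used to approximate noncarrier penetrance when carriers are
#' rare. Vectors must be nondecreasing and within `[0, 1]`.
#'
#' @param female Cumulative risk for females, length `max_age`.
#' @param male Cumulative risk for males (defaults to `female`).
#' @param max_age Age-grid upper bound.
#' @return An object of class `baseline_risk` with components `female`,
#'   `male` (cumulative vectors) and `max_age`.
#' @export
baseline_risk <- function(female, male = female, max_age = length(female)) {
  check_cum <- function(x, lab) {
    if (length(x) != max_age)
      stop(sprintf("%s baseline must have length max_age (%d)", lab, max_age))
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(sprintf("%s baseline must lie in [0, 1]", lab))
    if (any(diff(x) < -1e-12))
      stop(sprintf("%s baseline cumulative risk must be nondecreasing", lab))
    pmin(pmax(x, 0), 1)
  }
  structure(list(female = check_cum(female, "female"),
                 male = check_cum(male, "male"),
                 max_age = as.integer(max_age)),
            class = "baseline_risk")
}

# linear interpolation of coarse (age, cumulative risk) points onto 1..max_age;
# anchored at (0, 0), constant beyond the last supplied age
interp_cumulative <- function(age, risk, max_age) {
  o <- order(age)
  age <- age[o]; risk <- risk[o]
  if (any(duplicated(age))) stop("duplicated ages in baseline table")
  if (any(diff(risk) < -1e-12))
    stop("baseline cumulative risk must be nondecreasing in age")
  approx(x = c(0, age), y = c(0, risk), xout = seq_len(max_age),
         method = "linear", rule = 2)$y
}

#' Read a baseline risk table
#'
#' Accepts a two-column table `(age, risk)` applied to both sexes, or a
#' three-column table `(age, female, male)`. Cumulative risks on a coarse age
#' grid are linearly interpolated to the annual grid (anchored at zero risk
#' at age 0, held constant beyond the last supplied age).
#'
#' @param file Path to a comma- or tab-delimited file with a header.
#' @param max_age Age-grid upper bound (default 94).
#' @return A [baseline_risk()] object.
#' @export
read_baseline <- function(file, max_age = 94) {
  tab <- read_delim_auto(file)
  names(tab) <- tolower(names(tab))
  if (!"age" %in% names(tab)) stop("baseline table needs an 'age' column")
  if (all(c("female", "male") %in% names(tab))) {
    baseline_risk(interp_cumulative(tab$age, tab$female, max_age),
                  interp_cumulative(tab$age, tab$male, max_age),
                  max_age = max_age)
  } else {
    riskcol <- setdiff(names(tab), "age")[1]
    if (is.na(riskcol)) stop("baseline table needs a risk column")
    cum <- interp_cumulative(tab$age, tab[[riskcol]], max_age)
    baseline_risk(cum, cum, max_age = max_age)
  }
}

#' Synthetic registry-style baseline risk
#'
#' A smooth stand-in for a SEER-style colorectal-cancer baseline: negligible
#' risk before age 30, rising to roughly 4% lifetime cumulative risk by age
#' 94, with males slightly above females. Synthetic; use [read_baseline()]
#' for real registry tables.
#'
#' @param max_age Age-grid upper bound (default 94).
#' @param lifetime Approximate sex-averaged lifetime cumulative risk.
#' @return A [baseline_risk()] object.
#' @export
default_baseline <- function(max_age = 94, lifetime = 0.045) {
  ages <- seq_len(max_age)
  shape <- ifelse(ages > 20, 1 - exp(-((ages - 20) / 60)^4), 0)
  baseline_risk(female = 0.9 * lifetime * shape,
                male = 1.1 * lifetime * shape,
                max_age = max_age)
}

#' Annual noncarrier onset probabilities
#'
#' Differences the per-sex cumulative baseline risk to annual onset
#' probabilities (entry `a` is the probability of onset in year `a`).
#'
#' @param b A [baseline_risk()] object.
#' @return List with numeric vectors `female` and `male` of length
#'   `max_age`.
#' @export
baseline_annual_onset <- function(b) {
  stopifnot(inherits(b, "baseline_risk"))
  list(female = diff(c(0, b$female)), male = diff(c(0, b$male)))
}

# shared delimiter-sniffing reader (header line decides between tab and comma)
read_delim_auto <- function(file) {
  if (!is.character(file) || length(file) != 1L || !file.exists(file))
    stop("file not found: ", file)
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.csv(file, sep = sep, stringsAsFactors = FALSE,
           na.strings = c("NA", ""), check.names = FALSE)
}
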