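test_that("default priors carry the documented shapes", {
  ps <- default_priors()
  expect_equal(ps$q1, c(6, 3))
  expect_equal(ps$med, c(2, 2))
  expect_equal(ps$gamma, c(1, 1))
  expect_equal(ps$delta, c(5, 30))
  expect_error(prior_set(q1 = c(-1, 3)), "positive")
  expect_error(prior_set(delta = c(10, 95)), "delta bounds")
})

test_that("prior draws respect the ordering and their component laws", {
  set.seed(61)
  ps <- default_priors()
  d <- sample_prior(ps, 1e5)
  expect_true(all(d$delta < d$q1 & d$q1 < d$med & d$med < 94))
  expect_true(all(d$delta >= 5 & d$delta <= 30))
  # Beta(1,1) mean 1/2, Beta(6,3) mean 2/3, within 3 standard errors
  se_g <- sqrt(1 / 12 / 1e5)
  expect_lt(abs(mean(d$gamma) - 0.5), 3 * se_g)
  b1 <- (d$q1 - d$delta) / (94 - d$delta)
  se_b1 <- sqrt(6 * 3 / (81 * 10) / 1e5)
  expect_lt(abs(mean(b1) - 6 / 9), 3 * se_b1)
  # sampling and log-density agree component-wise (KS, n = 1e5, alpha = 0.01)
  b2 <- (d$med - d$q1) / (94 - d$q1)
  expect_gt(suppressWarnings(ks.test(d$delta, "punif", 5, 30))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(b1, "pbeta", 6, 3))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(b2, "pbeta", 2, 2))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(d$gamma, "pbeta", 1, 1))$p.value, 0.01)
})

test_that("log_prior_density: support, flat components, and quadrature", {
  ps <- default_priors()
  q_ok <- quantile_params(45, 55, 0.5, 20)
  expect_true(is.finite(log_prior_density(ps, q_ok)))
  expect_identical(log_prior_density(ps, quantile_params(55, 65, 0.5, 40)), -Inf)
  expect_identical(log_prior_density(ps, list(q1 = 45, med = 40, gamma = 0.5,
                                              delta = 20)), -Inf)
  # Beta(1,1) asymptote contributes 0 in log for any gamma in (0, 1)
  l1 <- log_prior_density(ps, list(q1 = 45, med = 55, gamma = 0.1, delta = 20))
  l2 <- log_prior_density(ps, list(q1 = 45, med = 55, gamma = 0.9, delta = 20))
  expect_equal(l1, l2, tolerance = 1e-12)
  # midpoint quadrature of exp(log-density) over the support is ~ 1
  g <- 20L
  u <- (seq_len(g) - 0.5) / g
  grid <- expand.grid(u1 = u, u2 = u, u3 = u, u4 = u)
  delta <- 5 + 25 * grid$u1
  q1 <- delta + (94 - delta) * grid$u2
  med <- q1 + (94 - q1) * grid$u3
  dens <- exp(log_prior_density(ps, list(q1 = q1, med = med,
                                         gamma = grid$u4, delta = delta)))
  integral <- mean(dens * 25 * (94 - delta) * (94 - q1))
  expect_equal(integral, 1, tolerance = 0.02)
})

test_that("relative-risk elicitation moment-matches the asymptote prior", {
  # identity risk ratio: prior mean equals the baseline lifetime risk
  ps1 <- elicit_from_relative_risk(1, ci = c(0.8, 1.25), baseline_lifetime = 0.04)
  m1 <- ps1$gamma[1] / sum(ps1$gamma)
  expect_equal(m1, 0.04, tolerance = 1e-9)
  # rr = 5, baseline 0.04: mean 0.20; delta-method sd reproduced by the Beta
  ps5 <- elicit_from_relative_risk(5, ci = c(4, 6.25), baseline_lifetime = 0.04)
  a <- ps5$gamma[1]; b <- ps5$gamma[2]
  expect_equal(a / (a + b), 0.20, tolerance = 1e-9)
  sd_beta <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  sd_delta <- 0.20 * (log(6.25) - log(4)) / (2 * qnorm(0.975))
  expect_equal(sd_beta, sd_delta, tolerance = 1e-6)
  # narrowing the CI never widens the prior
  widths <- c(2, 1.5, 1, 0.5, 0.2)
  vars <- vapply(widths, function(w) {
    g <- elicit_from_relative_risk(5, ci = c(5 / exp(w), 5 * exp(w)),
                                   baseline_lifetime = 0.04)$gamma
    g[1] * g[2] / ((g[1] + g[2])^2 * (g[1] + g[2] + 1))
  }, 0)
  expect_true(all(diff(vars) < 0))
  # other components untouched; invalid rr rejected
  expect_equal(ps5$q1, c(6, 3))
  expect_error(elicit_from_relative_risk(-2, baseline_lifetime = 0.1), "positive")
})

test_that("risk-point elicitation centres quartile priors by construction", {
  pts <- data.frame(age = c(45, 55), risk = c(0.10, 0.25))
  ps <- elicit_from_risk_points(points = pts, n = 5000, followup = 80)
  # scaled prior mean equals the requested centre exactly
  m1 <- ps$q1[1] / sum(ps$q1)
  expect_equal(m1, (45 - 17.5) / (94 - 17.5), tolerance = 1e-6)
  m2 <- ps$med[1] / sum(ps$med)
  expect_equal(m2, (55 - 45) / (94 - 45), tolerance = 1e-6)
  # large n concentrates (ESS capped at 1000)
  expect_equal(sum(ps$q1), 1000, tolerance = 1e-9)
  # asymptote read as twice the median-point risk
  expect_equal(ps$gamma[1] / sum(ps$gamma), 0.5, tolerance = 1e-9)
  # threshold untouched
  expect_equal(ps$delta, c(5, 30))
  # n = 1: effective sample size floored at the default's
  ps1 <- elicit_from_risk_points(points = pts, n = 1)
  expect_equal(sum(ps1$q1), sum(default_priors()$q1) + 0)
  # >= 3 points: terminal plateau + interpolated quartiles
  pts3 <- data.frame(age = c(40, 55, 80), risk = c(0.10, 0.25, 0.50))
  ps3 <- elicit_from_risk_points(points = pts3, n = 200)
  expect_equal(ps3$gamma[1] / sum(ps3$gamma), 0.5, tolerance = 1e-9)
  m1_3 <- ps3$q1[1] / sum(ps3$q1)
  q1_age <- 40 + 15 * (0.125 - 0.10) / 0.15   # linear interpolation at gamma/4
  expect_equal(m1_3, (q1_age - 17.5) / (94 - 17.5), tolerance = 1e-6)
  # non-monotone or malformed input
  expect_error(elicit_from_risk_points(
    points = data.frame(age = c(45, 55), risk = c(0.3, 0.2)), n = 10),
    "nondecreasing")
  expect_error(elicit_from_risk_points(points = pts[1, , drop = FALSE], n = 10),
               ">= 2")
})

test_that("elicitation always yields valid prior sets under fuzzing", {
  set.seed(62)
  for (r in 1:50) {
    rr <- exp(runif(1, -1, 3))
    w <- runif(1, 0.01, 1.5)
    ps <- elicit_from_relative_risk(rr, ci = c(rr / exp(w), rr * exp(w)),
                                    baseline_lifetime = runif(1, 0.005, 0.3))
    expect_s3_class(ps, "prior_set")
    expect_true(all(ps$gamma > 0))
    a1 <- runif(1, 25, 60); a2 <- a1 + runif(1, 2, 20)
    r2 <- sort(runif(2, 0.02, 0.45))
    ps2 <- elicit_from_risk_points(points = data.frame(age = c(a1, a2), risk = r2),
                                   n = sample(1:5000, 1))
    expect_true(all(c(ps2$q1, ps2$med, ps2$gamma) > 0))
    # draws from the elicited prior are valid by construction
    d <- sample_prior(ps2, 100)
    expect_true(all(d$delta < d$q1 & d$q1 < d$med))
  }
})
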