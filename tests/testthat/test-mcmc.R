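mid_state <- function(d = 4L, scale = 1e-4, cfg = mcmc_config(sex_specific = d == 8L)) {
  cur <- rep(c(45, 55, 0.5, 20), d / 4)
  names(cur) <- pedpen:::param_names(cfg)
  list(current = cur, lp = 0, chol = chol(diag(scale^2, d)),
       cov0 = diag(scale^2, d), mean = rep(0, d), m2 = matrix(0, d, d),
       n_hist = 0L, iter = 0L, accept = 0L, d = d,
       priors = default_priors(), cfg = cfg)
}

test_that("config and retained-count arithmetic", {
  cfg <- mcmc_config()
  expect_identical(cfg$n_iter, 20000L)
  expect_identical(cfg$n_chains, 4L)
  expect_equal(cfg$burn_in, 0.1)
  expect_error(mcmc_config(burn_in = 1), "burn_in")
  expect_error(mcmc_config(n_iter = 0), "n_iter")
  # retained = n_iter - floor(burn_in * n_iter), exactly
  for (bi in c(0, 0.1, 0.25, 0.333)) {
    s <- suppressMessages(run_chains(
      empty_ped_set(),
      cfg = mcmc_config(n_chains = 1, n_iter = 400, burn_in = bi, seed = 9,
                        sex_specific = FALSE)))
    expect_identical(nrow(s$retained[[1]]), 400L - as.integer(floor(bi * 400)))
  }
})

test_that("check_bounds enforces support and ordering per sex block", {
  ps <- default_priors()
  cfg4 <- mcmc_config(sex_specific = FALSE)
  expect_true(check_bounds(c(45, 55, 0.5, 20), ps, cfg4))
  expect_false(check_bounds(c(45, 55, 1.2, 20), ps, cfg4))   # asymptote
  expect_false(check_bounds(c(56, 55, 0.5, 20), ps, cfg4))   # ordering
  expect_false(check_bounds(c(45, 55, 0.5, 40), ps, cfg4))   # delta support
  expect_false(check_bounds(c(45, 95, 0.5, 20), ps, cfg4))   # med < max_age
  cfg8 <- mcmc_config(sex_specific = TRUE)
  expect_true(check_bounds(rep(c(45, 55, 0.5, 20), 2), ps, cfg8))
  expect_false(check_bounds(c(45, 55, 0.5, 20, 56, 55, 0.5, 20), ps, cfg8))
})

test_that("proposals have the configured dimension and covariance", {
  expect_length(propose(mid_state(4L)), 4L)
  expect_length(propose(mid_state(8L)), 8L)
  # Monte-Carlo covariance check against a fixed correlated target
  set.seed(71)
  A <- matrix(rnorm(16), 4)
  target <- crossprod(A) + diag(4)
  st <- mid_state(4L)
  st$chol <- chol(target)
  n <- 1e5
  steps <- matrix(rnorm(n * 4), n, 4) %*% st$chol  # propose() vectorized
  emp <- cov(steps)
  rel <- norm(emp - target, "F") / norm(target, "F")
  expect_lt(rel, 0.05)
  # epsilon regularization keeps proposals non-degenerate after adaptation
  st2 <- mid_state(4L)
  st2$cfg <- mcmc_config(sex_specific = FALSE, adapt_start = 1L,
                         adapt_epsilon = 1e-6)
  for (i in 1:20) st2 <- pedpen:::update_adaptation(st2)  # constant history
  prop <- replicate(10, propose(st2))
  expect_gt(min(apply(prop, 1, sd)), 0)
})

test_that("empirical initialization uses observed onset quartiles", {
  onsets <- c(40L, 50L, 60L, 70L)
  p <- as_ped(data.frame(
    pedigree_id = "1", id = as.character(1:6), sex = c(rep("female", 4), "female", "male"),
    mother_id = NA_character_, father_id = NA_character_,
    is_proband = c(TRUE, rep(FALSE, 5)),
    cur_age = c(75L, 75L, 75L, 75L, 60L, 60L),
    is_aff = c(rep("affected", 4), "unaffected", "unaffected"),
    onset_age = c(onsets, NA, NA),
    geno = c("carrier", "carrier", "unknown", "unknown", "unknown", "unknown"),
    stringsAsFactors = FALSE))
  peds <- as_ped_set(p)
  cfg <- mcmc_config(sex_specific = TRUE, seed = 1)
  set.seed(5)
  st <- suppressMessages(initialize_state(peds, default_priors(), cfg))
  # female block from empirical quartiles (47.5, 55) with N(0,2) jitter
  expect_lt(abs(st$current[["q1_female"]] - 47.5), 8)
  expect_lt(abs(st$current[["med_female"]] - 55), 8)
  # gamma from proportion affected among genotyped carriers (2/2 -> clamp 0.95)
  expect_equal(unname(st$current[["gamma_female"]]), 0.95)
  # delta below the minimum observed onset
  expect_lt(st$current[["delta_female"]], 40)
  # no affected males: male block falls back to a prior draw with a message
  expect_message(initialize_state(peds, default_priors(), cfg), "prior")
  # determinism under identical seeds
  set.seed(42); s1 <- suppressMessages(initialize_state(peds, default_priors(), cfg))
  set.seed(42); s2 <- suppressMessages(initialize_state(peds, default_priors(), cfg))
  expect_identical(s1, s2)
})

test_that("mh_step accepts every in-bounds proposal of a flat posterior", {
  set.seed(72)
  st <- mid_state(4L, scale = 1e-3)
  flat <- function(v) 0
  # stay in the pre-adaptation window: a flat target is improper, so the
  # adapted random walk would eventually diffuse to the support boundary
  for (i in 1:80) st <- mh_step(st, flat)
  expect_identical(st$iter, 80L)
  expect_identical(st$accept, 80L)  # tiny steps never leave the support
  # and a -Inf posterior is always rejected
  st2 <- mid_state(4L, scale = 1e-3)
  for (i in 1:50) st2 <- mh_step(st2, function(v) -Inf)
  expect_identical(st2$accept, 0L)
})

test_that("runs are deterministic given the seed and differ across seeds", {
  cfg <- function(seed) mcmc_config(n_chains = 2, n_iter = 300, seed = seed,
                                    sex_specific = FALSE)
  a <- suppressMessages(run_chains(empty_ped_set(), cfg = cfg(123)))
  b <- suppressMessages(run_chains(empty_ped_set(), cfg = cfg(123)))
  expect_identical(a$chains, b$chains)
  expect_identical(a$subseeds, b$subseeds)
  d <- suppressMessages(run_chains(empty_ped_set(), cfg = cfg(124)))
  expect_false(identical(a$chains, d$chains))
  # chains within a run explore differently
  expect_false(identical(a$chains[[1]], a$chains[[2]]))
})

test_that("estimation on a small simulated study stays in a sane regime", {
  set.seed(73)
  d <- sim_design(n_probands = 8, prevalence = 0.01, seed = 74)
  st <- simulate_study(d)
  cfg <- mcmc_config(n_chains = 1, n_iter = 1200, seed = 7, sex_specific = FALSE)
  s <- suppressMessages(estimate_penetrance(st$peds, 0.01, default_baseline(),
                                            cfg = cfg))
  # acceptance after adaptation within the fine-tuning band
  tr <- s$chains[[1]]
  second_half <- tr[601:1200, ]
  acc_post <- mean(rowSums(abs(diff(second_half))) > 0)
  expect_gt(acc_post, 0.05)
  expect_lt(acc_post, 0.6)
  # retained draws all satisfy the bounds
  r <- s$retained[[1]]
  expect_true(all(r[, "delta"] >= 5 & r[, "delta"] <= 30))
  expect_true(all(r[, "q1"] > r[, "delta"] & r[, "med"] > r[, "q1"]))
  expect_true(all(r[, "gamma"] > 0 & r[, "gamma"] < 1))
})
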