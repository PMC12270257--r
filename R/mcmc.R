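# Adaptive Metropolis sampler over the quantile-space parameters
# (q1, med, gamma, delta), one block per sex when sex_specific. Haario-style
# adaptation: after adapt_start the proposal covariance is
# s_d * (running empirical covariance + epsilon * I) with s_d = 2.38^2 / d.

#' MCMC configuration
#'
#' @param n_chains Number of independent chains (default 4).
#' @param n_iter Iterations per chain (default 20000).
#' @param burn_in Fraction of each chain discarded, in `[0, 1)`; the
#'   discarded count is `floor(burn_in * n_iter)` (default 0.1).
#' @param seed Master seed; per-chain sub-seeds derive from it.
#' @param adapt_start Iteration at which covariance adaptation begins.
#' @param adapt_epsilon Regularization added to the empirical covariance.
#' @param sex_specific Estimate separate female/male parameter blocks
#'   (default `TRUE`; the parameter vector then has 8 entries, female block
#'   first).
#' @param age_imputation Impute missing ages in-chain (default `FALSE`).
#' @param impute_every Re-imputation period in iterations (default 100).
#' @param remove_proband Mask proband phenotypes for ascertainment
#'   correction (default `FALSE`).
#' @param max_age Age-grid upper bound (default 94).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 20000L, burn_in = 0.1,
                        seed = 42L, adapt_start = 100L, adapt_epsilon = 1e-6,
                        sex_specific = TRUE, age_imputation = FALSE,
                        impute_every = 100L, remove_proband = FALSE,
                        max_age = 94L) {
  stopifnot(n_iter > 0, n_chains > 0, burn_in >= 0, burn_in < 1,
            adapt_start >= 1, adapt_epsilon > 0, impute_every >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = burn_in, seed = as.integer(seed),
                 adapt_start = as.integer(adapt_start),
                 adapt_epsilon = adapt_epsilon,
                 sex_specific = isTRUE(sex_specific),
                 age_imputation = isTRUE(age_imputation),
                 impute_every = as.integer(impute_every),
                 remove_proband = isTRUE(remove_proband),
                 max_age = as.integer(max_age)),
            class = "mcmc_config")
}

param_names <- function(cfg) {
  base <- c("q1", "med", "gamma", "delta")
  if (cfg$sex_specific) c(paste0(base, "_female"), paste0(base, "_male")) else base
}

# split an estimation vector into per-sex 4-blocks (female first)
split_blocks <- function(vec, cfg) {
  if (cfg$sex_specific) list(female = vec[1:4], male = vec[5:8])
  else list(all = vec[1:4])
}

# fast construction of weibull_params from a bounds-checked quantile block
qblock_to_weibull <- function(b, max_age) {
  beta <- log(log(4 / 3) / log(2)) / log((b[1] - b[4]) / (b[2] - b[4]))
  alpha <- (b[2] - b[4]) / log(2)^(1 / beta)
  structure(list(alpha = alpha, beta = beta, gamma = b[3], delta = b[4],
                 max_age = max_age), class = "weibull_params")
}

#' Parameter bound check
#'
#' `TRUE` iff, in every per-sex block, the threshold lies within its prior
#' support, `delta < q1 < med < max_age`, and `0 < gamma < 1`. Proposals
#' failing the check are rejected without a likelihood evaluation.
#'
#' @param vec Parameter vector (4 entries, or 8 when sex-specific).
#' @param priors A [prior_set()].
#' @param cfg An [mcmc_config()].
#' @return Logical scalar.
#' @export
check_bounds <- function(vec, priors, cfg) {
  if (any(!is.finite(vec))) return(FALSE)
  for (b in split_blocks(vec, cfg)) {
    q1 <- b[1]; med <- b[2]; gamma <- b[3]; delta <- b[4]
    if (delta < priors$delta[1] || delta > priors$delta[2]) return(FALSE)
    if (!(delta < q1 && q1 < med && med < cfg$max_age)) return(FALSE)
    if ((q1 - delta) < 1e-6 || (med - q1) < 1e-6) return(FALSE)
    if (gamma <= 0 || gamma >= 1) return(FALSE)
  }
  TRUE
}

# log prior of the full vector (blocks independent, same prior per sex)
log_prior_vec <- function(vec, priors, cfg) {
  s <- 0
  for (b in split_blocks(vec, cfg)) {
    s <- s + log_prior_density(priors, list(q1 = b[1], med = b[2],
                                            gamma = b[3], delta = b[4]))
    if (!is.finite(s)) return(-Inf)
  }
  s
}

# log-posterior closure over a compiled pedigree environment (env may be
# NULL: prior-only target, e.g. zero families)
make_log_posterior <- function(env, gm, priors, cfg) {
  fp <- if (!is.null(gm)) gm$founder_probs else NULL
  tv <- trans_vec()
  ages <- seq_len(cfg$max_age)
  function(vec) {
    lp <- log_prior_vec(vec, priors, cfg)
    if (!is.finite(lp)) return(-Inf)
    if (is.null(env) || env$n_members == 0L) return(lp)
    bl <- split_blocks(vec, cfg)
    thf <- qblock_to_weibull(bl[[1]], cfg$max_age)
    thm <- qblock_to_weibull(bl[[length(bl)]], cfg$max_age)
    cf <- penetrance_cdf(thf, ages); cm <- penetrance_cdf(thm, ages)
    car <- pheno_value(env$ptype, env$page, env$sexcode,
                       diff(c(0, cf)), diff(c(0, cm)), cf, cm)
    ph <- cbind(env$nc_val, car, car)
    ph[env$geno == 1L, 1L] <- 0
    ph[env$geno == 2L, 2:3] <- 0
    ll <- sum(peel_families_cpp(env$structs, ph, fp, tv))
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }
}

#' Initialize a chain state empirically
#'
#' `q1` and `med` start at the jittered empirical 25th/50th percentiles of
#' the observed onset ages (per sex when sex-specific); `gamma` starts at
#' the observed proportion affected among genotyped carriers, clamped to
#' (0.05, 0.95); `delta` starts uniformly on its prior support below the
#' minimum observed onset age. When a stratum has no usable onsets the
#' block falls back to a prior draw (logged via `message()`). The initial
#' proposal covariance is diagonal with scales proportional to the prior
#' standard deviations.
#'
#' @param peds A `pedigree_set` (may be empty).
#' @param priors A [prior_set()].
#' @param cfg An [mcmc_config()].
#' @return A `chain_state` list with elements `current`, `lp` (unset, `NA`),
#'   proposal Cholesky factor, running-moment accumulators, and counters.
#' @export
initialize_state <- function(peds, priors, cfg) {
  d <- if (cfg$sex_specific) 8L else 4L
  members <- if (length(peds)) do.call(rbind, lapply(peds, as.data.frame)) else NULL
  strata <- if (cfg$sex_specific) c("female", "male") else "all"
  vec <- numeric(0)
  for (s in strata) {
    sub <- if (is.null(members)) members
           else if (s == "all") members else members[members$sex == s, ]
    onsets <- if (is.null(sub)) integer(0)
              else sub$onset_age[sub$is_aff == "affected" & !is.na(sub$onset_age)]
    blk <- NULL
    if (length(onsets) >= 2L) {
      carr <- if (is.null(sub)) integer(0) else which(sub$geno == "carrier")
      g0 <- if (length(carr)) mean(sub$is_aff[carr] == "affected") else
        priors$gamma[1] / sum(priors$gamma)
      g0 <- min(max(g0, 0.05), 0.95)
      dl <- priors$delta[1]; du <- min(priors$delta[2], min(onsets) - 1)
      if (du <= dl) du <- priors$delta[2]
      for (try in seq_len(100L)) {
        cand <- c(unname(quantile(onsets, 0.25)) + rnorm(1, 0, 2),
                  unname(quantile(onsets, 0.50)) + rnorm(1, 0, 2),
                  g0, runif(1, dl, du))
        if (check_bounds(cand, priors, mcmc_config(sex_specific = FALSE,
                                                   max_age = cfg$max_age,
                                                   seed = cfg$seed))) {
          blk <- cand; break
        }
      }
    }
    if (is.null(blk)) {
      message("stratum '", s, "': no usable onset ages; initializing from the prior")
      repeat {
        dr <- sample_prior(priors, 1L)
        cand <- c(dr$q1, dr$med, min(max(dr$gamma, 1e-3), 1 - 1e-3), dr$delta)
        if (check_bounds(cand, priors, mcmc_config(sex_specific = FALSE,
                                                   max_age = cfg$max_age,
                                                   seed = cfg$seed))) {
          blk <- cand; break
        }
      }
    }
    vec <- c(vec, blk)
  }
  names(vec) <- param_names(cfg)
  sds <- rep(prior_component_sds(priors), length(strata))
  cov0 <- diag((0.05 * sds)^2, d)
  list(current = vec, lp = NA_real_,
       chol = chol(cov0), cov0 = cov0,
       mean = rep(0, d), m2 = matrix(0, d, d), n_hist = 0L,
       iter = 0L, accept = 0L, d = d,
       priors = priors, cfg = cfg)
}

#' Generate a random-walk proposal
#'
#' Multivariate Gaussian step centred at the current state with covariance
#' `s_d (Sigma_emp + epsilon I)`, `s_d = 2.38^2/d`, where `Sigma_emp` is the
#' running empirical covariance of the chain history once adaptation has
#' begun; before `adapt_start` the initial diagonal covariance is used.
#'
#' @param state A `chain_state`.
#' @return Proposed parameter vector.
#' @export
propose <- function(state) {
  state$current + drop(rnorm(state$d) %*% state$chol)
}

# Welford update of the running moments with the (possibly unchanged)
# current position, then refresh the proposal Cholesky once adapting
update_adaptation <- function(state) {
  x <- state$current
  state$n_hist <- state$n_hist + 1L
  dx <- x - state$mean
  state$mean <- state$mean + dx / state$n_hist
  state$m2 <- state$m2 + outer(dx, x - state$mean)
  if (state$iter >= state$cfg$adapt_start && state$n_hist > state$d) {
    sigma <- state$m2 / (state$n_hist - 1L)
    sd_scale <- 2.38^2 / state$d
    state$chol <- chol(sd_scale * (sigma + state$cfg$adapt_epsilon * diag(state$d)))
  }
  state
}

#' One Metropolis step
#'
#' Symmetric random-walk Metropolis: out-of-bounds proposals are rejected
#' without a likelihood evaluation; a non-finite log-posterior at an
#' in-bounds proposal is treated as a rejection. The acceptance counter and
#' the running proposal covariance are updated.
#'
#' @param state A `chain_state` with finite `lp`.
#' @param log_post Function mapping a parameter vector to the log-posterior
#'   (log prior plus summed family log-likelihoods).
#' @return The updated `chain_state`.
#' @export
mh_step <- function(state, log_post) {
  prop <- propose(state)
  state$iter <- state$iter + 1L
  if (check_bounds(prop, state$priors, state$cfg)) {
    lp2 <- log_post(prop)
    if (is.finite(lp2) && log(runif(1)) < lp2 - state$lp) {
      state$current <- setNames(prop, names(state$current))
      state$lp <- lp2
      state$accept <- state$accept + 1L
    }
  }
  update_adaptation(state)
}

#' Run the adaptive Metropolis chains
#'
#' Runs `cfg$n_chains` independent chains with distinct sub-seeds derived
#' from `cfg$seed`, discarding the first `floor(burn_in * n_iter)` draws of
#' each chain. When `cfg$age_imputation` is enabled and the data contain
#' missing ages, ages are imputed before each chain starts and re-imputed
#' every `cfg$impute_every` iterations from the carrier-posterior mixture
#' under the current parameters.
#'
#' @param peds A `pedigree_set` (may be empty: the chains then sample the
#'   prior).
#' @param gm A [genotype_model()] (`NULL` allowed with empty `peds`).
#' @param baseline A [baseline_risk()] (`NULL` allowed with empty `peds`).
#' @param priors A [prior_set()].
#' @param cfg An [mcmc_config()].
#' @return An object of class `posterior_samples`: per-chain full traces
#'   and post-burn-in `retained` matrices (columns named sex x parameter),
#'   acceptance rates, the configuration echo and the sub-seeds.
#' @export
run_chains <- function(peds, gm = NULL, baseline = NULL,
                       priors = default_priors(), cfg = mcmc_config()) {
  if (is.null(baseline) && length(peds))
    stop("baseline risk is required when families are supplied")
  if (is.null(gm) && length(peds))
    stop("a genotype model (carrier prevalence) is required when families are supplied")
  if (length(peds)) {
    for (p in peds) if (length(detect_loops(p)))
      stop(sprintf("family %s contains loops; peeling supports loop-free pedigrees",
                   p$pedigree_id[1]))
  }
  set.seed(cfg$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, cfg$n_chains)
  nms <- param_names(cfg)
  n_burn <- as.integer(floor(cfg$burn_in * cfg$n_iter))
  plan <- if (cfg$age_imputation && length(peds)) build_plan(peds) else NULL
  do_impute <- !is.null(plan) && nrow(plan$targets) > 0L

  chains <- vector("list", cfg$n_chains)
  acc <- numeric(cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(subseeds[ch])
    peds_ch <- peds
    if (do_impute) peds_ch <- initial_impute(plan, peds_ch, baseline)
    env <- NULL
    if (length(peds_ch)) {
      env <- compile_peds(peds_ch, max_age = cfg$max_age,
                          age_imputation = cfg$age_imputation)
      compile_baseline(env, baseline)
    }
    log_post <- make_log_posterior(env, gm, priors, cfg)
    state <- initialize_state(peds_ch, priors, cfg)
    state$lp <- log_post(state$current)
    tries <- 0L
    while (!is.finite(state$lp) && tries < 100L) {
      state <- initialize_state(structure(list(), class = "pedigree_set"),
                                priors, cfg)
      state$lp <- log_post(state$current)
      tries <- tries + 1L
    }
    if (!is.finite(state$lp))
      stop(sprintf("chain %d: could not find a starting point with finite posterior", ch))
    trace <- matrix(NA_real_, cfg$n_iter, state$d, dimnames = list(NULL, nms))
    for (i in seq_len(cfg$n_iter)) {
      if (do_impute && i > 1L && (i - 1L) %% cfg$impute_every == 0L) {
        bl <- split_blocks(state$current, cfg)
        thf <- qblock_to_weibull(bl[[1]], cfg$max_age)
        thm <- qblock_to_weibull(bl[[length(bl)]], cfg$max_age)
        peds_ch <- reimpute(plan, peds_ch, thf, thm, gm, baseline)
        recompile_observations(env, peds_ch, baseline, cfg$age_imputation)
        state$lp <- log_post(state$current)
      }
      state <- mh_step(state, log_post)
      trace[i, ] <- state$current
    }
    chains[[ch]] <- trace
    acc[ch] <- state$accept / cfg$n_iter
  }
  retained <- lapply(chains, function(tr)
    tr[seq.int(n_burn + 1L, cfg$n_iter), , drop = FALSE])
  structure(list(chains = chains, retained = retained,
                 acceptance_rate = acc, n_burn = n_burn,
                 param_names = nms, config = cfg, subseeds = subseeds),
            class = "posterior_samples")
}

# refresh the compiled observation arrays after imputation (structure and
# member order are unchanged)
recompile_observations <- function(env, peds, baseline, age_imputation) {
  sexcode <- integer(0); ptype <- integer(0); page <- integer(0)
  for (p in peds) {
    pt <- ptype_of(p$is_aff, p$onset_age, p$cur_age, age_imputation)
    sexcode <- c(sexcode, match(p$sex, c("female", "male", "unknown")))
    ptype <- c(ptype, pt$ptype); page <- c(page, pt$page)
  }
  env$sexcode <- sexcode; env$ptype <- ptype; env$page <- page
  compile_baseline(env, baseline)
  invisible(env)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "posterior_samples: %d chain(s) x %d iterations (%d burn-in discarded per chain)\n",
    length(x$chains), nrow(x$chains[[1]]), x$n_burn))
  cat("acceptance rates:", paste(sprintf("%.3f", x$acceptance_rate), collapse = ", "), "\n")
  invisible(x)
}

#' Estimate penetrance from pedigree data
#'
#' The top-level estimation entry point: validates the families, optionally
#' applies proband removal (excluding proband-only singletons), and runs
#' the adaptive Metropolis chains.
#'
#' @param peds A `pedigree_set` from [parse_pedigrees()].
#' @param prevalence Carrier prevalence in the population, in (0, 1).
#' @param baseline A [baseline_risk()] object.
#' @param priors A [prior_set()] (default [default_priors()]).
#' @param cfg An [mcmc_config()].
#' @return A `posterior_samples` object; see [summarize_posterior()] and
#'   [mcmc_diagnostics()].
#' @export
estimate_penetrance <- function(peds, prevalence, baseline,
                                priors = default_priors(),
                                cfg = mcmc_config()) {
  peds <- prepare_families(peds, remove_proband = cfg$remove_proband)
  run_chains(peds, genotype_model(prevalence), baseline, priors, cfg)
}

#' Export retained posterior draws as a delimited table
#'
#' One row per retained draw with a `chain` column, columns named by
#' sex x parameter.
#'
#' @param samples A `posterior_samples` object.
#' @param file Output path (CSV).
#' @return `file`, invisibly.
#' @export
write_samples <- function(samples, file) {
  stopifnot(inherits(samples, "posterior_samples"))
  tabs <- lapply(seq_along(samples$retained), function(ch)
    cbind(data.frame(chain = ch), as.data.frame(samples$retained[[ch]])))
  write.csv(do.call(rbind, tabs), file, row.names = FALSE)
  invisible(file)
}
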