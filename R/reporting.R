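# Posterior summarization (penetrance curves with credible bands, parameter
# summaries in both parameterizations), convergence diagnostics, and
# dataset-level bookkeeping summaries.

#' Summarize posterior draws into penetrance curves and parameter tables
#'
#' Each retained draw is mapped through [quantiles_to_weibull()] and
#' [penetrance_cdf()] on the annual grid; pointwise means, medians and
#' equal-tailed credible bands are computed per sex, along with parameter
#' summaries in quantile space and in `(alpha, beta, gamma, delta)` space.
#'
#' @param samples A `posterior_samples` object.
#' @param levels Credible-band levels (default `c(0.5, 0.95)`); bands are
#'   nested by construction.
#' @param max_draws Cap on the number of pooled draws mapped to curves
#'   (deterministic thinning; `Inf` to use all).
#' @return An object of class `penetrance_summary`: per sex a data frame
#'   `age, mean, median, lower_<level>, upper_<level>` plus a parameter
#'   summary table.
#' @export
summarize_posterior <- function(samples, levels = c(0.5, 0.95),
                                max_draws = 4000) {
  stopifnot(inherits(samples, "posterior_samples"))
  draws <- do.call(rbind, samples$retained)
  if (nrow(draws) == 0L) stop("no retained draws to summarize")
  cfg <- samples$config
  if (nrow(draws) > max_draws) {
    keep <- unique(round(seq(1, nrow(draws), length.out = max_draws)))
    draws <- draws[keep, , drop = FALSE]
  }
  ages <- seq_len(cfg$max_age)
  sexes <- if (cfg$sex_specific) c("female", "male") else "all"
  qs <- sort(unique(c((1 - levels) / 2, 1 - (1 - levels) / 2, 0.5)))
  out <- list()
  params <- list()
  for (si in seq_along(sexes)) {
    cols <- if (cfg$sex_specific) (si - 1L) * 4L + 1:4 else 1:4
    blk <- draws[, cols, drop = FALSE]
    curves <- matrix(NA_real_, nrow(blk), length(ages))
    ab <- matrix(NA_real_, nrow(blk), 2, dimnames = list(NULL, c("alpha", "beta")))
    for (r in seq_len(nrow(blk))) {
      th <- qblock_to_weibull(blk[r, ], cfg$max_age)
      curves[r, ] <- penetrance_cdf(th, ages)
      ab[r, ] <- c(th$alpha, th$beta)
    }
    cm <- colMeans(curves)
    cq <- apply(curves, 2, quantile, probs = qs)
    tab <- data.frame(age = ages, mean = cm, median = cq["50%", ])
    for (lv in levels) {
      lo <- sprintf("%g%%", 100 * (1 - lv) / 2)
      hi <- sprintf("%g%%", 100 * (1 - (1 - lv) / 2))
      tab[[sprintf("lower_%g", lv)]] <- cq[lo, ]
      tab[[sprintf("upper_%g", lv)]] <- cq[hi, ]
    }
    pmat <- cbind(blk, ab)
    psum <- data.frame(
      parameter = colnames(pmat),
      mean = colMeans(pmat),
      median = apply(pmat, 2, median),
      q2.5 = apply(pmat, 2, quantile, probs = 0.025),
      q97.5 = apply(pmat, 2, quantile, probs = 0.975),
      row.names = NULL)
    out[[sexes[si]]] <- tab
    params[[sexes[si]]] <- psum
  }
  structure(list(curves = out, params = params, levels = levels,
                 n_draws = nrow(draws), sex_specific = cfg$sex_specific),
            class = "penetrance_summary")
}

#' @export
print.penetrance_summary <- function(x, ...) {
  cat(sprintf("penetrance_summary over %d draws (%s)\n", x$n_draws,
              if (x$sex_specific) "sex-specific" else "sex-shared"))
  for (s in names(x$params)) {
    cat("--", s, "--\n")
    print(x$params[[s]], digits = 3)
  }
  invisible(x)
}

#' Write the age-by-statistics penetrance summary table
#'
#' @param summary A `penetrance_summary`.
#' @param file Output path (CSV); one block per sex with a `sex` column.
#' @return `file`, invisibly.
#' @export
write_summary <- function(summary, file) {
  stopifnot(inherits(summary, "penetrance_summary"))
  tabs <- lapply(names(summary$curves), function(s)
    cbind(data.frame(sex = s), summary$curves[[s]]))
  write.csv(do.call(rbind, tabs), file, row.names = FALSE)
  invisible(file)
}

# ---- diagnostics ------------------------------------------------------------

# Geyer initial-positive-sequence effective sample size
ess_ips <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(NA_real_)
  rho <- acf(x, lag.max = min(n - 1L, 1000L), plot = FALSE)$acf[-1]
  s <- 0; k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  min(n, n / (1 + 2 * s))  # an iid chain cannot beat its own length
}

# split-chain potential scale reduction factor
split_rhat <- function(chains_mat) {
  halves <- list()
  for (m in chains_mat) {
    n2 <- floor(length(m) / 2)
    halves <- c(halves, list(m[1:n2]), list(m[(length(m) - n2 + 1):length(m)]))
  }
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[1:n])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

#' Convergence diagnostics for posterior samples
#'
#' Autocorrelation functions (biased estimator), effective sample sizes via
#' Geyer's initial-positive-sequence truncation, split-chain potential
#' scale reduction factors (requires at least 2 chains), and acceptance
#' rates.
#'
#' @param samples A `posterior_samples` object, or a list of numeric
#'   matrices (chains x (iterations x parameters)) for standalone use.
#' @param max_lag Largest lag tabulated in the ACF output.
#' @return An object of class `mcmc_diagnostics` with per-parameter `ess`,
#'   `rhat`, an `acf` table, and `acceptance_rate` when available.
#' @export
mcmc_diagnostics <- function(samples, max_lag = 50L) {
  if (inherits(samples, "posterior_samples")) {
    chains <- samples$retained
    acc <- samples$acceptance_rate
  } else {
    chains <- samples
    acc <- NULL
  }
  stopifnot(length(chains) >= 1L)
  pn <- colnames(chains[[1]])
  if (is.null(pn)) pn <- paste0("param", seq_len(ncol(chains[[1]])))
  ess <- setNames(numeric(length(pn)), pn)
  rhat <- setNames(rep(NA_real_, length(pn)), pn)
  acfs <- list()
  for (j in seq_along(pn)) {
    per_chain <- lapply(chains, function(m) m[, j])
    ess[j] <- sum(vapply(per_chain, ess_ips, 0), na.rm = TRUE)
    if (length(chains) >= 2L) rhat[j] <- split_rhat(per_chain)
    a <- acf(do.call(c, per_chain), lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
    acfs[[pn[j]]] <- data.frame(lag = seq_along(a) - 1L, acf = a)
  }
  structure(list(ess = ess, rhat = rhat, acf = acfs,
                 acceptance_rate = acc,
                 n_retained = sum(vapply(chains, nrow, 0L))),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat("mcmc_diagnostics:\n")
  tab <- data.frame(parameter = names(x$ess), ess = round(x$ess, 1),
                    rhat = round(x$rhat, 4))
  print(tab, row.names = FALSE)
  if (!is.null(x$acceptance_rate))
    cat("acceptance rates:", paste(sprintf("%.3f", x$acceptance_rate),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Write the per-parameter diagnostics table
#'
#' @param diag An `mcmc_diagnostics` object.
#' @param file Output path (CSV).
#' @return `file`, invisibly.
#' @export
write_diagnostics <- function(diag, file) {
  stopifnot(inherits(diag, "mcmc_diagnostics"))
  write.csv(data.frame(parameter = names(diag$ess), ess = diag$ess,
                       rhat = diag$rhat, row.names = NULL),
            file, row.names = FALSE)
  invisible(file)
}

# ---- dataset bookkeeping ----------------------------------------------------

#' Summary statistics of a family collection
#'
#' Bookkeeping counts used in study descriptions: number of families and
#' individuals, mean family size, diagnoses overall and by sex, observed
#' carriers, and probands.
#'
#' @param peds A `pedigree_set`.
#' @return A list of counts (class `pedigree_summary`).
#' @export
pedigree_summary <- function(peds) {
  stopifnot(inherits(peds, "pedigree_set"))
  all <- do.call(rbind, lapply(peds, as.data.frame))
  structure(list(
    n_families = length(peds),
    n_individuals = nrow(all),
    mean_family_size = nrow(all) / length(peds),
    n_affected = sum(all$is_aff == "affected"),
    n_affected_female = sum(all$is_aff == "affected" & all$sex == "female"),
    n_affected_male = sum(all$is_aff == "affected" & all$sex == "male"),
    n_carriers_observed = sum(all$geno == "carrier"),
    n_probands = sum(all$is_proband)
  ), class = "pedigree_summary")
}

#' @export
print.pedigree_summary <- function(x, ...) {
  cat(sprintf(
    "%d families, %d individuals (mean family size %.1f)\n%d diagnoses (%d female, %d male); %d observed carriers; %d probands\n",
    x$n_families, x$n_individuals, x$mean_family_size, x$n_affected,
    x$n_affected_female, x$n_affected_male, x$n_carriers_observed,
    x$n_probands))
  invisible(x)
}
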