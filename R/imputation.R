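# Optional in-chain imputation of missing onset and censoring ages.
# Re-imputation draws onset ages from the carrier-posterior-weighted mixture
# of the current carrier onset distribution and the noncarrier baseline,
# truncated to the individual's feasible age window. This is an
# approximation: the age draw carries no Metropolis-within-Gibbs correction.

#' Enumerate individuals whose ages need imputation
#'
#' Targets are affected members missing their onset age and any member
#' missing the censoring age; members with unknown affection status and
#' missing ages are censoring-age targets.
#'
#' @param peds A `pedigree_set`.
#' @return An `imputation_plan`: a list with a `targets` data frame
#'   (`family_idx, family_id, individual_id, which, is_aff, sex`).
#' @export
build_plan <- function(peds) {
  stopifnot(inherits(peds, "pedigree_set"))
  rows <- list()
  for (fi in seq_along(peds)) {
    p <- peds[[fi]]
    for (i in seq_len(nrow(p))) {
      if (p$is_aff[i] == "affected" && is.na(p$onset_age[i]))
        rows[[length(rows) + 1L]] <- data.frame(
          family_idx = fi, family_id = p$pedigree_id[1], individual_id = p$id[i],
          which = "onset", is_aff = p$is_aff[i], sex = p$sex[i],
          stringsAsFactors = FALSE)
      if (is.na(p$cur_age[i]))
        rows[[length(rows) + 1L]] <- data.frame(
          family_idx = fi, family_id = p$pedigree_id[1], individual_id = p$id[i],
          which = "censoring", is_aff = p$is_aff[i], sex = p$sex[i],
          stringsAsFactors = FALSE)
    }
  }
  targets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_idx = integer(0), family_id = character(0),
               individual_id = character(0), which = character(0),
               is_aff = character(0), sex = character(0),
               stringsAsFactors = FALSE)
  structure(list(targets = targets), class = "imputation_plan")
}

# empirical onset pool for a sex stratum (affected members, observed onset)
onset_pool <- function(peds, sex) {
  out <- integer(0)
  for (p in peds) {
    keep <- p$is_aff == "affected" & !is.na(p$onset_age) &
      (p$sex == sex | sex == "unknown")
    out <- c(out, p$onset_age[keep])
  }
  out
}

# sample one onset age from an annual onset-probability vector restricted to
# [lo, hi]; returns NA when the window carries no mass
draw_from_dens <- function(dens, lo, hi) {
  lo <- max(1L, lo); hi <- min(length(dens), hi)
  if (hi < lo) return(NA_integer_)
  w <- dens[lo:hi]
  if (sum(w) <= 0) return(NA_integer_)
  (lo:hi)[sample.int(hi - lo + 1L, 1L, prob = w)]
}

# mixture draw used by reimpute: carrier weight w, per-class densities
draw_onset_age <- function(w, dens_car, dens_nc, lo, hi) {
  if (runif(1) < w) draw_from_dens(dens_car, lo, hi)
  else draw_from_dens(dens_nc, lo, hi)
}

#' Fill missing ages before the chains start
#'
#' Missing onset ages are drawn from the empirical distribution of observed
#' onset ages in the same sex stratum (with an integer jitter of up to
#' plus/minus 2 years, clamped to the feasible window), falling back to the
#' baseline-risk onset distribution when the stratum is empty. Missing
#' censoring ages are drawn uniformly from `[20, max_age]` (respecting any
#' observed onset age). All filled ages satisfy onset <= censoring.
#'
#' @param plan An `imputation_plan` from [build_plan()].
#' @param peds The `pedigree_set` the plan was built from.
#' @param baseline A [baseline_risk()] object.
#' @return The `pedigree_set` with ages filled.
#' @export
initial_impute <- function(plan, peds, baseline) {
  stopifnot(inherits(plan, "imputation_plan"), inherits(peds, "pedigree_set"))
  tg <- plan$targets
  if (nrow(tg) == 0L) return(peds)
  max_age <- baseline$max_age
  bd <- baseline_annual_onset(baseline)
  # censoring ages first so onset windows are known
  for (r in order(tg$which != "censoring")) {
    fi <- tg$family_idx[r]
    p <- peds[[fi]]
    i <- match(tg$individual_id[r], p$id)
    if (tg$which[r] == "censoring") {
      lo <- max(20L, p$onset_age[i], 1L, na.rm = TRUE)
      p$cur_age[i] <- if (lo >= max_age) max_age else
        sample(lo:max_age, 1L)
    } else {
      hi <- min(p$cur_age[i], max_age, na.rm = TRUE)
      pool <- onset_pool(peds, p$sex[i])
      pool <- pool[pool <= hi]
      if (length(pool)) {
        a <- pool[sample.int(length(pool), 1L)] + sample(-2:2, 1L)
        p$onset_age[i] <- min(max(a, 1L), hi)
      } else {
        dens <- switch(p$sex[i], female = bd$female, male = bd$male,
                       (bd$female + bd$male) / 2)
        a <- draw_from_dens(dens, 1L, hi)
        p$onset_age[i] <- if (is.na(a)) max(1L, hi %/% 2L) else a
      }
    }
    peds[[fi]] <- p
  }
  peds
}

#' Re-impute missing ages under the current parameters
#'
#' For each onset target the carrier posterior `w` of the individual given
#' all family data is computed under the current carrier parameters; the
#' onset age is then drawn from the mixture `w` x (carrier onset
#' distribution) + `(1 - w)` x (baseline onset distribution), truncated to
#' the feasible window. Censoring targets are redrawn uniformly on their
#' feasible window. A zero-mass window keeps the previous value with a
#' warning.
#'
#' @param plan An `imputation_plan`.
#' @param peds The current `pedigree_set` (ages previously filled).
#' @param theta_female,theta_male Current carrier [weibull_params()].
#' @param gm A [genotype_model()].
#' @param baseline A [baseline_risk()] object.
#' @return The `pedigree_set` with target ages re-drawn.
#' @export
reimpute <- function(plan, peds, theta_female, theta_male, gm, baseline) {
  stopifnot(inherits(plan, "imputation_plan"))
  tg <- plan$targets
  if (nrow(tg) == 0L) return(peds)
  max_age <- baseline$max_age
  pen <- penetrance_set(theta_female, theta_male, baseline)
  for (r in seq_len(nrow(tg))) {
    fi <- tg$family_idx[r]
    p <- peds[[fi]]
    i <- match(tg$individual_id[r], p$id)
    if (tg$which[r] == "censoring") {
      lo <- max(20L, p$onset_age[i], 1L, na.rm = TRUE)
      if (lo >= max_age) { p$cur_age[i] <- max_age }
      else p$cur_age[i] <- sample(lo:max_age, 1L)
    } else {
      hi <- min(p$cur_age[i], max_age, na.rm = TRUE)
      # mask this onset before computing the carrier posterior so the
      # previous imputed value does not feed back
      pm <- p; pm$onset_age[i] <- NA_integer_; pm$is_aff[i] <- "unknown"
      w <- carrier_posterior(pm, gm, pen, p$id[i])
      dc <- switch(p$sex[i], female = pen$dens$carrier$female,
                   male = pen$dens$carrier$male,
                   (pen$dens$carrier$female + pen$dens$carrier$male) / 2)
      dn <- switch(p$sex[i], female = pen$dens$noncarrier$female,
                   male = pen$dens$noncarrier$male,
                   (pen$dens$noncarrier$female + pen$dens$noncarrier$male) / 2)
      a <- draw_onset_age(w, dc, dn, 1L, hi)
      if (is.na(a)) {
        warning(sprintf("family %s, individual %s: zero-mass onset window; keeping previous value",
                        tg$family_id[r], tg$individual_id[r]))
      } else p$onset_age[i] <- a
    }
    peds[[fi]] <- p
  }
  peds
}
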