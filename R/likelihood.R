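# Pedigree likelihood for a single biallelic autosomal locus. Genotypes are
# coded 0 = aa (noncarrier), 1 = Aa, 2 = AA; Aa and AA share the carrier
# penetrance (dominant model) but stay distinct states for Mendelian
# transmission. Peeling itself lives in src/peel.cpp.

#' Genetic model for a single biallelic locus
#'
#' From the carrier prevalence the risk-allele frequency is
#' `f = 1 - sqrt(1 - prevalence)`, so that under Hardy-Weinberg equilibrium
#' the founder carrier probability `2f(1-f) + f^2` equals the prevalence
#' exactly.
#'
#' @param prevalence Carrier prevalence in the founder population, in (0, 1).
#' @return An object of class `genotype_model` with `allele_freq`,
#'   `founder_probs` (aa, Aa, AA) and `prevalence`.
#' @export
genotype_model <- function(prevalence) {
  probs <- founder_genotype_probs(prevalence)
  structure(list(allele_freq = 1 - sqrt(1 - prevalence),
                 founder_probs = probs, prevalence = prevalence),
            class = "genotype_model")
}

#' Founder genotype probabilities under Hardy-Weinberg equilibrium
#'
#' @inheritParams genotype_model
#' @return Numeric 3-vector `(aa, Aa, AA)` summing to 1, with
#'   `Aa + AA = prevalence` exactly.
#' @export
founder_genotype_probs <- function(prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      !is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be a single number in (0, 1)")
  f <- 1 - sqrt(1 - prevalence)
  c(aa = (1 - f)^2, Aa = 2 * f * (1 - f), AA = f^2)
}

#' Mendelian transmission array
#'
#' `P(child genotype | mother genotype, father genotype)` for a biallelic
#' autosomal locus: each parent transmits the risk allele with probability
#' `g/2` where `g` is the parent's risk-allele count.
#'
#' @return A 3x3x3 array with dimensions (child, mother, father), each
#'   child-column summing to 1.
#' @export
transmission_matrix <- function() {
  tr <- array(0, dim = c(3, 3, 3),
              dimnames = list(child = c("aa", "Aa", "AA"),
                              mother = c("aa", "Aa", "AA"),
                              father = c("aa", "Aa", "AA")))
  for (m in 0:2) for (f in 0:2) {
    pm <- m / 2; pf <- f / 2
    tr[1, m + 1, f + 1] <- (1 - pm) * (1 - pf)
    tr[2, m + 1, f + 1] <- pm * (1 - pf) + (1 - pm) * pf
    tr[3, m + 1, f + 1] <- pm * pf
  }
  tr
}

#' Per-sex, per-class penetrance vectors on the annual grid
#'
#' Bundles the carrier (modified Weibull) and noncarrier (baseline) annual
#' onset and cumulative-risk vectors used by the likelihood. The carrier
#' class is shared by genotypes Aa and AA.
#'
#' @param theta_female Carrier [weibull_params()] for females.
#' @param theta_male Carrier parameters for males (defaults to the female
#'   parameters, i.e. a sex-shared model).
#' @param baseline A [baseline_risk()] object for noncarriers.
#' @return An object of class `penetrance_set` with per-sex onset densities
#'   (`dens`) and cumulative risks (`cum`) for classes `carrier` and
#'   `noncarrier`.
#' @export
penetrance_set <- function(theta_female, theta_male = theta_female, baseline) {
  stopifnot(inherits(theta_female, "weibull_params"),
            inherits(theta_male, "weibull_params"),
            inherits(baseline, "baseline_risk"))
  max_age <- baseline$max_age
  if (theta_female$max_age != max_age || theta_male$max_age != max_age)
    stop("theta and baseline must share max_age")
  cf <- penetrance_cdf(theta_female, seq_len(max_age))
  cm <- penetrance_cdf(theta_male, seq_len(max_age))
  structure(list(
    dens = list(carrier = list(female = diff(c(0, cf)), male = diff(c(0, cm))),
                noncarrier = baseline_annual_onset(baseline)),
    cum = list(carrier = list(female = cf, male = cm),
               noncarrier = list(female = baseline$female, male = baseline$male)),
    max_age = max_age), class = "penetrance_set")
}

# phenotype-observation codes used by the compiled representation:
#   1 affected with onset age; 2 unaffected with censoring age; 3 unknown;
#   4 affected with onset age missing but censoring age observed
PTYPE_AFF <- 1L; PTYPE_UNAFF <- 2L; PTYPE_UNKNOWN <- 3L; PTYPE_AFF_CENS <- 4L

ptype_of <- function(is_aff, onset_age, cur_age, age_imputation = FALSE) {
  n <- length(is_aff)
  out <- integer(n); age <- integer(n)
  for (i in seq_len(n)) {
    if (is_aff[i] == "affected") {
      if (!is.na(onset_age[i])) { out[i] <- PTYPE_AFF; age[i] <- onset_age[i] }
      else if (!is.na(cur_age[i])) { out[i] <- PTYPE_AFF_CENS; age[i] <- cur_age[i] }
      else if (age_imputation) { out[i] <- PTYPE_UNKNOWN; age[i] <- NA_integer_ }
      else stop("affected individual with both ages missing; enable age_imputation ",
                "to impute missing ages during estimation")
    } else if (is_aff[i] == "unaffected") {
      if (!is.na(cur_age[i])) { out[i] <- PTYPE_UNAFF; age[i] <- cur_age[i] }
      else if (age_imputation) { out[i] <- PTYPE_UNKNOWN; age[i] <- NA_integer_ }
      else { out[i] <- PTYPE_UNKNOWN; age[i] <- NA_integer_ }
    } else {
      if (!is.na(cur_age[i])) { out[i] <- PTYPE_UNAFF; age[i] <- cur_age[i] }
      else { out[i] <- PTYPE_UNKNOWN; age[i] <- NA_integer_ }
    }
  }
  list(ptype = out, page = age)
}

# per-class value of each phenotype observation, vectorized (hot path)
pheno_value <- function(ptype, page, sexcode, dens_f, dens_m, cum_f, cum_m) {
  n <- length(ptype)
  vf <- rep(1, n); vm <- rep(1, n)
  i1 <- ptype == PTYPE_AFF; i2 <- ptype == PTYPE_UNAFF; i4 <- ptype == PTYPE_AFF_CENS
  vf[i1] <- dens_f[page[i1]];     vm[i1] <- dens_m[page[i1]]
  vf[i2] <- 1 - cum_f[page[i2]];  vm[i2] <- 1 - cum_m[page[i2]]
  vf[i4] <- cum_f[page[i4]];      vm[i4] <- cum_m[page[i4]]
  val <- vf
  m <- sexcode == 2L; u <- sexcode == 3L
  val[m] <- vm[m]
  val[u] <- (vf[u] + vm[u]) / 2
  val
}

# flattened transmission array for the C++ engine, built once at load
trans_vec <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- as.numeric(transmission_matrix())
    cache
  }
})

#' Per-genotype phenotype likelihood for one individual
#'
#' The 3-vector `(aa, Aa, AA)` entering the pedigree likelihood: an affected
#' individual with onset age `a` contributes the annual onset probability at
#' `a` for the genotype's class and the individual's sex; an unaffected (or
#' unknown-status) individual censored at `c` contributes `1 - F(c)`; a
#' fully unobserved phenotype contributes 1. An observed genotype multiplies
#' in an indicator (carrier zeroes the `aa` entry; noncarrier zeroes `Aa`
#' and `AA`). Unknown sex averages the female and male values. An affected
#' individual whose onset age is missing but whose censoring age is known
#' contributes `F(c)` (diagnosed at an unknown age before censoring).
#'
#' @param ind A one-row `pedigree` data frame (or list with the same
#'   fields).
#' @param pen A [penetrance_set()].
#' @return Named numeric 3-vector `(aa, Aa, AA)`.
#' @export
phenotype_likelihood <- function(ind, pen) {
  stopifnot(inherits(pen, "penetrance_set"))
  pt <- ptype_of(ind$is_aff, ind$onset_age, ind$cur_age)
  sexcode <- match(ind$sex, c("female", "male", "unknown"))
  car <- pheno_value(pt$ptype, pt$page, sexcode,
                     pen$dens$carrier$female, pen$dens$carrier$male,
                     pen$cum$carrier$female, pen$cum$carrier$male)
  nc <- pheno_value(pt$ptype, pt$page, sexcode,
                    pen$dens$noncarrier$female, pen$dens$noncarrier$male,
                    pen$cum$noncarrier$female, pen$cum$noncarrier$male)
  v <- c(aa = nc, Aa = car, AA = car)
  if (ind$geno == "carrier") v["aa"] <- 0
  if (ind$geno == "noncarrier") v[c("Aa", "AA")] <- 0
  v
}

# ---- compiled representation ------------------------------------------------

# min-degree elimination order on the moral graph (child-mother-father
# triangles); quality of the order only affects speed, not correctness
peel_order <- function(mother, father) {
  n <- length(mother)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (is.na(mother[i])) next
    m <- mother[i]; f <- father[i]
    A[i, m] <- A[m, i] <- TRUE
    A[i, f] <- A[f, i] <- TRUE
    A[m, f] <- A[f, m] <- TRUE
  }
  alive <- rep(TRUE, n)
  ord <- integer(n)
  for (k in seq_len(n)) {
    deg <- rowSums(A[, alive, drop = FALSE]) - !alive  # degrees among alive
    deg[!alive] <- Inf
    v <- which.min(deg)
    nb <- which(A[v, ] & alive)
    nb <- setdiff(nb, v)
    if (length(nb) > 1) A[nb, nb] <- TRUE  # fill-in
    alive[v] <- FALSE
    A[v, ] <- FALSE; A[, v] <- FALSE
    ord[k] <- v
  }
  ord
}

# Compile a pedigree set for repeated likelihood evaluation: per-family
# structure (0-based indices + elimination order for the C++ engine) and
# flat per-member observation arrays. Returned as an environment so the
# imputation hook can update ages in place.
compile_peds <- function(peds, max_age = 94, age_imputation = FALSE) {
  stopifnot(inherits(peds, "pedigree_set"))
  env <- new.env(parent = emptyenv())
  env$max_age <- as.integer(max_age)
  structs <- vector("list", length(peds))
  sexcode <- integer(0); ptype <- integer(0); page <- integer(0); genoc <- integer(0)
  fam_of <- integer(0); loc_of <- integer(0)
  offset <- 0L
  for (fi in seq_along(peds)) {
    p <- peds[[fi]]
    n <- nrow(p)
    mo <- match(p$mother_id, p$id); fa <- match(p$father_id, p$id)
    structs[[fi]] <- list(
      rows = offset + seq_len(n) - 1L,
      mother = ifelse(is.na(mo), -1L, mo - 1L),
      father = ifelse(is.na(fa), -1L, fa - 1L),
      order = peel_order(mo, fa) - 1L
    )
    pt <- ptype_of(p$is_aff, p$onset_age, p$cur_age, age_imputation)
    sexcode <- c(sexcode, match(p$sex, c("female", "male", "unknown")))
    ptype <- c(ptype, pt$ptype); page <- c(page, pt$page)
    genoc <- c(genoc, match(p$geno, c("unknown", "carrier", "noncarrier")) - 1L)
    fam_of <- c(fam_of, rep(fi, n)); loc_of <- c(loc_of, seq_len(n))
    offset <- offset + n
  }
  env$structs <- structs
  env$n_members <- offset
  env$sexcode <- sexcode; env$ptype <- ptype; env$page <- page
  env$geno <- genoc; env$fam_of <- fam_of; env$loc_of <- loc_of
  env$family_ids <- vapply(peds, function(p) p$pedigree_id[1], "")
  env
}

# attach baseline-driven (noncarrier) phenotype values; constant across theta
compile_baseline <- function(env, baseline) {
  bd <- baseline_annual_onset(baseline)
  env$nc_val <- pheno_value(env$ptype, env$page, env$sexcode,
                            bd$female, bd$male, baseline$female, baseline$male)
  invisible(env)
}

# N x 3 phenotype matrix for the current carrier penetrance
build_pheno <- function(env, pen) {
  car <- pheno_value(env$ptype, env$page, env$sexcode,
                     pen$dens$carrier$female, pen$dens$carrier$male,
                     pen$cum$carrier$female, pen$cum$carrier$male)
  ph <- cbind(env$nc_val, car, car)
  ph[env$geno == 1L, 1L] <- 0
  ph[env$geno == 2L, 2:3] <- 0
  ph
}

# total log-likelihood of a compiled pedigree set
loglik_compiled <- function(env, gm, pen) {
  ph <- build_pheno(env, pen)
  sum(peel_families_cpp(env$structs, ph, gm$founder_probs, trans_vec()))
}

# ---- user-facing likelihood operations --------------------------------------

#' Pedigree log-likelihood by Elston-Stewart peeling
#'
#' Log of the sum, over all genotype configurations, of founder priors times
#' Mendelian transmissions times per-individual phenotype likelihoods,
#' computed by peeling (variable elimination) in time linear in family size
#' for loop-free pedigrees. Looped pedigrees are rejected. Data of
#' probability zero yield `-Inf` with a warning.
#'
#' @param p A `pedigree` (single family).
#' @param gm A [genotype_model()].
#' @param pen A [penetrance_set()].
#' @return Log-likelihood (scalar).
#' @seealso [brute_force_loglikelihood()] for the enumeration oracle.
#' @export
peel_loglikelihood <- function(p, gm, pen) {
  stopifnot(inherits(p, "pedigree"), inherits(gm, "genotype_model"),
            inherits(pen, "penetrance_set"))
  if (length(detect_loops(p)))
    stop(sprintf("family %s contains marriage/inbreeding loop(s); peeling supports loop-free pedigrees only",
                 p$pedigree_id[1]))
  env <- compile_peds(structure(list(p), class = "pedigree_set"),
                      max_age = pen$max_age)
  compile_baseline(env, baseline_from_pen(pen))
  ll <- loglik_compiled(env, gm, pen)
  if (!is.finite(ll))
    warning(sprintf("family %s: observed data have probability zero", p$pedigree_id[1]))
  ll
}

# recover a baseline_risk view from a penetrance_set (for standalone calls)
baseline_from_pen <- function(pen) {
  baseline_risk(pen$cum$noncarrier$female, pen$cum$noncarrier$male,
                max_age = pen$max_age)
}

#' Pedigree log-likelihood by explicit genotype enumeration
#'
#' Test oracle for the peeling engine: sums over all `3^n` genotype
#' assignments directly. Refuses families above 15 members.
#'
#' @inheritParams peel_loglikelihood
#' @return Log-likelihood (scalar), `-Inf` for impossible data.
#' @export
brute_force_loglikelihood <- function(p, gm, pen) {
  stopifnot(inherits(p, "pedigree"))
  n <- nrow(p)
  if (n > 15L) stop("brute-force enumeration refuses families above 15 members")
  ph <- t(vapply(seq_len(n), function(i) phenotype_likelihood(p[i, ], pen),
                 numeric(3)))
  mo <- match(p$mother_id, p$id); fa <- match(p$father_id, p$id)
  tr <- transmission_matrix()
  fp <- gm$founder_probs
  total <- 3^n
  cfg <- seq_len(total) - 1L
  gcol <- function(i) (cfg %/% 3L^(i - 1L)) %% 3L
  pr <- rep(1, total)
  for (i in seq_len(n)) {
    gi <- gcol(i)
    w <- ph[i, gi + 1L]
    if (is.na(mo[i])) w <- w * fp[gi + 1L]
    else w <- w * tr[cbind(gi + 1L, gcol(mo[i]) + 1L, gcol(fa[i]) + 1L)]
    pr <- pr * w
  }
  log(sum(pr))
}

#' Posterior carrier probability for one family member
#'
#' `P(individual carries the risk allele | all family data)`, computed by
#' restricting the individual's genotype to the carrier states `{Aa, AA}`
#' in a second peeling pass.
#'
#' @inheritParams peel_loglikelihood
#' @param individual_id The member's `ID` within the family.
#' @return Probability in `[0, 1]`.
#' @export
carrier_posterior <- function(p, gm, pen, individual_id) {
  stopifnot(inherits(p, "pedigree"))
  i <- match(as.character(individual_id), p$id)
  if (is.na(i)) stop(sprintf("individual '%s' not found in family %s",
                             individual_id, p$pedigree_id[1]))
  if (length(detect_loops(p)))
    stop("carrier_posterior requires a loop-free pedigree")
  env <- compile_peds(structure(list(p), class = "pedigree_set"),
                      max_age = pen$max_age)
  compile_baseline(env, baseline_from_pen(pen))
  ph <- build_pheno(env, pen)
  tr <- as.numeric(transmission_matrix())
  ll_all <- peel_families_cpp(env$structs, ph, gm$founder_probs, tr)
  if (!is.finite(ll_all)) stop("family data have probability zero")
  ph[i, 1L] <- 0  # restrict to carrier states
  ll_car <- peel_families_cpp(env$structs, ph, gm$founder_probs, tr)
  min(1, max(0, exp(ll_car - ll_all)))
}
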