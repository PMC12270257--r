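# Synthetic family studies with known ground truth, mirroring a
# carrier-proband ascertainment design: three generations around the
# proband (grandparents, parents with siblings and their spouses/children,
# proband siblings/spouse/children), founder genotypes from Hardy-Weinberg,
# Mendelian transmission, and onset ages from the carrier or baseline
# annual onset distributions.

#' Simulation design
#'
#' Defaults emulate a Lynch-syndrome-like study of a mismatch-repair gene:
#' rare carrier prevalence, colorectal-cancer-like baseline, carrier onset
#' concentrated between ages 35 and 65, and sibship-size distributions
#' tuned so the expected family size is about 35 (see
#' [expected_family_size()]).
#'
#' @param n_probands Number of ascertained families.
#' @param prevalence Carrier prevalence in (0, 1).
#' @param theta_female,theta_male True carrier [weibull_params()].
#' @param baseline A [baseline_risk()] for noncarriers.
#' @param lambda_sibs,lambda_aunts,lambda_cousins,lambda_nieces,lambda_children
#'   Poisson means: proband siblings; aunts/uncles per parental side;
#'   children per aunt/uncle; children per proband sibling; proband
#'   children. Spouses of a relative enter the family only when that
#'   relative has children.
#' @param censoring_mean,censoring_sd Named numeric vectors (by generation
#'   `"3"` grandparents, `"2"` parents' generation, `"1"` proband's
#'   generation, `"0"` children) for the Gaussian censoring-age draw
#'   (rounded, clamped to `[1, max_age]`).
#' @param geno_obs_rate Probability that a non-proband relative's genotype
#'   is observed (default 0: the proband is the only genotyped member).
#' @param condition_proband_carrier Rejection-sample genotypes until the
#'   proband carries the risk allele (the ascertainment condition).
#' @param require_proband_affected Additionally redraw the proband's
#'   phenotype until affected (off by default).
#' @param seed Seed stored with the design (used by [simulate_study()]).
#' @param max_age Age-grid upper bound.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_probands = 130L,
                       prevalence = 5e-4,
                       theta_female = quantiles_to_weibull(
                         quantile_params(40, 50, 0.5, 20, max_age = max_age)),
                       theta_male = quantiles_to_weibull(
                         quantile_params(38, 48, 0.6, 18, max_age = max_age)),
                       baseline = default_baseline(max_age),
                       lambda_sibs = 2, lambda_aunts = 2.8,
                       lambda_cousins = 1.5, lambda_nieces = 1.5,
                       lambda_children = 2,
                       censoring_mean = c("3" = 82, "2" = 70, "1" = 57, "0" = 32),
                       censoring_sd = c("3" = 8, "2" = 8, "1" = 10, "0" = 8),
                       geno_obs_rate = 0,
                       condition_proband_carrier = TRUE,
                       require_proband_affected = FALSE,
                       seed = 1L, max_age = 94L) {
  stopifnot(prevalence > 0, prevalence < 1, n_probands >= 1,
            all(c(lambda_sibs, lambda_aunts, lambda_cousins,
                  lambda_nieces, lambda_children) >= 0),
            geno_obs_rate >= 0, geno_obs_rate <= 1)
  structure(list(n_probands = as.integer(n_probands), prevalence = prevalence,
                 theta_female = theta_female, theta_male = theta_male,
                 baseline = baseline,
                 lambda_sibs = lambda_sibs, lambda_aunts = lambda_aunts,
                 lambda_cousins = lambda_cousins, lambda_nieces = lambda_nieces,
                 lambda_children = lambda_children,
                 censoring_mean = censoring_mean, censoring_sd = censoring_sd,
                 geno_obs_rate = geno_obs_rate,
                 condition_proband_carrier = isTRUE(condition_proband_carrier),
                 require_proband_affected = isTRUE(require_proband_affected),
                 seed = seed, max_age = as.integer(max_age)),
            class = "sim_design")
}

#' Analytic expected family size of a design
#'
#' Closed form from the composition of the design's Poisson counts: 7 core
#' members (proband, parents, grandparents) plus aunts/uncles with their
#' conditional spouses and children, proband siblings likewise, and the
#' proband's spouse and children.
#'
#' @param design A [sim_design()].
#' @return Expected number of members per family.
#' @export
expected_family_size <- function(design) {
  sp <- function(lam) 1 - exp(-lam)  # P(at least one child) => spouse present
  7 +
    2 * design$lambda_aunts * (1 + sp(design$lambda_cousins) + design$lambda_cousins) +
    design$lambda_sibs * (1 + sp(design$lambda_nieces) + design$lambda_nieces) +
    sp(design$lambda_children) + design$lambda_children
}

# ---- structure --------------------------------------------------------------

# builder closure collecting member rows; parents always precede children
new_family_builder <- function(fam_id, max_age) {
  rows <- list()
  nid <- 0L
  add <- function(sex, mother = NA_character_, father = NA_character_,
                  proband = FALSE, gen = 1L) {
    nid <<- nid + 1L
    id <- as.character(nid)
    rows[[nid]] <<- data.frame(
      pedigree_id = fam_id, id = id, sex = sex,
      mother_id = mother, father_id = father, is_proband = proband,
      cur_age = NA_integer_, is_aff = "unknown", onset_age = NA_integer_,
      geno = "unknown", gen = gen, stringsAsFactors = FALSE)
    id
  }
  finish <- function() {
    p <- do.call(rbind, rows)
    rownames(p) <- NULL
    attr(p, "max_age") <- as.integer(max_age)
    class(p) <- c("pedigree", "data.frame")
    p
  }
  list(add = add, finish = finish)
}

rsex <- function(n = 1L) sample(c("female", "male"), n, replace = TRUE)

# attach a spouse + children block under (person, side-parents context)
add_offspring <- function(b, person_id, person_sex, n_children, child_gen) {
  if (n_children == 0L) return(invisible(NULL))
  spouse_sex <- if (person_sex == "female") "male" else "female"
  spouse <- b$add(spouse_sex, gen = child_gen + 1L)
  mo <- if (person_sex == "female") person_id else spouse
  fa <- if (person_sex == "female") spouse else person_id
  for (k in seq_len(n_children)) b$add(rsex(), mother = mo, father = fa, gen = child_gen)
  invisible(NULL)
}

#' Simulate one family's pedigree skeleton
#'
#' Three generations around the proband: grandparents, parents, paternal
#' and maternal aunts/uncles (with spouses and children when they have
#' any), proband siblings (likewise), and the proband's spouse and
#' children. Sizes are drawn from the design's Poisson distributions. The
#' result is loop-free by construction; phenotype, age, and genotype
#' columns are left unobserved.
#'
#' @param design A [sim_design()].
#' @param fam_id Family identifier.
#' @return A `pedigree` skeleton (with an internal `gen` column).
#' @export
simulate_structure <- function(design, fam_id = "1") {
  b <- new_family_builder(fam_id, design$max_age)
  pgf <- b$add("male", gen = 3L);  pgm <- b$add("female", gen = 3L)
  mgf <- b$add("male", gen = 3L);  mgm <- b$add("female", gen = 3L)
  father <- b$add("male", mother = pgm, father = pgf, gen = 2L)
  mother <- b$add("female", mother = mgm, father = mgf, gen = 2L)
  proband_sex <- rsex()
  proband <- b$add(proband_sex, mother = mother, father = father,
                   proband = TRUE, gen = 1L)
  for (side in list(c(pgm, pgf), c(mgm, mgf))) {
    for (a in seq_len(rpois(1L, design$lambda_aunts))) {
      asex <- rsex()
      aid <- b$add(asex, mother = side[1], father = side[2], gen = 2L)
      add_offspring(b, aid, asex, rpois(1L, design$lambda_cousins), child_gen = 1L)
    }
  }
  for (s in seq_len(rpois(1L, design$lambda_sibs))) {
    ssex <- rsex()
    sid <- b$add(ssex, mother = mother, father = father, gen = 1L)
    add_offspring(b, sid, ssex, rpois(1L, design$lambda_nieces), child_gen = 0L)
  }
  add_offspring(b, proband, proband_sex, rpois(1L, design$lambda_children),
                child_gen = 0L)
  b$finish()
}

# ---- genotypes --------------------------------------------------------------

# risk-allele count of a child given parental counts
child_gcount <- function(gm, gf) rbinom(length(gm), 1L, gm / 2) + rbinom(length(gf), 1L, gf / 2)

# Rejection sampling of the proband's ancestor core (4 grandparents ->
# 2 parents -> proband) until the proband carries the risk allele; the rest
# of the family is then drawn forward conditionally, which is equivalent to
# whole-family rejection but feasible at rare prevalences.
sample_core_conditioned <- function(fp, batch = 4096L, max_batches = 4096L) {
  for (b in seq_len(max_batches)) {
    g <- matrix(sample.int(3L, 4L * batch, replace = TRUE, prob = fp) - 1L,
                nrow = batch)
    fa <- child_gcount(g[, 1], g[, 2])
    mo <- child_gcount(g[, 3], g[, 4])
    pr <- child_gcount(mo, fa)
    hit <- which(pr >= 1L)
    if (length(hit)) {
      h <- hit[1]
      return(list(gp = g[h, ], father = fa[h], mother = mo[h], proband = pr[h]))
    }
  }
  stop("ascertainment rejection sampling failed; prevalence too small?")
}

#' Assign genotypes to a family skeleton
#'
#' Founders draw from Hardy-Weinberg at the design prevalence; children
#' follow Mendelian transmission. Under the default ascertainment condition
#' the draw is rejection-resampled until the proband is a carrier. The
#' observed `geno` column is set to `carrier` for the proband and left
#' unknown for relatives except a `geno_obs_rate` fraction; the true
#' risk-allele counts are stored in the internal `gcount` column.
#'
#' @param ped A skeleton from [simulate_structure()].
#' @param design A [sim_design()].
#' @return The `pedigree` with `gcount` and observed `geno` filled.
#' @export
drop_genotypes <- function(ped, design) {
  fp <- founder_genotype_probs(design$prevalence)
  n <- nrow(ped)
  mo <- match(ped$mother_id, ped$id); fa <- match(ped$father_id, ped$id)
  g <- rep(NA_integer_, n)
  pro <- which(ped$is_proband)[1]
  if (design$condition_proband_carrier) {
    core <- sample_core_conditioned(fp)
    g[1:4] <- core$gp  # grandparents are members 1..4 by construction
    g[5] <- core$father; g[6] <- core$mother; g[pro] <- core$proband
  }
  for (i in seq_len(n)) {
    if (!is.na(g[i])) next
    g[i] <- if (is.na(mo[i])) sample.int(3L, 1L, prob = fp) - 1L
            else child_gcount(g[mo[i]], g[fa[i]])
  }
  ped$gcount <- g
  ped$geno <- "unknown"
  obs <- runif(n) < design$geno_obs_rate
  obs[pro] <- TRUE
  ped$geno[obs] <- ifelse(g[obs] >= 1L, "carrier", "noncarrier")
  ped
}

# ---- phenotypes -------------------------------------------------------------

# inverse-CDF draw of an onset age from a cumulative vector; NA = never
draw_onset_from_cum <- function(cum) {
  u <- runif(1)
  if (u > cum[length(cum)]) return(NA_integer_)
  findInterval(u, cum, left.open = TRUE) + 1L
}

#' Simulate phenotypes given genotypes
#'
#' Each member gets a censoring age from the design's generation-specific
#' Gaussian (rounded, clamped to `[1, max_age]`) and a latent onset age
#' from the carrier (sex-specific modified Weibull) or noncarrier
#' (baseline) onset distribution; with probability `1 - F(max_age)` onset
#' never occurs. Members whose onset is at or before censoring are recorded
#' affected at the onset age, others unaffected.
#'
#' @param ped A genotyped `pedigree` from [drop_genotypes()].
#' @param design A [sim_design()].
#' @return The completed `pedigree`.
#' @export
simulate_phenotypes <- function(ped, design) {
  max_age <- design$max_age
  cum_car <- list(female = penetrance_cdf(design$theta_female, seq_len(max_age)),
                  male = penetrance_cdf(design$theta_male, seq_len(max_age)))
  cum_nc <- list(female = design$baseline$female, male = design$baseline$male)
  pro <- which(ped$is_proband)[1]
  for (i in seq_len(nrow(ped))) {
    gen <- as.character(ped$gen[i])
    repeat {
      cens <- round(rnorm(1, design$censoring_mean[[gen]], design$censoring_sd[[gen]]))
      cens <- min(max(cens, 1L), max_age)
      cum <- if (ped$gcount[i] >= 1L) cum_car[[ped$sex[i]]] else cum_nc[[ped$sex[i]]]
      onset <- draw_onset_from_cum(cum)
      affected <- !is.na(onset) && onset <= cens
      if (!(design$require_proband_affected && i == pro) || affected) break
    }
    ped$cur_age[i] <- as.integer(cens)
    if (affected) {
      ped$is_aff[i] <- "affected"; ped$onset_age[i] <- as.integer(onset)
    } else {
      ped$is_aff[i] <- "unaffected"; ped$onset_age[i] <- NA_integer_
    }
  }
  ped
}

#' Simulate a complete family study
#'
#' End-to-end generation of `n_probands` ascertained families (structure,
#' genotypes under the ascertainment condition, phenotypes), returning the
#' study alongside its ground-truth record.
#'
#' @param design A [sim_design()].
#' @return List with `peds` (a `pedigree_set`) and `truth` (true
#'   parameters, prevalence, seed and the design echo).
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  peds <- vector("list", design$n_probands)
  for (f in seq_len(design$n_probands)) {
    ped <- simulate_structure(design, fam_id = as.character(f))
    ped <- drop_genotypes(ped, design)
    peds[[f]] <- simulate_phenotypes(ped, design)
  }
  names(peds) <- as.character(seq_len(design$n_probands))
  list(peds = structure(peds, class = "pedigree_set"),
       truth = list(theta_female = design$theta_female,
                    theta_male = design$theta_male,
                    prevalence = design$prevalence,
                    seed = design$seed, design = design))
}

# ---- deterministic count calibration ---------------------------------------

#' Calibrate a simulated study to exact summary counts
#'
#' Deterministically adjusts a simulated study so that
#' [pedigree_summary()] reproduces stated bookkeeping counts: total
#' individuals (trimming childless non-proband members from the largest
#' families or adding unaffected adult founders to the smallest) and exact
#' numbers of female and male diagnoses (toggling non-proband affection
#' status). Useful for reproducing a published study's headline counts in
#' reporting tests; no randomness is involved.
#'
#' @param peds A `pedigree_set`.
#' @param n_individuals Target total number of individuals.
#' @param n_aff_female,n_aff_male Target diagnosis counts by sex.
#' @return The adjusted `pedigree_set`.
#' @export
calibrate_study_counts <- function(peds, n_individuals, n_aff_female, n_aff_male) {
  stopifnot(inherits(peds, "pedigree_set"))
  sizes <- function() vapply(peds, nrow, 0L)
  # total size
  while (sum(sizes()) > n_individuals) {
    fi <- which.max(sizes())
    p <- peds[[fi]]
    is_parent <- p$id %in% c(p$mother_id, p$father_id)
    cand <- which(!is_parent & !p$is_proband)
    if (!length(cand)) stop("cannot trim family further")
    peds[[fi]] <- p[-cand[length(cand)], ]
    class(peds[[fi]]) <- c("pedigree", "data.frame")
  }
  while (sum(sizes()) < n_individuals) {
    fi <- which.min(sizes())
    p <- peds[[fi]]
    new_id <- as.character(max(as.integer(p$id)) + 1L)
    row <- p[1, ]
    row$id <- new_id; row$sex <- "female"; row$mother_id <- NA_character_
    row$father_id <- NA_character_; row$is_proband <- FALSE
    row$cur_age <- 50L; row$is_aff <- "unaffected"; row$onset_age <- NA_integer_
    row$geno <- "unknown"
    if ("gcount" %in% names(row)) row$gcount <- 0L
    if ("gen" %in% names(row)) row$gen <- 2L
    peds[[fi]] <- rbind(p, row)
    class(peds[[fi]]) <- c("pedigree", "data.frame")
  }
  # affection counts by sex
  for (s in c("female", "male")) {
    target <- if (s == "female") n_aff_female else n_aff_male
    repeat {
      aff <- integer(0); unaff <- integer(0)
      for (fi in seq_along(peds)) {
        p <- peds[[fi]]
        aff <- c(aff, sum(p$sex == s & p$is_aff == "affected"))
        unaff <- c(unaff, sum(p$sex == s & p$is_aff == "unaffected" &
                                !p$is_proband & !is.na(p$cur_age) & p$cur_age >= 30))
      }
      now <- sum(aff)
      if (now == target) break
      if (now > target) {
        fi <- which(aff > 0)[1]
        p <- peds[[fi]]
        i <- which(p$sex == s & p$is_aff == "affected" & !p$is_proband)
        if (!length(i)) i <- which(p$sex == s & p$is_aff == "affected")
        i <- i[length(i)]
        p$is_aff[i] <- "unaffected"; p$onset_age[i] <- NA_integer_
        peds[[fi]] <- p
      } else {
        fi <- which(unaff > 0)[1]
        if (is.na(fi)) stop("not enough adjustable members to reach diagnosis count")
        p <- peds[[fi]]
        i <- which(p$sex == s & p$is_aff == "unaffected" & !p$is_proband &
                     !is.na(p$cur_age) & p$cur_age >= 30)[1]
        p$is_aff[i] <- "affected"
        p$onset_age[i] <- max(21L, p$cur_age[i] - 5L)
        peds[[fi]] <- p
      }
    }
  }
  peds
}
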