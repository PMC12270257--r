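test_that("founder genotype probabilities follow HWE with exact prevalence", {
  expect_equal(founder_genotype_probs(0.19), c(aa = 0.81, Aa = 0.18, AA = 0.01),
               tolerance = 1e-12)
  expect_equal(unname(founder_genotype_probs(1e-9)), c(1, 0, 0), tolerance = 1e-8)
  p <- founder_genotype_probs(0.0051)
  expect_lt(abs(p[["Aa"]] + p[["AA"]] - 0.0051), 1e-14)
  expect_lt(abs(sum(p) - 1), 1e-14)
  expect_error(founder_genotype_probs(0), "prevalence")
  expect_error(founder_genotype_probs(1.3), "prevalence")
})

test_that("Mendelian transmission array is a Punnett square and row-normalizes", {
  tr <- transmission_matrix()
  expect_equal(tr["Aa", "Aa", "Aa"], 0.5)
  expect_equal(tr["AA", "Aa", "Aa"], 0.25)
  expect_equal(tr["AA", "aa", "aa"], 0)
  for (m in 1:3) for (f in 1:3)
    expect_equal(sum(tr[, m, f]), 1, tolerance = 1e-15)
})

test_that("phenotype likelihood composes observation indicators", {
  pen <- penetrance_set(quantiles_to_weibull(quantile_params(45, 55, 0.8, 20)),
                        baseline = default_baseline())
  mk <- function(sex, aff, onset, cur, geno)
    list(sex = sex, is_aff = aff, onset_age = onset, cur_age = cur, geno = geno)
  # unaffected, observed noncarrier genotype
  v <- phenotype_likelihood(mk("female", "unaffected", NA, 60L, "noncarrier"), pen)
  expect_equal(unname(v), c(1 - pen$cum$noncarrier$female[60], 0, 0))
  # fully unobserved
  v2 <- phenotype_likelihood(mk("male", "unknown", NA, NA, "unknown"), pen)
  expect_equal(unname(v2), c(1, 1, 1))
  # affected carrier at 50: dominant collapse + genotype indicator
  v3 <- phenotype_likelihood(mk("male", "affected", 50L, 60L, "carrier"), pen)
  d50 <- pen$dens$carrier$male[50]
  expect_equal(unname(v3), c(0, d50, d50))
  # unknown sex averages female and male values
  v4 <- phenotype_likelihood(mk("unknown", "affected", 50L, 60L, "unknown"), pen)
  expect_equal(unname(v4[2]),
               (pen$dens$carrier$female[50] + pen$dens$carrier$male[50]) / 2)
  # affected with missing onset but known censoring age: cumulative by then
  v5 <- phenotype_likelihood(mk("female", "affected", NA, 70L, "unknown"), pen)
  expect_equal(unname(v5[2]), pen$cum$carrier$female[70])
})

founder_only <- function(geno = "unknown", aff = "unknown", cur = NA_integer_) {
  as_ped(data.frame(
    pedigree_id = "1", id = "1", sex = "female", mother_id = NA_character_,
    father_id = NA_character_, is_proband = TRUE, cur_age = cur,
    is_aff = aff, onset_age = NA_integer_, geno = geno,
    stringsAsFactors = FALSE))
}

test_that("peeling marginal anchors: single founders", {
  gm <- genotype_model(0.05)
  pen <- random_pen_set()
  expect_equal(peel_loglikelihood(founder_only(), gm, pen), 0, tolerance = 1e-12)
  expect_equal(peel_loglikelihood(founder_only("carrier"), gm, pen),
               log(0.05), tolerance = 1e-12)
  expect_equal(peel_loglikelihood(founder_only("noncarrier"), gm, pen),
               log(0.95), tolerance = 1e-12)
})

test_that("peeling equals enumeration across random pedigrees and models", {
  set.seed(51)
  worst <- 0
  for (r in 1:60) {
    p <- random_pedigree(sample(3:12, 1), p_aff = runif(1, 0.1, 0.6),
                         p_geno = runif(1, 0, 0.35))
    gm <- genotype_model(runif(1, 0.001, 0.4))
    pen <- random_pen_set()
    lb <- brute_force_loglikelihood(p, gm, pen)
    lp <- suppressWarnings(peel_loglikelihood(p, gm, pen))
    if (is.infinite(lb)) {
      expect_identical(lp, lb)
    } else {
      worst <- max(worst, abs(lp - lb) / abs(lb))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("likelihood invariances: permutation, uninformative data, smoothness", {
  set.seed(52)
  gm <- genotype_model(0.02)
  pen <- random_pen_set()
  p <- random_pedigree(10, p_aff = 0.5, p_geno = 0, p_missing_cur = 0)
  # keep onsets inside the support of both onset distributions
  aff <- which(p$is_aff == "affected")
  p$cur_age[aff] <- pmax(p$cur_age[aff], 60L)
  p$onset_age[aff] <- pmax(p$onset_age[aff], 35L)
  ll <- peel_loglikelihood(p, gm, pen)
  # member order within the table does not matter
  for (r in 1:5) {
    perm <- as_ped(p[sample.int(nrow(p)), ])
    expect_equal(peel_loglikelihood(perm, gm, pen), ll, tolerance = 1e-12)
  }
  # all phenotypes and genotypes unknown: log-likelihood 0 for any family
  blank <- p
  blank$is_aff <- "unknown"; blank$onset_age <- NA_integer_
  blank$cur_age <- NA_integer_; blank$geno <- "unknown"
  expect_equal(peel_loglikelihood(as_ped(blank), gm, pen), 0, tolerance = 1e-12)
  # continuity in theta
  q <- quantile_params(45, 55, 0.6, 20)
  qe <- quantile_params(45 + 1e-8, 55 + 1e-8, 0.6 + 1e-8, 20)
  l1 <- peel_loglikelihood(p, gm, penetrance_set(quantiles_to_weibull(q),
                                                 baseline = default_baseline()))
  l2 <- peel_loglikelihood(p, gm, penetrance_set(quantiles_to_weibull(qe),
                                                 baseline = default_baseline()))
  expect_lt(abs(l1 - l2), 1e-5)
})

test_that("impossible transmissions yield -Inf and are flagged", {
  tab <- nuclear_tab()
  tab$Geno <- c(0, 0, 1, NA)  # child carrier, both parents observed noncarrier
  p <- parse_pedigrees(tab)[[1]]
  gm <- genotype_model(0.1)
  pen <- random_pen_set()
  expect_warning(ll <- peel_loglikelihood(p, gm, pen), "probability zero")
  expect_identical(ll, -Inf)
  expect_identical(brute_force_loglikelihood(p, gm, pen), -Inf)
})

test_that("looped pedigrees are rejected by the peeler", {
  p <- make_motif("cousin")
  gm <- genotype_model(0.1)
  pen <- random_pen_set()
  expect_error(peel_loglikelihood(p, gm, pen), "loop")
  expect_error(carrier_posterior(p, gm, pen, "9"), "loop")
})

# independent enumeration oracle for the carrier posterior
enum_carrier_posterior <- function(p, gm, pen, id) {
  n <- nrow(p)
  i <- match(id, p$id)
  ph <- t(vapply(seq_len(n), function(j) phenotype_likelihood(p[j, ], pen),
                 numeric(3)))
  mo <- match(p$mother_id, p$id); fa <- match(p$father_id, p$id)
  tr <- transmission_matrix()
  G <- as.matrix(expand.grid(rep(list(0:2), n)))
  pr <- rep(1, nrow(G))
  for (j in seq_len(n)) {
    w <- ph[j, G[, j] + 1L]
    if (is.na(mo[j])) w <- w * gm$founder_probs[G[, j] + 1L]
    else w <- w * tr[cbind(G[, j] + 1L, G[, mo[j]] + 1L, G[, fa[j]] + 1L)]
    pr <- pr * w
  }
  sum(pr[G[, i] >= 1L]) / sum(pr)
}

test_that("carrier posterior: anchors and enumeration oracle", {
  gm <- genotype_model(0.07)
  pen <- random_pen_set()
  expect_equal(carrier_posterior(founder_only(), gm, pen, "1"), 0.07,
               tolerance = 1e-12)
  expect_equal(carrier_posterior(founder_only("carrier"), gm, pen, "1"), 1,
               tolerance = 1e-12)
  set.seed(53)
  err <- numeric(20)
  for (r in 1:20) {
    repeat {  # redraw families whose data are impossible (zero likelihood)
      p <- random_pedigree(sample(3:8, 1), p_aff = 0.5, p_geno = 0.15)
      gm_r <- genotype_model(runif(1, 0.01, 0.3))
      pen_r <- random_pen_set()
      if (is.finite(brute_force_loglikelihood(p, gm_r, pen_r))) break
    }
    id <- sample(p$id, 1)
    want <- enum_carrier_posterior(p, gm_r, pen_r, id)
    got <- carrier_posterior(p, gm_r, pen_r, id)
    err[r] <- abs(want - got)
  }
  expect_lt(max(err), 1e-9)
})

test_that("affected member with no ages errors toward imputation", {
  tab <- nuclear_tab()
  tab$Age[3] <- NA; tab$CurAge[3] <- NA
  p <- parse_pedigrees(tab)[[1]]
  expect_error(
    peel_loglikelihood(p, genotype_model(0.1), random_pen_set()),
    "age_imputation")
})
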