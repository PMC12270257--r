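# Fixtures are generated in code. Random pedigrees are loop-free by
# construction (spouses marrying in are always new founders).

nuclear_tab <- function() {
  data.frame(
    PedigreeID = 1, ID = 1:4, Sex = c(1, 0, 1, 0),
    MotherID = c(NA, NA, 2, 2), FatherID = c(NA, NA, 1, 1),
    isProband = c(0, 0, 1, 0), CurAge = c(70, 68, 45, 40),
    isAff = c(0, 0, 1, 0), Age = c(NA, NA, 44, NA),
    Geno = c(NA, NA, 1, NA))
}

as_ped <- function(df, max_age = 94) {
  attr(df, "max_age") <- as.integer(max_age)
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

as_ped_set <- function(...) structure(list(...), class = "pedigree_set")

# random loop-free family structure with n members; uses the current RNG
random_structure <- function(n, fam_id = "F") {
  stopifnot(n >= 2)
  sex <- character(n); mo <- rep(NA_integer_, n); fa <- rep(NA_integer_, n)
  sex[1] <- "female"; sex[2] <- "male"
  couples <- list(c(1L, 2L))  # (mother, father)
  i <- 3L
  while (i <= n) {
    if (runif(1) < 0.6 || i == n) {
      cp <- couples[[sample.int(length(couples), 1L)]]
      sex[i] <- sample(c("female", "male"), 1L)
      mo[i] <- cp[1]; fa[i] <- cp[2]
      i <- i + 1L
    } else {
      mate <- sample.int(i - 1L, 1L)
      sex[i] <- if (sex[mate] == "female") "male" else "female"
      cp <- if (sex[mate] == "female") c(mate, i) else c(i, mate)
      couples[[length(couples) + 1L]] <- cp
      i <- i + 1L
    }
  }
  data.frame(pedigree_id = fam_id, id = as.character(seq_len(n)), sex = sex,
             mother_id = as.character(mo), father_id = as.character(fa),
             is_proband = c(rep(FALSE, n - 1L), TRUE),
             cur_age = NA_integer_, is_aff = "unknown",
             onset_age = NA_integer_, geno = "unknown",
             stringsAsFactors = FALSE)
}

# random valid observations: phenotypes, censoring ages, partial genotypes
random_pedigree <- function(n, fam_id = "F", p_aff = 0.3, p_geno = 0.2,
                            p_missing_cur = 0.1, max_age = 94) {
  p <- random_structure(n, fam_id)
  for (i in seq_len(n)) {
    cur <- sample(25:90, 1L)
    if (runif(1) < p_aff) {
      p$is_aff[i] <- "affected"
      p$onset_age[i] <- sample(seq(max(1L, cur - 40L), cur), 1L)
      p$cur_age[i] <- cur
    } else {
      p$is_aff[i] <- sample(c("unaffected", "unknown"), 1L, prob = c(0.8, 0.2))
      p$cur_age[i] <- if (runif(1) < p_missing_cur) NA_integer_ else cur
    }
    if (runif(1) < p_geno)
      p$geno[i] <- sample(c("carrier", "noncarrier"), 1L)
  }
  # occasional unknown sex for members that are not parents
  parents <- unique(c(p$mother_id, p$father_id))
  for (i in seq_len(n))
    if (!(p$id[i] %in% parents) && runif(1) < 0.1) p$sex[i] <- "unknown"
  as_ped(p, max_age)
}

random_quantile_params <- function(max_age = 94) {
  delta <- runif(1, 5, 30)
  q1 <- delta + runif(1, 2, 0.6 * (max_age - delta))
  med <- q1 + runif(1, 1, 0.8 * (max_age - q1))
  quantile_params(q1, med, runif(1, 0.05, 0.95), delta, max_age = max_age)
}

random_pen_set <- function(baseline = default_baseline()) {
  penetrance_set(quantiles_to_weibull(random_quantile_params()),
                 quantiles_to_weibull(random_quantile_params()),
                 baseline)
}

empty_ped_set <- function() structure(list(), class = "pedigree_set")

# KS distance of an integer sample against a discrete CDF on 1..length(cdf);
# comparing with the continuous critical value is conservative under ties
ks_discrete <- function(x, cdf) {
  ec <- cumsum(tabulate(x, nbins = length(cdf))) / length(x)
  max(abs(ec - cdf))
}

# curated loop/no-loop family motifs
make_motif <- function(kind) {
  base <- data.frame(
    pedigree_id = "L", id = as.character(1:10), sex = "female",
    mother_id = NA_character_, father_id = NA_character_,
    is_proband = FALSE, cur_age = 50L, is_aff = "unknown",
    onset_age = NA_integer_, geno = "unknown", stringsAsFactors = FALSE)
  set_child <- function(p, i, mo, fa) {
    p$mother_id[i] <- as.character(mo); p$father_id[i] <- as.character(fa); p
  }
  p <- base
  p$sex <- c("female", "male", "male", "female", "female", "male",
             "male", "female", "female", "male")
  if (kind == "cousin") {
    p <- set_child(p, 3, 1, 2); p <- set_child(p, 4, 1, 2)
    p <- set_child(p, 7, 5, 3); p <- set_child(p, 8, 4, 6)
    p <- set_child(p, 9, 8, 7)     # first cousins mate
  } else if (kind == "uncle_niece") {
    p <- set_child(p, 3, 1, 2); p <- set_child(p, 4, 1, 2)
    p <- set_child(p, 8, 4, 6)
    p <- set_child(p, 9, 8, 3)     # uncle x niece
  } else if (kind == "sib_exchange") {
    p <- set_child(p, 3, 1, 2); p <- set_child(p, 4, 1, 2)
    p <- set_child(p, 7, 5, 6); p <- set_child(p, 8, 5, 6)
    p$sex[4] <- "male"; p$sex[8] <- "female"
    p <- set_child(p, 9, 3, 7)     # sister marries brother-in-law's family
    p <- set_child(p, 10, 8, 4)
  } else if (kind == "chain") {
    p <- set_child(p, 3, 1, 2); p <- set_child(p, 7, 5, 6)
    p$sex[7] <- "female"
    p <- set_child(p, 9, 7, 3)     # two families joined by one marriage
  }
  as_ped(p)
}
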