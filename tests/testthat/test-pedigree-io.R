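test_that("parse maps the ten-column schema structurally", {
  peds <- parse_pedigrees(nuclear_tab())
  expect_length(peds, 1L)
  p <- peds[[1]]
  expect_equal(nrow(p), 4L)
  expect_equal(sum(is.na(p$mother_id) & is.na(p$father_id)), 2L)  # founders
  expect_identical(p$sex, c("male", "female", "male", "female"))
  expect_identical(p$is_proband, c(FALSE, FALSE, TRUE, FALSE))
  # affected with missing diagnosis age parses with onset retained missing
  tab <- nuclear_tab(); tab$Age[3] <- NA
  p2 <- parse_pedigrees(tab)[[1]]
  expect_identical(p2$is_aff[3], "affected")
  expect_true(is.na(p2$onset_age[3]))
})

test_that("parse rejects structural impossibilities with informative errors", {
  tab <- nuclear_tab()
  expect_error(parse_pedigrees(tab[, setdiff(names(tab), "Geno")]),
               "missing mandatory column.*geno")
  bad <- nuclear_tab(); bad$MotherID[3] <- 99
  expect_error(parse_pedigrees(bad), "family 1.*absent ID.*99")
  dup <- nuclear_tab(); dup$ID[4] <- 3
  expect_error(parse_pedigrees(dup), "duplicate ID.*3")
  frac <- nuclear_tab(); frac$CurAge[1] <- 70.5
  expect_error(parse_pedigrees(frac), "fractional CurAge")
})

test_that("sex and missingness codings are accepted interchangeably", {
  tab <- nuclear_tab()
  tab$Sex <- c("M", "F", "male", "female")
  p <- parse_pedigrees(tab)[[1]]
  expect_identical(p$sex, c("male", "female", "male", "female"))
  tab$Sex <- c(1, 0, NA, 0)
  p2 <- parse_pedigrees(tab)[[1]]
  expect_identical(p2$sex[3], "unknown")
  expect_error(parse_pedigrees(transform(nuclear_tab(), Sex = "banana")),
               "unrecognized Sex")
})

test_that("parse -> write -> parse round-trips bit-faithfully", {
  set.seed(31)
  peds <- structure(lapply(1:5, function(i) random_pedigree(sample(3:12, 1),
                                                            fam_id = as.character(i))),
                    class = "pedigree_set")
  for (sep in c(",", "\t")) {
    f <- tempfile()
    write_pedigrees(peds, f, sep = sep)
    back <- parse_pedigrees(f)
    expect_length(back, 5L)
    for (i in 1:5) {
      a <- as.data.frame(peds[[i]])[, 1:10]
      b <- as.data.frame(back[[i]])[, 1:10]
      rownames(a) <- rownames(b) <- NULL
      expect_identical(a, b)
    }
  }
})

test_that("validate enumerates every violation without stopping", {
  p <- parse_pedigrees(nuclear_tab())[[1]]
  expect_true(is_valid(validate_pedigree(p)))
  bad <- nuclear_tab()
  bad$Age[3] <- 70; bad$CurAge[3] <- 65       # onset after censoring
  bad$Age[4] <- 30                            # onset but unaffected
  bad$CurAge[1] <- 120                        # out of range
  r <- validate_pedigree(parse_pedigrees(bad)[[1]])
  expect_false(is_valid(r))
  expect_setequal(unique(r$errors$rule),
                  c("onset_after_censoring", "onset_without_affected",
                    "age_out_of_range"))
  expect_gte(nrow(r$errors), 3L)
  js <- report_to_json(r)
  expect_true(jsonlite::validate(js))
})

test_that("fuzzed single-defect injections are each flagged", {
  set.seed(32)
  inject <- list(
    onset_after_censoring = function(p) {
      i <- which(p$is_aff == "affected" & !is.na(p$cur_age))[1]
      p$onset_age[i] <- p$cur_age[i] + 5L; p
    },
    onset_without_affected = function(p) {
      i <- which(p$is_aff == "unaffected")[1]
      p$onset_age[i] <- 40L; p
    },
    parent_pair_incomplete = function(p) {
      i <- which(!is.na(p$mother_id))[1]
      p$father_id[i] <- NA_character_; p
    },
    age_out_of_range = function(p) {
      i <- which(!is.na(p$cur_age))[1]
      p$cur_age[i] <- 200L; p
    }
  )
  for (rep_i in 1:20) {
    p <- random_pedigree(sample(6:14, 1), p_aff = 0.6, p_missing_cur = 0)
    rule <- sample(names(inject), 1)
    q <- inject[[rule]](p)
    r <- validate_pedigree(as_ped(q))
    expect_true(rule %in% r$errors$rule,
                info = sprintf("rep %d rule %s", rep_i, rule))
  }
})

# independent cycle oracle over a differently-encoded marriage graph
igraph_has_loop <- function(p) {
  skip_if_not_installed("igraph")
  kids <- which(!is.na(p$mother_id))
  if (!length(kids)) return(FALSE)
  couple <- paste0("c:", p$mother_id[kids], "+", p$father_id[kids])
  el <- rbind(cbind(paste0("i:", p$mother_id[kids]), couple),
              cbind(paste0("i:", p$father_id[kids]), couple),
              cbind(paste0("i:", p$id[kids]), couple))
  g <- igraph::simplify(igraph::graph_from_edgelist(unique(el), directed = FALSE))
  comp <- igraph::components(g)
  any(vapply(seq_len(comp$no), function(k) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == k))
    igraph::ecount(sub) > igraph::vcount(sub) - 1
  }, TRUE))
}


test_that("detect_loops matches curated cases and the igraph oracle", {
  expect_length(detect_loops(parse_pedigrees(nuclear_tab())[[1]]), 0L)
  for (kind in c("cousin", "uncle_niece", "sib_exchange")) {
    p <- make_motif(kind)
    loops <- detect_loops(p)
    expect_gte(length(loops), 1L)
    expect_true(igraph_has_loop(p), info = kind)
    # the cycle description names real members
    expect_true(all(unlist(loops) %in% p$id))
  }
  for (kind in "chain") {
    p <- make_motif(kind)
    expect_length(detect_loops(p), 0L)
    expect_false(igraph_has_loop(p))
  }
})

test_that("random loop-free structures agree with the igraph oracle", {
  set.seed(33)
  for (r in 1:30) {
    p <- as_ped(random_structure(sample(4:20, 1)))
    expect_length(detect_loops(p), 0L)
    expect_false(igraph_has_loop(p))
  }
})

test_that("proband removal masks phenotype, keeps genotype, excludes singletons", {
  set.seed(34)
  p <- random_pedigree(10, p_aff = 0.8, p_missing_cur = 0)
  pro <- which(p$is_proband)
  p$is_aff[pro] <- "affected"; p$onset_age[pro] <- 45L
  p$cur_age[pro] <- 60L; p$geno[pro] <- "carrier"
  q <- apply_proband_removal(p)
  expect_identical(q$is_aff[pro], "unknown")
  expect_true(is.na(q$onset_age[pro]))
  expect_identical(q$geno[pro], "carrier")
  expect_identical(q$id, p$id)
  # disabled: identity
  expect_identical(apply_proband_removal(p, remove = FALSE), p)
  # singleton proband-only family is excluded
  single <- as_ped(data.frame(
    pedigree_id = "S", id = "1", sex = "female", mother_id = NA_character_,
    father_id = NA_character_, is_proband = TRUE, cur_age = 50L,
    is_aff = "affected", onset_age = 40L, geno = "carrier",
    stringsAsFactors = FALSE))
  expect_null(apply_proband_removal(single))
  # no proband at all is a validation error
  nop <- p; nop$is_proband[] <- FALSE
  expect_error(apply_proband_removal(nop), "no proband")
  # set-level preparation logs the exclusion
  set2 <- structure(list(p, single), class = "pedigree_set")
  expect_message(out <- prepare_families(set2, remove_proband = TRUE),
                 "singleton")
  expect_length(out, 1L)
  expect_identical(attr(out, "excluded"), "S")
})
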