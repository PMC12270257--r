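# Pedigree tables: one row per individual, columns PedigreeID, ID, Sex,
# MotherID, FatherID, isProband, CurAge, isAff, Age, Geno. Sex 0=female
# 1=male (M/F/male/female also accepted), isAff 1=diagnosed 0=unaffected
# NA=unknown, Geno 1=carrier 0=noncarrier NA=unknown, CurAge = censoring age
# (current age if alive, age at death otherwise), Age = diagnosis age.

PED_COLUMNS <- c("pedigreeid", "id", "sex", "motherid", "fatherid",
                 "isproband", "curage", "isaff", "age", "geno")

norm_sex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("0", "f", "female")] <- "female"
  out[s %in% c("1", "m", "male")] <- "male"
  bad <- !is.na(s) & s != "" & is.na(out) & !s %in% c("na", "u", "unknown")
  if (any(bad)) stop("unrecognized Sex coding: ", paste(unique(s[bad]), collapse = ", "))
  out[is.na(out)] <- "unknown"
  out
}

norm_tristate <- function(x, one, zero, column) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("1", "true", one)] <- one
  out[s %in% c("0", "false", zero)] <- zero
  bad <- !is.na(s) & s != "" & s != "na" & is.na(out)
  if (any(bad)) stop(sprintf("unrecognized %s coding: %s", column,
                             paste(unique(s[bad]), collapse = ", ")))
  out[is.na(out)] <- "unknown"
  out
}

norm_age <- function(x, column) {
  a <- suppressWarnings(as.numeric(as.character(x)))
  raw <- trimws(as.character(x))
  bad <- !is.na(raw) & raw != "" & tolower(raw) != "na" & is.na(a)
  if (any(bad)) stop(sprintf("non-numeric %s value: %s", column,
                             paste(unique(raw[bad]), collapse = ", ")))
  frac <- !is.na(a) & abs(a - round(a)) > 1e-8
  if (any(frac))
    stop(sprintf("fractional %s values are rejected (ages are integer years): %s",
                 column, paste(unique(a[frac]), collapse = ", ")))
  as.integer(round(a))
}

norm_id <- function(x) {
  s <- trimws(as.character(x))
  s[!is.na(s) & (s == "" | tolower(s) == "na" | s == "0")] <- NA_character_
  s
}

#' Parse pedigree tables into a validated family collection
#'
#' Accepts a data frame or a path to a comma-/tab-delimited file with the
#' ten schema columns (header match is case-insensitive; extra columns are
#' ignored). Returns one pedigree per distinct `PedigreeID`, preserving
#' member order. Structural impossibilities (missing column, duplicate `ID`
#' within a family, dangling parent reference, fractional age) are errors;
#' all other consistency rules are reported by [validate_pedigree()].
#'
#' @param x Data frame or file path.
#' @param max_age Age-grid upper bound carried by each pedigree (default 94).
#' @return An object of class `pedigree_set`: a named list of `pedigree`
#'   data frames with columns `pedigree_id, id, sex, mother_id, father_id,
#'   is_proband, cur_age, is_aff, onset_age, geno`.
#' @export
parse_pedigrees <- function(x, max_age = 94) {
  tab <- if (is.character(x) && length(x) == 1L) read_delim_auto(x) else as.data.frame(x)
  lk <- tolower(gsub("[ ._]", "", names(tab)))
  missing_cols <- setdiff(PED_COLUMNS, lk)
  if (length(missing_cols))
    stop("pedigree table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  col <- function(nm) tab[[which(lk == nm)[1]]]
  d <- data.frame(
    pedigree_id = trimws(as.character(col("pedigreeid"))),
    id = trimws(as.character(col("id"))),
    sex = norm_sex(col("sex")),
    mother_id = norm_id(col("motherid")),
    father_id = norm_id(col("fatherid")),
    is_proband = norm_tristate(col("isproband"), "yes", "no", "isProband") == "yes",
    cur_age = norm_age(col("curage"), "CurAge"),
    is_aff = norm_tristate(col("isaff"), "affected", "unaffected", "isAff"),
    onset_age = norm_age(col("age"), "Age"),
    geno = norm_tristate(col("geno"), "carrier", "noncarrier", "Geno"),
    stringsAsFactors = FALSE
  )
  if (any(is.na(d$pedigree_id) | d$pedigree_id == ""))
    stop("PedigreeID must be present for every row")
  if (any(is.na(d$id) | d$id == "")) stop("ID must be present for every row")
  fams <- split(d, factor(d$pedigree_id, levels = unique(d$pedigree_id)))
  peds <- lapply(fams, function(p) {
    rownames(p) <- NULL
    dup <- p$id[duplicated(p$id)]
    if (length(dup))
      stop(sprintf("family %s: duplicate ID within family: %s",
                   p$pedigree_id[1], paste(unique(dup), collapse = ", ")))
    for (pc in c("mother_id", "father_id")) {
      dangling <- !is.na(p[[pc]]) & !(p[[pc]] %in% p$id)
      if (any(dangling))
        stop(sprintf("family %s: %s references absent ID(s): %s",
                     p$pedigree_id[1], pc,
                     paste(unique(p[[pc]][dangling]), collapse = ", ")))
    }
    attr(p, "max_age") <- as.integer(max_age)
    class(p) <- c("pedigree", "data.frame")
    p
  })
  structure(peds, class = "pedigree_set")
}

#' @rdname parse_pedigrees
#' @param file Path to a pedigree file.
#' @export
read_pedigrees <- function(file, max_age = 94) parse_pedigrees(file, max_age = max_age)

#' Write a pedigree collection in the ten-column schema
#'
#' Serializes back to the external coding (Sex 0/1, isAff 1/0, Geno 1/0,
#' missing values written as `NA`), bit-faithful for missingness, so that
#' `parse -> write -> parse` round-trips.
#'
#' @param peds A `pedigree_set` (or single `pedigree`).
#' @param file Output path.
#' @param sep Field separator: `","` (default) or `"\t"`.
#' @return `file`, invisibly.
#' @export
write_pedigrees <- function(peds, file, sep = ",") {
  if (inherits(peds, "pedigree")) peds <- structure(list(peds), class = "pedigree_set")
  stopifnot(inherits(peds, "pedigree_set"))
  rows <- do.call(rbind, lapply(peds, function(p) {
    data.frame(
      PedigreeID = p$pedigree_id,
      ID = p$id,
      Sex = ifelse(p$sex == "female", 0L, ifelse(p$sex == "male", 1L, NA_integer_)),
      MotherID = p$mother_id,
      FatherID = p$father_id,
      isProband = as.integer(p$is_proband),
      CurAge = p$cur_age,
      isAff = ifelse(p$is_aff == "affected", 1L,
                     ifelse(p$is_aff == "unaffected", 0L, NA_integer_)),
      Age = p$onset_age,
      Geno = ifelse(p$geno == "carrier", 1L,
                    ifelse(p$geno == "noncarrier", 0L, NA_integer_)),
      stringsAsFactors = FALSE
    )
  }))
  write.table(rows, file, sep = sep, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(file)
}

#' @export
print.pedigree_set <- function(x, ...) {
  n <- vapply(x, nrow, 0L)
  cat(sprintf("pedigree_set: %d families, %d individuals (sizes %s)\n",
              length(x), sum(n), paste(range(n), collapse = "-")))
  invisible(x)
}

# ---- validation -------------------------------------------------------------

new_report <- function(errors, warnings, counts) {
  structure(list(errors = errors, warnings = warnings, counts = counts),
            class = "validation_report")
}

report_row <- function(family, id, rule, message) {
  data.frame(family_id = family, individual_id = id, rule = rule,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a pedigree against the schema invariants
#'
#' Checks every individual-level and family-level invariant and enumerates
#' all violations (it does not stop at the first): onset age implies
#' affected status, onset not after the censoring age, parent references
#' both-present-or-both-absent and resolvable, ages on the integer grid
#' `[1, max_age]`, acyclic parent structure, and parent-sex consistency
#' (warning). Violations are data, not exceptions.
#'
#' @param p A `pedigree` (or a `pedigree_set`, in which case reports are
#'   pooled).
#' @param max_age Age-grid upper bound (defaults to the pedigree attribute).
#' @return A `validation_report` with data-frame `errors` and `warnings`
#'   (columns `family_id, individual_id, rule, message`) and a `counts`
#'   list; the input is accepted iff `errors` is empty (see [is_valid()]).
#' @export
validate_pedigree <- function(p, max_age = NULL) {
  if (inherits(p, "pedigree_set")) {
    reps <- lapply(p, validate_pedigree, max_age = max_age)
    errors <- do.call(rbind, lapply(reps, `[[`, "errors"))
    warnings <- do.call(rbind, lapply(reps, `[[`, "warnings"))
    counts <- Reduce(function(a, b) Map(`+`, a, b), lapply(reps, `[[`, "counts"))
    counts$families <- length(p)
    return(new_report(errors, warnings, counts))
  }
  stopifnot(inherits(p, "pedigree"))
  if (is.null(max_age)) max_age <- attr(p, "max_age") %||% 94L
  fam <- p$pedigree_id[1]
  err <- list(); wrn <- list()
  add_err <- function(id, rule, msg) err[[length(err) + 1L]] <<- report_row(fam, id, rule, msg)
  add_wrn <- function(id, rule, msg) wrn[[length(wrn) + 1L]] <<- report_row(fam, id, rule, msg)

  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    if (!is.na(r$onset_age) && r$is_aff != "affected")
      add_err(r$id, "onset_without_affected",
              "onset age recorded but individual not coded affected")
    if (!is.na(r$onset_age) && !is.na(r$cur_age) && r$onset_age > r$cur_age)
      add_err(r$id, "onset_after_censoring",
              sprintf("onset at %d after censoring age %d", r$onset_age, r$cur_age))
    if (xor(is.na(r$mother_id), is.na(r$father_id)))
      add_err(r$id, "parent_pair_incomplete",
              "exactly one of mother/father recorded; founders must have neither")
    for (ac in c("cur_age", "onset_age")) {
      a <- r[[ac]]
      if (!is.na(a) && (a < 1L || a > max_age))
        add_err(r$id, "age_out_of_range",
                sprintf("%s = %d outside [1, %d]", ac, a, max_age))
    }
    for (pc in c("mother_id", "father_id")) {
      pid <- r[[pc]]
      if (!is.na(pid) && !(pid %in% p$id))
        add_err(r$id, "parent_not_found", sprintf("%s '%s' not in family", pc, pid))
    }
    if (!is.na(r$mother_id) && !is.na(r$father_id) && r$mother_id == r$father_id)
      add_err(r$id, "identical_parents", "mother and father are the same individual")
  }
  # parent-sex consistency (paper silent: warn, do not reject)
  for (pc in c("mother_id", "father_id")) {
    want <- if (pc == "mother_id") "female" else "male"
    pids <- unique(p[[pc]][!is.na(p[[pc]])])
    pids <- pids[pids %in% p$id]
    for (pid in pids) {
      s <- p$sex[match(pid, p$id)]
      if (s != "unknown" && s != want)
        add_wrn(pid, "parent_sex_inconsistent",
                sprintf("recorded as %s but referenced as %s", s,
                        sub("_id", "", pc)))
    }
  }
  if (!any(p$is_proband)) add_wrn(NA_character_, "no_proband", "family has no proband")
  # acyclicity through parent edges (an individual must not be its own ancestor)
  idx <- seq_len(nrow(p))
  mo <- match(p$mother_id, p$id); fa <- match(p$father_id, p$id)
  state <- integer(nrow(p)) # 0 unvisited, 1 in stack, 2 done
  cyc <- character(0)
  visit <- function(i, trail) {
    if (state[i] == 1L) { cyc <<- union(cyc, p$id[i]); return() }
    if (state[i] == 2L) return()
    state[i] <<- 1L
    for (par in c(mo[i], fa[i])) if (!is.na(par)) visit(par, c(trail, i))
    state[i] <<- 2L
  }
  for (i in idx) if (state[i] == 0L) visit(i, integer(0))
  for (cid in cyc)
    add_err(cid, "ancestor_cycle", "individual is its own ancestor")

  empty <- report_row(character(0), character(0), character(0), character(0))
  new_report(
    errors = if (length(err)) do.call(rbind, err) else empty,
    warnings = if (length(wrn)) do.call(rbind, wrn) else empty,
    counts = list(families = 1L, individuals = nrow(p),
                  affected = sum(p$is_aff == "affected"),
                  carriers_observed = sum(p$geno == "carrier"),
                  probands = sum(p$is_proband))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Did validation accept the input?
#'
#' @param report A `validation_report`.
#' @return `TRUE` iff the error list is empty.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  nrow(report$errors) == 0L
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d error(s), %d warning(s); %d families, %d individuals, %d affected, %d carriers observed\n",
              nrow(x$errors), nrow(x$warnings), x$counts$families,
              x$counts$individuals, x$counts$affected, x$counts$carriers_observed))
  if (nrow(x$errors)) print(x$errors)
  invisible(x)
}

#' Export a validation report as JSON
#'
#' @param report A `validation_report`.
#' @param file Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
report_to_json <- function(report, file = NULL) {
  stopifnot(inherits(report, "validation_report"))
  js <- jsonlite::toJSON(list(errors = report$errors, warnings = report$warnings,
                              counts = report$counts),
                         dataframe = "rows", auto_unbox = TRUE, na = "null")
  if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
  js
}

# ---- loop detection ---------------------------------------------------------

#' Detect marriage and inbreeding loops
#'
#' Elston-Stewart peeling assumes a loop-free pedigree. A loop is a cycle in
#' the marriage-node graph (nodes: individuals and mating pairs; edges:
#' partner-to-couple and couple-to-child), which covers both inbreeding
#' loops (mates sharing a common ancestor, e.g. cousin matings) and marriage
#' rings (families joined by more than one marriage).
#'
#' @param p A `pedigree`.
#' @return A list of loops, each a character vector of the member ids lying
#'   on the cycle; empty list for loop-free pedigrees.
#' @export
detect_loops <- function(p) {
  stopifnot(inherits(p, "pedigree"))
  n <- nrow(p)
  mo <- match(p$mother_id, p$id); fa <- match(p$father_id, p$id)
  has_par <- !is.na(mo) & !is.na(fa)
  if (!any(has_par)) return(list())
  couple_key <- paste(mo[has_par], fa[has_par])
  couples <- unique(couple_key)
  cnode <- n + match(couples, couples)            # couple node ids n+1..n+k
  # edge list over nodes 1..n+k
  ekey <- match(couple_key, couples)
  edges <- rbind(
    cbind(mo[has_par], n + ekey),                 # mother - couple
    cbind(fa[has_par], n + ekey),                 # father - couple
    cbind(which(has_par), n + ekey)               # child - couple
  )
  edges <- unique(edges)
  nn <- n + length(couples)
  # grow a spanning forest with union-find; every extra edge closes one loop
  uf <- seq_len(nn)
  find <- function(a) { while (uf[a] != a) { uf[a] <<- uf[uf[a]]; a <- uf[a] }; a }
  tree_adj <- vector("list", nn)
  extra <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    ra <- find(a); rb <- find(b)
    if (ra == rb) {
      extra <- rbind(extra, c(a, b))
    } else {
      uf[ra] <- rb
      tree_adj[[a]] <- c(tree_adj[[a]], b)
      tree_adj[[b]] <- c(tree_adj[[b]], a)
    }
  }
  loops <- lapply(seq_len(nrow(extra)), function(r) {
    # BFS path through the spanning forest between the extra edge's endpoints
    from <- extra[r, 1]; to <- extra[r, 2]
    prev <- rep(NA_integer_, nn); prev[from] <- from
    queue <- from
    while (length(queue) && is.na(prev[to])) {
      v <- queue[1]; queue <- queue[-1]
      for (w in tree_adj[[v]]) if (is.na(prev[w])) { prev[w] <- v; queue <- c(queue, w) }
    }
    path <- to
    while (path[1] != from) path <- c(prev[path[1]], path)
    sort(unique(p$id[path[path <= n]]))
  })
  unique(loops)
}

# ---- ascertainment ----------------------------------------------------------

#' Mask the proband's phenotype for ascertainment correction
#'
#' Families enter a study through their proband, which biases naive
#' estimates. Correction masks every proband's phenotype observations
#' (`is_aff`, `onset_age`) to unknown while retaining the genotype
#' observation. A family consisting only of probands carries no
#' age-specific risk information after masking and is excluded (returns
#' `NULL`).
#'
#' @param p A `pedigree`.
#' @param remove Apply the correction? When `FALSE` the pedigree is
#'   returned unchanged.
#' @return The modified `pedigree`, or `NULL` when the family is excluded.
#' @export
apply_proband_removal <- function(p, remove = TRUE) {
  stopifnot(inherits(p, "pedigree"))
  if (!remove) return(p)
  if (!any(p$is_proband))
    stop(sprintf("family %s: no proband recorded", p$pedigree_id[1]))
  if (all(p$is_proband)) return(NULL)
  p$is_aff[p$is_proband] <- "unknown"
  p$onset_age[p$is_proband] <- NA_integer_
  p
}

#' Prepare a family collection for estimation
#'
#' Validates every family, optionally applies proband removal (excluding
#' proband-only singletons, which are logged via `message()`), and returns
#' the analysis set.
#'
#' @param peds A `pedigree_set`.
#' @param remove_proband Apply [apply_proband_removal()] to every family.
#' @return A `pedigree_set`; excluded family ids are attached as the
#'   `"excluded"` attribute.
#' @export
prepare_families <- function(peds, remove_proband = FALSE) {
  stopifnot(inherits(peds, "pedigree_set"))
  rep <- validate_pedigree(peds)
  if (!is_valid(rep))
    stop("pedigree validation failed with ", nrow(rep$errors),
         " error(s); inspect validate_pedigree() output")
  excluded <- character(0)
  if (remove_proband) {
    kept <- list()
    for (p in peds) {
      q <- apply_proband_removal(p, remove = TRUE)
      if (is.null(q)) excluded <- c(excluded, p$pedigree_id[1]) else kept[[length(kept) + 1L]] <- q
    }
    if (length(excluded))
      message("excluded ", length(excluded),
              " singleton proband-only family(ies): ",
              paste(excluded, collapse = ", "))
    peds <- structure(kept, class = "pedigree_set")
  }
  attr(peds, "excluded") <- excluded
  peds
}
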