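## Monte-Carlo test of Mendelian segregation of S-locus genotypes.
##
## Two crossing schemes are supported: (case 1) both parents heterozygous,
## four offspring genotype classes expected at frequency 0.25 each;
## (case 2) one parent homozygous, two classes at 0.5 each. Observed class
## counts are compared against 100,000 simulated multinomial cohorts of
## the same size.

## evaluate code under a temporary RNG state, restoring the caller's
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Segregation case descriptor
#'
#' @param case_id `"case1_het_x_het"` (4 classes, 0.25 each) or
#'   `"case2_hom_x_het"` (2 classes, 0.5 each).
#' @return list with `case_id`, `n_classes`, `freq`.
#' @export
segregation_case <- function(case_id = c("case1_het_x_het",
                                         "case2_hom_x_het")) {
  case_id <- match.arg(case_id)
  if (case_id == "case1_het_x_het")
    list(case_id = case_id, n_classes = 4L, freq = 0.25)
  else
    list(case_id = case_id, n_classes = 2L, freq = 0.5)
}

#' Classify a cohort into a segregation case
#'
#' Case 2 requires one (putative or confirmed) homozygous parent *and* at
#' most two observed genotype classes; everything else with two
#' heterozygous parents is case 1. Two homozygous parents fall outside the
#' scheme (their offspring are monomorphic at the S-locus) and raise an
#' error.
#'
#' @param cohort an `si_cohort`.
#' @param genotypes an `si_genotypes`.
#' @return the [segregation_case()] list, plus `hom_parent` (ID or `NA`).
#' @export
classify_case <- function(cohort, genotypes) {
  g1 <- geno_of(genotypes, cohort$parent1)
  g2 <- geno_of(genotypes, cohort$parent2)
  hom1 <- g1[1] == g1[2]; hom2 <- g2[1] == g2[2]
  if (hom1 && hom2)
    stop("cohort ", cohort$cohort_id,
         ": both parents homozygous, outside the supported crossing scheme")
  if ((hom1 || hom2) && length(cohort$combos) <= 2L) {
    cs <- segregation_case("case2_hom_x_het")
    cs$hom_parent <- if (hom1) cohort$parent1 else cohort$parent2
  } else {
    cs <- segregation_case("case1_het_x_het")
    cs$hom_parent <- NA_character_
  }
  cs
}

#' Observed counts per expected offspring genotype class
#'
#' Enumerates the expected offspring genotype classes of the cohort's
#' parental cross, projects each class onto its observable label set
#' (untypable labels masked), and matches the cohort's observed
#' combinations against them. Combinations matching no expected class are
#' pooled as `unexpected`.
#'
#' @param cohort an `si_cohort`.
#' @param genotypes an `si_genotypes`.
#' @param catalog an `si_catalog`.
#' @param untypable labels unscorable in progeny.
#' @return list with `classes` (data.frame: `class` genotype key,
#'   `labels` observable key, `count`), `unexpected` (pooled count) and
#'   `n`.
#' @export
cohort_class_counts <- function(cohort, genotypes, catalog,
                                untypable = character()) {
  g1 <- geno_of(genotypes, cohort$parent1)
  g2 <- geno_of(genotypes, cohort$parent2)
  sets <- catalog_label_sets(catalog)
  cls <- expand.grid(h1 = unique(g1), h2 = unique(g2),
                     stringsAsFactors = FALSE)
  geno_key <- apply(cls, 1L, function(r) paste(sort(r), collapse = "/"))
  if (anyDuplicated(geno_key))
    stop("cohort ", cohort$cohort_id,
         ": parents share haplotypes producing coinciding offspring ",
         "genotype classes; outside the supported scheme")
  obs_key <- vapply(seq_len(nrow(cls)), function(i) {
    labs <- sort(setdiff(union(sets[[cls$h1[i]]], sets[[cls$h2[i]]]),
                         untypable))
    paste(labs, collapse = "+")
  }, "")
  if (anyDuplicated(obs_key))
    stop("cohort ", cohort$cohort_id,
         ": expected classes are indistinguishable after masking ",
         "untypable labels")
  combo_key <- vapply(cohort$combos, paste, "", collapse = "+")
  idx <- match(combo_key, obs_key)
  counts <- integer(length(obs_key))
  counts[idx[!is.na(idx)]] <- cohort$counts[!is.na(idx)]
  list(classes = data.frame(class = geno_key, labels = obs_key,
                            count = counts, stringsAsFactors = FALSE),
       unexpected = sum(cohort$counts[is.na(idx)]),
       n = cohort$n)
}

#' Simulate the null distribution of offspring class counts
#'
#' Draws `reps` cohorts of size `n` from the Mendelian multinomial of the
#' given case (0.25 x 4 or 0.5 x 2).
#'
#' @param n cohort size.
#' @param case a [segregation_case()] list.
#' @param reps number of simulated cohorts.
#' @param seed RNG seed (the caller's RNG state is left untouched).
#' @return integer matrix, `n_classes` rows x `reps` columns.
#' @export
simulate_null <- function(n, case, reps = 100000L, seed = 20131223L) {
  stopifnot(n >= 1L, reps >= 1L)
  with_seed(seed,
            stats::rmultinom(reps, size = n,
                             prob = rep(case$freq, case$n_classes)))
}

#' Monte-Carlo segregation test for one cohort
#'
#' Per expected class, a one-sided Monte-Carlo tail probability in the
#' direction of the observed deviation, with the add-one correction
#' `p = (1 + #simulated counts as-or-more extreme) / (reps + 1)`. A class
#' is flagged when `p < alpha`. Offspring in unexpected genotype classes
#' additionally reject the cross hypothesis (under the null they cannot
#' occur); the cohort conforms iff no class is flagged and no unexpected
#' offspring were observed.
#'
#' @param observed integer vector of counts per expected class (length 4
#'   for case 1, 2 for case 2).
#' @param case a [segregation_case()] list.
#' @param n cohort size; defaults to `sum(observed) + unexpected`.
#' @param unexpected count of offspring in unexpected classes.
#' @param reps,alpha,seed test parameters.
#' @return object of class `si_segresult`.
#' @export
test_cohort <- function(observed, case, n = NULL, unexpected = 0L,
                        reps = 100000L, alpha = 0.05, seed = 20131223L) {
  observed <- stats::setNames(as.integer(observed), names(observed))
  if (length(observed) != case$n_classes)
    stop("expected ", case$n_classes, " class counts, got ", length(observed))
  if (is.null(n)) n <- sum(observed) + unexpected
  if (sum(observed) + unexpected != n)
    stop("class counts (", sum(observed), ") + unexpected (", unexpected,
         ") do not sum to n = ", n)
  sims <- simulate_null(n, case, reps = reps, seed = seed)
  mu <- n * case$freq
  per_class_p <- vapply(seq_along(observed), function(j) {
    c_obs <- observed[j]
    extreme <- if (c_obs >= mu) sum(sims[j, ] >= c_obs)
               else sum(sims[j, ] <= c_obs)
    (1 + extreme) / (reps + 1)
  }, 0)
  names(per_class_p) <- names(observed) %||% paste0("class", seq_along(observed))
  flagged <- names(per_class_p)[per_class_p < alpha]
  ## under the null the expected classes are exhaustive, so simulated
  ## cohorts never contain an unexpected genotype
  extra_class_p <- if (unexpected > 0L) 1 / (reps + 1) else 1
  structure(list(case_id = case$case_id, n = n, observed = observed,
                 unexpected = unexpected, per_class_p = per_class_p,
                 flagged_classes = flagged, extra_class_p = extra_class_p,
                 conforms = length(flagged) == 0L && unexpected == 0L,
                 reps = reps, alpha = alpha, seed = seed),
            class = "si_segresult")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.si_segresult <- function(x, ...) {
  cat("Segregation test (", x$case_id, "), n = ", x$n, "\n", sep = "")
  cat("  observed: ", paste(x$observed, collapse = ", "),
      if (x$unexpected) paste0(" (+", x$unexpected, " unexpected)"), "\n",
      sep = "")
  cat("  per-class p: ", paste(signif(x$per_class_p, 3), collapse = ", "),
      "\n", sep = "")
  cat("  ", if (x$conforms) "conforms to Mendelian expectations"
      else paste0("deviates (", length(x$flagged_classes), " flagged class(es)",
                  if (x$unexpected) "; unexpected genotypes present", ")"),
      "\n", sep = "")
  invisible(x)
}

#' Segregation tests for a set of cohorts
#'
#' Applies [classify_case()], [cohort_class_counts()] and [test_cohort()]
#' to every cohort. Deterministic given `seed` (cohort `i` uses
#' `seed + i`).
#'
#' @param cohorts list of `si_cohort`.
#' @param genotypes an `si_genotypes`.
#' @param catalog an `si_catalog`.
#' @param untypable labels unscorable in progeny.
#' @param reps,alpha,seed test parameters.
#' @return data.frame summary (one row per cohort: `cohort_id`,
#'   `parent1`, `parent2`, `n`, `case`, `hom_parent`, `conforms`,
#'   `n_flagged`, `flagged_classes`, `unexpected`); full `si_segresult`
#'   objects in `attr(, "results")`.
#' @export
batch_test <- function(cohorts, genotypes, catalog, untypable = character(),
                       reps = 100000L, alpha = 0.05, seed = 20131223L) {
  results <- list()
  rows <- lapply(seq_along(cohorts), function(i) {
    co <- cohorts[[i]]
    cs <- classify_case(co, genotypes)
    cc <- cohort_class_counts(co, genotypes, catalog, untypable)
    obs <- stats::setNames(cc$classes$count, cc$classes$class)
    res <- test_cohort(obs, cs, n = cc$n, unexpected = cc$unexpected,
                       reps = reps, alpha = alpha, seed = seed + i)
    results[[co$cohort_id]] <<- res
    data.frame(cohort_id = co$cohort_id, parent1 = co$parent1,
               parent2 = co$parent2, n = co$n, case = cs$case_id,
               hom_parent = cs$hom_parent, conforms = res$conforms,
               n_flagged = length(res$flagged_classes),
               flagged_classes = paste(res$flagged_classes, collapse = ";"),
               unexpected = res$unexpected, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cohort_id = character(), parent1 = character(),
               parent2 = character(), n = integer(), case = character(),
               hom_parent = character(), conforms = logical(),
               n_flagged = integer(), flagged_classes = character(),
               unexpected = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
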