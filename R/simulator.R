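## Synthetic SSI data generator.
##
## Builds an S-locus ground truth (haplotypes carrying 1-2 linked sequence
## labels, a diploid panel, per-organ dominance ranks), then emits every
## observable layer of the study design: the F0 presence/absence typing
## matrix, offspring cohorts with Mendelian transmission, and diallel
## cross outcomes with pollination failure and SI leakage noise.

#' Simulation configuration
#'
#' Defaults are anchored to the study conditions the pipeline targets:
#' a panel of 21 individuals segregating 13 S-haplotypes of which 8 carry
#' a linked label pair, two homozygotes, 13 offspring cohorts, ~29% of
#' compatible pollinations failing to set fruit and ~9% of incompatible
#' pollinations leaking through.
#'
#' @param n_haplotypes number of S-haplotypes (>= 2).
#' @param paired_fraction fraction of haplotypes carrying two linked
#'   labels.
#' @param n_individuals panel size.
#' @param n_homozygotes individuals forced homozygous.
#' @param cohort_sizes integer vector, one offspring cohort per entry.
#' @param dominance per-organ dominance scheme: a character vector with
#'   entries `pollen` and `stigma`, each `"codominant"`, `"linear"` or
#'   `"class_levels"` (class A dominant over class B, codominance within
#'   a class).
#' @param pollination_failure_rate probability a compatible pollination
#'   sets no fruit.
#' @param si_leakage_rate probability an incompatible pollination sets
#'   fruit.
#' @param untypable_fraction fraction of labels unscorable in progeny
#'   (masked in cohort observations only, never in the F0 matrix).
#' @param replicate_count pollination replicates per ordered cross.
#' @param shared_label include one label shared between two haplotypes
#'   (only applied when `n_haplotypes >= 4`, to keep designs
#'   identifiable).
#' @param seed RNG seed for [simulate_locus()] / [emit_dataset()].
#' @return validated list of class `si_sim_config`.
#' @export
sim_config <- function(n_haplotypes = 13L,
                       paired_fraction = 8 / 13,
                       n_individuals = 21L,
                       n_homozygotes = 2L,
                       cohort_sizes = c(7L, 13L, 5L, 7L, 21L, 7L, 6L, 16L,
                                        14L, 30L, 30L, 50L, 14L),
                       dominance = c(pollen = "class_levels",
                                     stigma = "codominant"),
                       pollination_failure_rate = 0.29,
                       si_leakage_rate = 0.09,
                       untypable_fraction = 0,
                       replicate_count = 1L,
                       shared_label = TRUE,
                       seed = 1L) {
  stopifnot(n_haplotypes >= 2L,
            paired_fraction >= 0, paired_fraction <= 1,
            n_individuals >= 2L,
            n_homozygotes >= 0L, n_homozygotes <= n_individuals,
            pollination_failure_rate >= 0, pollination_failure_rate <= 1,
            si_leakage_rate >= 0, si_leakage_rate <= 1,
            untypable_fraction >= 0, untypable_fraction < 1,
            replicate_count >= 1L)
  if (!all(c("pollen", "stigma") %in% names(dominance)))
    stop("dominance must name both 'pollen' and 'stigma'")
  bad <- setdiff(dominance, c("codominant", "linear", "class_levels"))
  if (length(bad)) stop("unknown dominance scheme: ", paste(bad, collapse = ", "))
  if (round(paired_fraction * n_haplotypes) > 0 && n_haplotypes < 2L)
    stop("paired labels require at least 2 haplotypes")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 paired_fraction = paired_fraction,
                 n_individuals = as.integer(n_individuals),
                 n_homozygotes = as.integer(n_homozygotes),
                 cohort_sizes = as.integer(cohort_sizes),
                 dominance = dominance[c("pollen", "stigma")],
                 pollination_failure_rate = pollination_failure_rate,
                 si_leakage_rate = si_leakage_rate,
                 untypable_fraction = untypable_fraction,
                 replicate_count = as.integer(replicate_count),
                 shared_label = isTRUE(shared_label),
                 seed = as.integer(seed)),
            class = "si_sim_config")
}

#' Simulate an S-locus ground truth
#'
#' Builds the haplotype catalog (classes, linked label pairs, optionally
#' one A01-like label shared between two same-class haplotypes), samples
#' diploid genotypes for the panel (haplotype copies balanced, requested
#' homozygotes forced), instantiates per-organ dominance ranks, and picks
#' the untypable label set.
#'
#' @param config an [sim_config()].
#' @return object of class `si_truth`: list with `config`, `catalog`
#'   (haplotype, label1, label2, class_tag), `hap_labels`, `class_tags`,
#'   `genotypes` (`si_genotypes`), `ranks` (per organ, named numeric),
#'   `untypable`.
#' @export
simulate_locus <- function(config) {
  with_seed(config$seed, {
    nh <- config$n_haplotypes
    n_pair <- round(config$paired_fraction * nh)
    n_a <- max(1L, floor(nh / 2))
    classes <- c(rep("A", n_a), rep("B", nh - n_a))
    paired <- rep(FALSE, nh)
    paired[sample.int(nh, n_pair)] <- TRUE
    share <- config$shared_label && nh >= 4L && sum(paired & classes == "A") >= 2L
    if (config$shared_label && nh >= 4L && n_pair >= 2L && !share) {
      ## make room for an A-class shared pair
      paired[which(classes == "A")[1:2]] <- TRUE
      paired[which(paired & classes == "B")[seq_len(max(0, sum(paired) - n_pair))]] <- FALSE
      share <- sum(paired & classes == "A") >= 2L
    }
    counter <- c(A = 0L, B = 0L)
    new_label <- function(cl) {
      counter[cl] <<- counter[cl] + 1L
      sprintf("%s%02d", cl, counter[cl])
    }
    hap_labels <- vector("list", nh)
    for (i in seq_len(nh)) {
      cl <- classes[i]
      hap_labels[[i]] <- if (paired[i]) c(new_label(cl), new_label(cl))
                         else new_label(cl)
    }
    if (share) {
      duo <- which(paired & classes == "A")[1:2]
      ## second haplotype re-uses the first one's leading label
      freed <- hap_labels[[duo[2]]][1]
      hap_labels[[duo[2]]][1] <- hap_labels[[duo[1]]][1]
      hap_labels <- lapply(hap_labels, function(ls)
        sort(unique(ls)))
      ## drop the freed label entirely (relabel nothing else)
      hap_labels <- lapply(hap_labels, function(ls) setdiff(ls, freed))
    }
    hap_ids <- sprintf("T%02d", seq_len(nh))
    names(hap_labels) <- hap_ids
    catalog <- data.frame(
      haplotype = hap_ids,
      label1 = vapply(hap_labels, function(l) sort(l)[1], ""),
      label2 = vapply(hap_labels, function(l)
        if (length(l) == 2L) sort(l)[2] else NA_character_, ""),
      class_tag = classes, stringsAsFactors = FALSE)
    all_labels <- sort(unique(unlist(hap_labels)))
    class_tags <- stats::setNames(substr(all_labels, 1L, 1L), all_labels)
    ## genotypes: forced homozygotes, then balanced random pairing
    n_het <- config$n_individuals - config$n_homozygotes
    hom_haps <- sample(hap_ids, config$n_homozygotes,
                       replace = config$n_homozygotes > nh)
    pool <- rep(hap_ids, length.out = 2L * n_het)
    pool <- sample(pool)
    g1 <- pool[seq_len(n_het) * 2L - 1L]
    g2 <- pool[seq_len(n_het) * 2L]
    for (i in which(g1 == g2)) {     # avoid accidental homozygotes
      j <- which(g1 != g1[i] & g2 != g1[i])
      if (length(j)) {
        j <- j[1]
        tmp <- g2[i]; g2[i] <- g2[j]; g2[j] <- tmp
      }
    }
    genotypes <- data.frame(
      individual = sprintf("I%02d", seq_len(config$n_individuals)),
      hap1 = c(hom_haps, pmin(g1, g2)),
      hap2 = c(hom_haps, pmax(g1, g2)),
      stringsAsFactors = FALSE)
    genotypes$status <- ifelse(genotypes$hap1 == genotypes$hap2,
                               "putative_homozygote", "heterozygous")
    class(genotypes) <- c("si_genotypes", "data.frame")
    ranks <- lapply(config$dominance, function(scheme) {
      r <- switch(scheme,
                  codominant = rep(0, nh),
                  linear = sample(nh),
                  class_levels = ifelse(classes == "A", 2, 1))
      stats::setNames(as.numeric(r), hap_ids)
    })
    n_untyp <- round(config$untypable_fraction * length(all_labels))
    untypable <- if (n_untyp > 0L) sort(sample(all_labels, n_untyp))
                 else character()
    structure(list(config = config, catalog = catalog,
                   hap_labels = hap_labels, class_tags = class_tags,
                   genotypes = genotypes, ranks = ranks,
                   untypable = untypable),
              class = "si_truth")
  })
}

#' @export
print.si_truth <- function(x, ...) {
  cat("Simulated S-locus truth: ", nrow(x$catalog), " haplotypes (",
      sum(!is.na(x$catalog$label2)), " linked pairs) over ",
      length(x$class_tags), " labels; ", nrow(x$genotypes),
      " individuals\n", sep = "")
  invisible(x)
}

## haplotypes expressed by a genotype in one organ = those of maximal rank
expressed_haps <- function(truth, geno, organ) {
  haps <- unique(geno)
  r <- truth$ranks[[organ]][haps]
  haps[r == max(r)]
}

#' Latent compatibility of an ordered cross under the sporophytic rule
#'
#' @param truth an `si_truth`.
#' @param donor,receptor individual IDs.
#' @return `TRUE` if the cross is compatible (no haplotype both expressed
#'   in donor pollen and receptor stigma).
#' @export
latent_compatible <- function(truth, donor, receptor) {
  gd <- geno_of(truth$genotypes, donor)
  gr <- geno_of(truth$genotypes, receptor)
  length(intersect(expressed_haps(truth, gd, "pollen"),
                   expressed_haps(truth, gr, "stigma"))) == 0L
}

#' Simulate one (replicated) controlled pollination
#'
#' Compatible crosses set fruit with probability
#' `1 - pollination_failure_rate`; incompatible crosses with probability
#' `si_leakage_rate`. One row per replicate. Uses the current RNG state.
#'
#' @param donor,receptor individual IDs.
#' @param truth an `si_truth`.
#' @param config an `si_sim_config` (noise rates, replicate count).
#' @return `si_crosses` data.frame with `replicates = 1` rows.
#' @export
simulate_cross <- function(donor, receptor, truth, config) {
  compat <- latent_compatible(truth, donor, receptor)
  p_fruit <- if (compat) 1 - config$pollination_failure_rate
             else config$si_leakage_rate
  res <- ifelse(stats::runif(config$replicate_count) < p_fruit,
                "fruit", "no_fruit")
  crosses(rep(donor, length(res)), rep(receptor, length(res)), res, 1L)
}

#' Simulate one offspring cohort
#'
#' Each offspring receives one haplotype from each parent with
#' probability 0.5 (pure Mendelian transmission: all pollen of a donor
#' shares one sporophytic phenotype, so no SI filtering operates within a
#' compatible cross). The observed combination of an offspring is the
#' union of the typable labels of its two haplotypes. Uses the current
#' RNG state.
#'
#' @param parent1,parent2 individual IDs.
#' @param n cohort size.
#' @param truth an `si_truth`.
#' @param cohort_id identifier for the resulting cohort.
#' @return list with `cohort` (an `si_cohort`) and `transmitted`
#'   (n x 2 character matrix of the transmitted haplotypes).
#' @export
simulate_cohort <- function(parent1, parent2, n, truth,
                            cohort_id = "sim") {
  if (n < 1L) stop("cohort size must be >= 1")
  g1 <- geno_of(truth$genotypes, parent1)
  g2 <- geno_of(truth$genotypes, parent2)
  h1 <- g1[1L + (stats::runif(n) < 0.5)]
  h2 <- g2[1L + (stats::runif(n) < 0.5)]
  combos <- vapply(seq_len(n), function(i) {
    labs <- union(truth$hap_labels[[h1[i]]], truth$hap_labels[[h2[i]]])
    paste(sort(setdiff(labs, truth$untypable)), collapse = "+")
  }, "")
  tb <- table(combos)
  list(cohort = cohort_observation(cohort_id, parent1, parent2, n,
                                   strsplit(names(tb), "+", fixed = TRUE),
                                   as.integer(tb)),
       transmitted = cbind(h1, h2))
}

## pick cohort parent pairs greedily so that every haplotype is carried by
## some cohort parent (coverage maximization mirrors a crossing design
## that targets all incompatibility groups). Pairs whose parents share a
## sequence label are avoided when possible: a label carried by both
## parents cannot be attributed to either in the progeny, so such crosses
## are uninformative for phasing.
choose_cohort_parents <- function(truth, n_cohorts) {
  gt <- truth$genotypes
  ids <- gt$individual
  hap_of <- lapply(ids, function(id) unique(geno_of(gt, id)))
  names(hap_of) <- ids
  lab_of <- lapply(hap_of, function(h) unique(unlist(truth$hap_labels[h])))
  cand <- list(); disjoint <- logical()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    hom_i <- gt$status[i] != "heterozygous"
    hom_j <- gt$status[j] != "heterozygous"
    if (hom_i && hom_j) next                 # outside the crossing scheme
    if (!latent_compatible(truth, ids[i], ids[j])) next
    cand[[length(cand) + 1L]] <- c(ids[i], ids[j])
    disjoint[length(cand)] <-
      !length(intersect(lab_of[[ids[i]]], lab_of[[ids[j]]]))
  }
  if (!length(cand)) stop("no compatible parent pair available for cohorts")
  if (any(disjoint)) cand <- cand[disjoint]
  chosen <- list()
  covered <- character()
  used <- integer(length(cand))
  ## a homozygous parent transmits its labels to every offspring, which is
  ## uninformative for phasing, so only heterozygous parents count as
  ## covering their haplotypes
  het <- stats::setNames(gt$status == "heterozygous", ids)
  informative_haps <- function(pr)
    unique(c(if (het[pr[1]]) hap_of[[pr[1]]],
             if (het[pr[2]]) hap_of[[pr[2]]]))
  for (k in seq_len(n_cohorts)) {
    gain <- vapply(cand, function(pr)
      length(setdiff(informative_haps(pr), covered)), 0L)
    best <- which(gain == max(gain))
    pick_i <- best[which.min(used[best])]    # spread repeats across pairs
    pick <- cand[[pick_i]]
    used[pick_i] <- used[pick_i] + 1L
    chosen[[k]] <- pick
    covered <- union(covered, informative_haps(pick))
  }
  chosen
}

#' Emit a complete synthetic dataset
#'
#' Generates, reproducibly from the config seed, the F0 presence matrix
#' (untypable labels never masked here), the offspring cohorts (untypable
#' labels masked, as in progeny typing), and a full diallel cross table
#' with noise. When `dir` is given, everything is also written as CSV
#' (plus the ground truth as JSON) in a form readable by the `read_*`
#' functions.
#'
#' @param truth an `si_truth` from [simulate_locus()].
#' @param dir optional output directory.
#' @return list with `presence` (`si_presence`), `cohorts` (list of
#'   `si_cohort`), `crosses` (`si_crosses`), `transmitted` (per cohort),
#'   `truth`.
#' @export
emit_dataset <- function(truth, dir = NULL) {
  config <- truth$config
  gt <- truth$genotypes
  ids <- gt$individual
  labs <- names(truth$class_tags)
  mat <- matrix(FALSE, nrow = length(ids), ncol = length(labs),
                dimnames = list(ids, labs))
  for (id in ids) {
    g <- geno_of(gt, id)
    mat[id, unique(unlist(truth$hap_labels[g]))] <- TRUE
  }
  presence <- presence_matrix(mat, class_tags = truth$class_tags)
  out <- with_seed(config$seed + 1L, {
    parents <- choose_cohort_parents(truth, length(config$cohort_sizes))
    cohorts <- list(); transmitted <- list()
    for (k in seq_along(parents)) {
      cid <- sprintf("C%02d", k)
      sim <- simulate_cohort(parents[[k]][1], parents[[k]][2],
                             config$cohort_sizes[k], truth, cohort_id = cid)
      cohorts[[cid]] <- sim$cohort
      transmitted[[cid]] <- sim$transmitted
    }
    cross_rows <- list()
    for (d in ids) for (r in ids)
      cross_rows[[length(cross_rows) + 1L]] <-
        simulate_cross(d, r, truth, config)
    crosses_df <- do.call(rbind, cross_rows)
    class(crosses_df) <- c("si_crosses", "data.frame")
    list(cohorts = cohorts, transmitted = transmitted, crosses = crosses_df)
  })
  res <- list(presence = presence, cohorts = out$cohorts,
              crosses = out$crosses, transmitted = out$transmitted,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_presence_matrix(presence, file.path(dir, "presence.csv"))
    write_cohorts(out$cohorts, file.path(dir, "cohorts.csv"))
    write_crosses(out$crosses, file.path(dir, "crosses.csv"))
    jsonlite::write_json(
      list(catalog = truth$catalog,
           genotypes = as.data.frame(gt),
           ranks = truth$ranks,
           untypable = truth$untypable,
           seed = config$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
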