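test_that("simulation configs are validated and the locus is reproducible", {
  expect_error(sim_config(n_haplotypes = 1), "n_haplotypes")
  expect_error(sim_config(pollination_failure_rate = 1.5))
  expect_error(sim_config(dominance = c(pollen = "magic",
                                        stigma = "codominant")),
               "unknown dominance")
  cfg <- sim_config(seed = 5L)
  t1 <- simulate_locus(cfg)
  t2 <- simulate_locus(cfg)
  expect_identical(t1$catalog, t2$catalog)
  expect_identical(t1$genotypes, t2$genotypes)
  expect_identical(t1$ranks, t2$ranks)

  ## the default preset mirrors the study design: 13 haplotypes, 8 linked
  ## pairs, one shared label -> 20 labels, 21 individuals, 2 homozygotes
  expect_equal(nrow(t1$catalog), 13L)
  expect_equal(sum(!is.na(t1$catalog$label2)), 8L)
  expect_equal(length(t1$class_tags), 20L)
  expect_equal(nrow(t1$genotypes), 21L)
  expect_equal(sum(t1$genotypes$hap1 == t1$genotypes$hap2), 2L)

  ## paired_fraction 0 -> all singleton haplotypes
  t0 <- simulate_locus(sim_config(n_haplotypes = 5, paired_fraction = 0,
                                  n_individuals = 10, n_homozygotes = 0,
                                  shared_label = FALSE, seed = 2L))
  expect_true(all(is.na(t0$catalog$label2)))
})

test_that("cross simulation follows the sporophytic rule and noise rates", {
  ## no noise: self-cross under codominance never fruits; a donor whose
  ## shared haplotype is pollen-recessive fruits
  cfg <- sim_config(n_haplotypes = 4, paired_fraction = 0,
                    n_individuals = 8, n_homozygotes = 0,
                    cohort_sizes = 10L,
                    dominance = c(pollen = "linear", stigma = "codominant"),
                    pollination_failure_rate = 0, si_leakage_rate = 0,
                    shared_label = FALSE, replicate_count = 3L, seed = 3L)
  tr <- simulate_locus(cfg)
  id1 <- tr$genotypes$individual[1]
  out_self <- with_seed(1L, simulate_cross(id1, id1, tr, cfg))
  expect_true(all(out_self$result == "no_fruit"))

  ## two individuals sharing one haplotype that is pollen-recessive in
  ## the donor: compatible when the recessive side donates
  gt <- tr$genotypes
  ranks <- tr$ranks$pollen
  found <- FALSE
  for (i in seq_len(nrow(gt))) for (j in seq_len(nrow(gt))) {
    if (i == j) next
    gi <- c(gt$hap1[i], gt$hap2[i]); gj <- c(gt$hap1[j], gt$hap2[j])
    sh <- intersect(gi, gj)
    if (length(sh) == 1L && ranks[sh] < max(ranks[gi]) && !found) {
      found <- TRUE
      expect_true(latent_compatible(tr, gt$individual[i], gt$individual[j]))
      out <- with_seed(2L, simulate_cross(gt$individual[i],
                                          gt$individual[j], tr, cfg))
      expect_true(all(out$result == "fruit"))
    }
  }
  expect_true(found)

  ## noise rates: fruit fraction of compatible crosses ~ 1 - failure
  cfgn <- sim_config(n_haplotypes = 4, paired_fraction = 0,
                     n_individuals = 8, n_homozygotes = 0,
                     cohort_sizes = 10L,
                     pollination_failure_rate = 0.29, si_leakage_rate = 0.09,
                     shared_label = FALSE, replicate_count = 1L, seed = 3L)
  trn <- simulate_locus(cfgn)
  ids <- trn$genotypes$individual
  pair <- NULL
  for (i in ids) for (j in ids)
    if (i != j && latent_compatible(trn, i, j) && is.null(pair))
      pair <- c(i, j)
  n <- 10000L
  fruits <- with_seed(4L, {
    cfg_many <- cfgn; cfg_many$replicate_count <- n
    sum(simulate_cross(pair[1], pair[2], trn, cfg_many)$result == "fruit")
  })
  expect_lt(abs(fruits / n - 0.71), 3 * sqrt(0.71 * 0.29 / n))
})

test_that("cohort transmission is Mendelian", {
  cfg <- sim_config(n_haplotypes = 4, paired_fraction = 0.5,
                    n_individuals = 8, n_homozygotes = 1,
                    cohort_sizes = 10L,
                    pollination_failure_rate = 0, si_leakage_rate = 0,
                    shared_label = FALSE, seed = 6L)
  tr <- simulate_locus(cfg)
  gt <- tr$genotypes
  hets <- gt$individual[gt$status == "heterozygous"]
  hom <- gt$individual[gt$status != "heterozygous"][1]
  ## pick two heterozygotes with four distinct haplotypes
  pair <- NULL
  for (i in hets) for (j in hets)
    if (is.null(pair) &&
        !length(intersect(geno_of(gt, i), geno_of(gt, j))))
      pair <- c(i, j)

  ## hom x het -> exactly two observable classes
  sim2 <- with_seed(8L, simulate_cohort(hom, pair[1], 60L, tr))
  expect_lte(length(sim2$cohort$combos), 2L)

  ## het x het, many offspring: four classes, counts ~ n/4, and class
  ## counts over repeated cohorts fit multinomial(n, 0.25 x 4)
  pooled <- with_seed(9L, {
    acc <- numeric(0)
    for (r in 1:300) {
      sim <- simulate_cohort(pair[1], pair[2], 20L, tr)
      key <- vapply(sim$cohort$combos, paste, "", collapse = "+")
      for (k in seq_along(key))
        acc[key[k]] <- sum(acc[key[k]], sim$cohort$counts[k], na.rm = TRUE)
    }
    acc
  })
  expect_length(pooled, 4L)
  ## chi-square goodness of fit on the pooled class totals
  gof <- stats::chisq.test(as.numeric(pooled), p = rep(0.25, 4))
  expect_gt(gof$p.value, 0.001)
  ## transmitted haplotypes recorded for every offspring
  sim <- with_seed(10L, simulate_cohort(pair[1], pair[2], 15L, tr))
  expect_equal(nrow(sim$transmitted), 15L)
  expect_true(all(sim$transmitted[, 1] %in% geno_of(gt, pair[1])))
  expect_error(simulate_cohort(pair[1], pair[2], 0L, tr), ">= 1")
})

test_that("emitted datasets round-trip through the readers", {
  cfg <- sim_config(n_haplotypes = 5, paired_fraction = 0.4,
                    n_individuals = 12, n_homozygotes = 1,
                    cohort_sizes = c(15L, 15L, 15L),
                    untypable_fraction = 0.15,
                    pollination_failure_rate = 0, si_leakage_rate = 0,
                    seed = 11L)
  tr <- simulate_locus(cfg)
  dir <- tempfile()
  ds <- emit_dataset(tr, dir = dir)
  ## deterministic re-emission
  ds2 <- emit_dataset(tr)
  expect_identical(ds$presence$mat, ds2$presence$mat)
  expect_identical(lapply(ds$cohorts, unclass),
                   lapply(ds2$cohorts, unclass))
  expect_identical(as.data.frame(ds$crosses), as.data.frame(ds2$crosses))

  ## untypable labels masked in cohorts but present in the F0 matrix
  if (length(tr$untypable)) {
    expect_true(all(tr$untypable %in% si_labels(ds$presence)))
    in_cohorts <- unique(unlist(lapply(ds$cohorts, function(co)
      unlist(co$combos))))
    expect_false(any(tr$untypable %in% in_cohorts))
  }

  ## files written and readable
  pm <- read_presence_matrix(file.path(dir, "presence.csv"))
  expect_equal(pm$mat, ds$presence$mat)
  cohorts <- read_cohorts(file.path(dir, "cohorts.csv"), pm)
  expect_equal(length(cohorts), 3L)
  crs <- read_crosses(file.path(dir, "crosses.csv"), pm)
  expect_equal(nrow(crs), nrow(ds$crosses))
  truth_json <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth_json$catalog), nrow(tr$catalog))
})

test_that("zero-noise pipeline recovers the simulated truth end to end", {
  cfg <- sim_config(n_haplotypes = 6, paired_fraction = 0.5,
                    n_individuals = 18, n_homozygotes = 1,
                    cohort_sizes = rep(25L, 6),
                    dominance = c(pollen = "linear", stigma = "codominant"),
                    pollination_failure_rate = 0, si_leakage_rate = 0,
                    seed = 13L)
  tr <- simulate_locus(cfg)
  ds <- emit_dataset(tr)
  pairs <- infer_linked_pairs(ds$presence, ds$cohorts, tr$untypable)
  catal <- build_catalog(pairs, ds$presence)
  expect_equal(sort(catalog_keys(catal)), truth_catalog_keys(tr))
  gt <- assign_genotypes(ds$presence, catal)
  ## every individual's genotype matches the simulated one (via label sets)
  key_of <- stats::setNames(catalog_keys(catal), catal$haplotype)
  for (i in seq_len(nrow(tr$genotypes))) {
    id <- tr$genotypes$individual[i]
    truth_keys <- sort(unname(
      vapply(unique(unlist(tr$genotypes[i, c("hap1", "hap2")])),
             function(h) paste(sort(tr$hap_labels[[h]]), collapse = "+"),
             "")))
    got <- sort(unique(unname(key_of[geno_of(gt, id)])))
    expect_equal(got, truth_keys, label = id)
  }
  ## compatibility predictions from inferred expression are sound
  cons <- consolidate_crosses(ds$crosses, tr$genotypes)
  ex <- infer_expression(cons, tr$genotypes)
  ids <- tr$genotypes$individual
  for (d in ids[1:6]) for (r in ids[1:6]) {
    p <- predict_compatibility(geno_of(tr$genotypes, d),
                               geno_of(tr$genotypes, r), ex)
    if (p != "undetermined")
      expect_equal(p == "compatible", latent_compatible(tr, d, r),
                   label = paste(d, "->", r))
  }
})
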