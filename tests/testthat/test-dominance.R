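## small genotype table used across dominance tests
worked_genotypes <- function() {
  structure(data.frame(individual = c("3", "4"),
                       hap1 = c("S01", "S01"),
                       hap2 = c("S01", "S02"),
                       status = c("confirmed_homozygote", "heterozygous"),
                       stringsAsFactors = FALSE),
            class = c("si_genotypes", "data.frame"))
}

test_that("cross consolidation merges replicates and genotype duplicates", {
  gt <- structure(data.frame(individual = c("a", "b", "c"),
                             hap1 = c("S01", "S01", "S03"),
                             hap2 = c("S02", "S02", "S04"),
                             status = "heterozygous",
                             stringsAsFactors = FALSE),
                  class = c("si_genotypes", "data.frame"))
  cr <- crosses(donor = c("a", "b", "a", "a"),
                receptor = c("c", "c", "c", "b"),
                result = c("no_fruit", "no_fruit", "no_fruit", "not_done"),
                replicates = c(2L, 1L, 1L, 1L))
  cons <- consolidate_crosses(cr, gt)
  ## a->c, b->c and the replicate all merge into one genotype pair
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$outcome, "incompatible")
  expect_equal(cons$n_no_fruit, 4L)

  ## mixed outcomes: strict -> conflicting; majority follows the majority
  cr2 <- crosses(c("a", "a", "a"), c("c", "c", "c"),
                 c("fruit", "no_fruit", "no_fruit"), 1L)
  expect_equal(consolidate_crosses(cr2, gt)$outcome, "conflicting")
  expect_equal(consolidate_crosses(cr2, gt, method = "majority")$outcome,
               "incompatible")
  ## ungenotyped individual
  expect_error(consolidate_crosses(crosses("z", "a", "fruit", 1), gt),
               "not genotyped")
})

test_that("the individual 3/4 worked example resolves organ-specific dominance", {
  gt <- worked_genotypes()
  cr <- read_crosses(silocus_example("worked_example_crosses.csv"))
  cons <- consolidate_crosses(cr, gt)
  ex <- infer_expression(cons, gt)
  st <- function(g, o, h) ex$state[ex$genotype == g & ex$organ == o &
                                     ex$haplotype == h]
  ## S01 silenced in pollen of the heterozygote, expressed in its stigma
  expect_equal(st("S01/S02", "pollen", "S01"), "silenced")
  expect_equal(st("S01/S02", "stigma", "S01"), "expressed")
  ## the homozygote expresses S01 in both organs
  expect_equal(st("S01/S01", "pollen", "S01"), "expressed")
  expect_equal(st("S01/S01", "stigma", "S01"), "expressed")
  ## S02 carries the heterozygote's pollen specificity
  expect_equal(st("S01/S02", "pollen", "S02"), "expressed")
  expect_length(attr(ex, "unexplained"), 0L)

  ## both directed outcomes are reproduced
  expect_equal(predict_compatibility(c("S01", "S02"), c("S01", "S01"), ex),
               "compatible")
  expect_equal(predict_compatibility(c("S01", "S01"), c("S01", "S02"), ex),
               "incompatible")

  dom <- build_dominance(ex)
  expect_equal(dom$relations$dominant, "S02")
  expect_equal(dom$relations$recessive, "S01")
  expect_equal(dom$relations$organ, "pollen")
  ## stigma: both expressed -> codominant
  expect_true(any(dom$codominant$organ == "stigma" &
                    dom$codominant$genotype == "S01/S02"))
  expect_length(unlist(dom$cycles), 0L)
})

test_that("a lone self-incompatible heterozygote stays ambiguous but never compatible", {
  gt <- structure(data.frame(individual = "a", hap1 = "X", hap2 = "Y",
                             status = "heterozygous",
                             stringsAsFactors = FALSE),
                  class = c("si_genotypes", "data.frame"))
  cons <- consolidate_crosses(crosses("a", "a", "no_fruit", 1), gt)
  ex <- infer_expression(cons, gt)
  expect_true(all(ex$state == "ambiguous"))
  expect_equal(predict_compatibility(c("X", "Y"), c("X", "Y"), ex),
               "undetermined")
})

test_that("contradictory evidence surfaces as conflicts, never silent flips", {
  ## a = X/X, b = X/Y, c = Y/Y; both of b's pollen haplotypes are forced
  ## silenced by compatible crosses onto the homozygotes, yet b is
  ## self-incompatible: the contradiction must surface as a conflicting
  ## cell or an unexplained incompatibility, and no cell may end up
  ## claiming an outcome that contradicts a derivation
  gt <- structure(data.frame(individual = c("a", "b", "c"),
                             hap1 = c("X", "X", "Y"),
                             hap2 = c("X", "Y", "Y"),
                             status = c("putative_homozygote",
                                        "heterozygous",
                                        "putative_homozygote"),
                             stringsAsFactors = FALSE),
                  class = c("si_genotypes", "data.frame"))
  cr <- crosses(donor = c("a", "c", "b", "b", "b"),
                receptor = c("a", "c", "b", "a", "c"),
                result = c("no_fruit", "no_fruit", "no_fruit",
                           "fruit", "fruit"), 1L)
  ex <- infer_expression(consolidate_crosses(cr, gt), gt)
  expect_true(any(ex$state == "conflicting") ||
                length(attr(ex, "unexplained")) > 0)
  ## replicate-level contradictions are caught earlier: strict
  ## consolidation marks the mixed pair conflicting and excludes it
  cr2 <- crosses(c("b", "b"), c("a", "a"), c("fruit", "no_fruit"), 1L)
  cons2 <- consolidate_crosses(cr2, gt)
  expect_equal(cons2$outcome, "conflicting")
})

test_that("compatibility prediction equals brute-force enumeration", {
  ## random complete expression tables over 4 haplotypes: the prediction
  ## must equal the direct set-intersection rule; with ambiguous cells it
  ## must equal the consensus over all completions
  haps <- c("A", "B", "C", "D")
  genos <- c(utils::combn(haps, 2, paste, collapse = "/"),
             paste(haps, haps, sep = "/"))
  enumerate_outcome <- function(expr, gd, gr) {
    shared <- intersect(strsplit(gd, "/")[[1]], strsplit(gr, "/")[[1]])
    shared <- unique(shared)
    if (!length(shared)) return("compatible")
    cell <- function(g, o, h) expr$state[expr$genotype == g &
                                           expr$organ == o &
                                           expr$haplotype == h]
    options <- list(expressed = "expressed", silenced = "silenced",
                    ambiguous = c("expressed", "silenced"))
    ## completions of the relevant cells only
    combos <- expand.grid(lapply(shared, function(h)
      seq_along(options[[cell(gd, "pollen", h)]])), KEEP.OUT.ATTRS = FALSE)
    combos2 <- expand.grid(lapply(shared, function(h)
      seq_along(options[[cell(gr, "stigma", h)]])), KEEP.OUT.ATTRS = FALSE)
    outcomes <- character()
    for (i in seq_len(nrow(combos))) for (j in seq_len(nrow(combos2))) {
      inc <- FALSE
      for (k in seq_along(shared)) {
        p <- options[[cell(gd, "pollen", shared[k])]][combos[i, k]]
        s <- options[[cell(gr, "stigma", shared[k])]][combos2[j, k]]
        if (p == "expressed" && s == "expressed") inc <- TRUE
      }
      outcomes <- union(outcomes, if (inc) "incompatible" else "compatible")
    }
    if (length(outcomes) == 1L) outcomes else "undetermined"
  }
  set.seed(2718)
  for (rep in 1:20) {
    rows <- do.call(rbind, lapply(genos, function(g) {
      hs <- unique(strsplit(g, "/")[[1]])
      expand.grid(genotype = g, organ = c("pollen", "stigma"),
                  haplotype = hs, stringsAsFactors = FALSE)
    }))
    rows$state <- sample(c("expressed", "silenced", "ambiguous"),
                         nrow(rows), replace = TRUE, prob = c(.5, .3, .2))
    class(rows) <- c("si_expression", "data.frame")
    for (gd in genos) for (gr in genos)
      expect_equal(predict_compatibility(gd, gr, rows),
                   enumerate_outcome(rows, gd, gr),
                   label = paste(rep, gd, "->", gr))
  }
  ## uncovered genotype -> undetermined
  expect_equal(predict_compatibility("Z/Z", genos[1],
                                     structure(data.frame(
                                       genotype = character(),
                                       organ = character(),
                                       haplotype = character(),
                                       state = character()),
                                       class = c("si_expression",
                                                 "data.frame"))),
               "undetermined")
})

test_that("identical genotypes under full codominance are self-incompatible", {
  rows <- expand.grid(genotype = "X/Y", organ = c("pollen", "stigma"),
                      haplotype = c("X", "Y"), stringsAsFactors = FALSE)
  rows$state <- "expressed"
  class(rows) <- c("si_expression", "data.frame")
  expect_equal(predict_compatibility("X/Y", "X/Y", rows), "incompatible")
})

test_that("compatibility summaries report shared/non-shared and class rates", {
  gt <- structure(data.frame(individual = c("a", "b", "c"),
                             hap1 = c("H01", "H01", "H03"),
                             hap2 = c("H02", "H02", "H04"),
                             status = "heterozygous",
                             stringsAsFactors = FALSE),
                  class = c("si_genotypes", "data.frame"))
  catal <- structure(data.frame(haplotype = c("H01", "H02", "H03", "H04"),
                                label1 = c("A01", "A02", "B01", "B02"),
                                label2 = NA_character_,
                                class_tag = c("A", "A", "B", "B"),
                                support = "singleton",
                                name = c("H01", "H02", "H03", "H04"),
                                stringsAsFactors = FALSE),
                     class = c("si_catalog", "data.frame"))
  cr <- crosses(donor = c("a", "a", "b"), receptor = c("b", "c", "c"),
                result = c("no_fruit", "fruit", "fruit"),
                replicates = c(2L, 1L, 1L))
  sm <- summarize_compatibility(cr, gt, catal)
  shared <- sm$overall[sm$overall$group == "shared_haplotype", ]
  expect_equal(shared$pollinations, 2L)
  expect_equal(shared$rate, 0)
  ctrl <- sm$overall[sm$overall$group == "no_shared_haplotype", ]
  expect_equal(ctrl$rate, 1)
  expect_equal(sm$per_class$class_tag, "A")
  expect_equal(sm$per_class$rate, 0)
  ## all not_done -> empty summary
  sm0 <- summarize_compatibility(crosses("a", "b", "not_done", NA), gt, catal)
  expect_equal(nrow(sm0$per_haplotype), 0L)
})
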