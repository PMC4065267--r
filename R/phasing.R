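## S-haplotype phasing from presence/absence typing + cohort co-segregation.
##
## A diploid individual carries two S-haplotypes; a haplotype carries one
## or two tightly linked sequence labels. Within an offspring cohort, the
## labels of one parental haplotype are transmitted together, so labels
## with identical transmission patterns across a cohort cluster into that
## parent's two haplotypes. Labels untypable in progeny can still be tied
## to a partner by perfect association across the parental panel.

#' Transmission vectors of one parent's labels across a cohort
#'
#' For every typable label carried by `parent`, the pattern of
#' presence/absence across the offspring combination classes of `cohort`.
#' A label carried by *both* parents cannot be attributed to either, and
#' is marked missing (`NA`) at every position rather than guessed.
#'
#' @param cohort an `si_cohort`.
#' @param parent one of the two parent IDs of the cohort.
#' @param presence an `si_presence`.
#' @param untypable character vector of labels that cannot be scored in
#'   progeny (they never receive a transmission vector).
#' @return object of class `si_transvec`: list with `parent`, `labels`,
#'   `mat` (labels x combination classes, logical with `NA` for
#'   unattributable positions) and `counts` (offspring per class).
#' @export
transmission_vectors <- function(cohort, parent, presence,
                                 untypable = character()) {
  if (!parent %in% c(cohort$parent1, cohort$parent2))
    stop("individual ", parent, " is not a parent of cohort ", cohort$cohort_id)
  other <- if (parent == cohort$parent1) cohort$parent2 else cohort$parent1
  p_lab <- labels_of(presence, parent)
  o_lab <- if (other == parent) p_lab else labels_of(presence, other)
  typable <- setdiff(p_lab, untypable)
  if (!length(typable))
    stop("parent ", parent, " has no typable label in cohort ",
         cohort$cohort_id)
  mat <- matrix(NA, nrow = length(typable), ncol = length(cohort$combos),
                dimnames = list(typable, NULL))
  for (lab in typable) {
    if (lab %in% o_lab) next        # shared between parents: stays NA
    mat[lab, ] <- vapply(cohort$combos, function(cb) lab %in% cb, TRUE)
  }
  if (all(is.na(mat)))
    stop("no informative offspring for parent ", parent, " in cohort ",
         cohort$cohort_id, " (all labels shared with the other parent)")
  structure(list(parent = parent, cohort_id = cohort$cohort_id,
                 labels = typable, mat = mat, counts = cohort$counts),
            class = "si_transvec")
}

#' Cluster co-transmitted labels of one parent
#'
#' Labels with identical transmission patterns (on shared non-missing
#' positions) are grouped; under faithful typing the groups are the
#' parent's two haplotypes. A label present in every informative offspring
#' is compatible with membership in *both* haplotypes (the shared-label
#' case) and is attached to every group; a label seen in *no* offspring is
#' uninformative (its haplotype may simply never have been transmitted)
#' and is set aside. More than two residual groups, or two
#' non-complementary groups, violate diploid transmission and flag the
#' cohort as inconsistent instead of forcing a partition.
#'
#' @param tv an `si_transvec` from [transmission_vectors()].
#' @return list with `groups` (list of label sets, at most 2), `shared`
#'   (all-present labels), `untransmitted` (all-absent labels),
#'   `possibly_homozygous` and `inconsistent` flags.
#' @export
cluster_cotransmitted <- function(tv) {
  mat <- tv$mat
  informative <- rownames(mat)[rowSums(!is.na(mat)) > 0]
  res <- list(groups = list(), shared = character(),
              untransmitted = character(),
              possibly_homozygous = FALSE, inconsistent = FALSE)
  if (!length(informative)) return(res)
  m <- mat[informative, , drop = FALSE]
  all1 <- apply(m, 1L, function(p) all(p[!is.na(p)]))
  all0 <- apply(m, 1L, function(p) !any(p[!is.na(p)]))
  res$shared <- informative[all1]
  res$untransmitted <- informative[all0]
  core <- informative[!all1 & !all0]
  if (!length(core)) {
    ## every informative label transmitted to all offspring: consistent
    ## with a homozygous parent (or a single visible haplotype)
    if (length(res$shared)) {
      res$groups <- list(res$shared)
      res$possibly_homozygous <- TRUE
      res$shared <- character()
    }
    return(res)
  }
  ## connected components under "identical on jointly non-missing positions"
  k <- length(core)
  comp <- seq_len(k)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    a <- m[core[i], ]; b <- m[core[j], ]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok) && all(a[ok] == b[ok]))
      comp[comp == comp[j]] <- comp[i]
  }
  groups <- split(core, comp)
  names(groups) <- NULL
  if (length(groups) > 2L) {
    res$inconsistent <- TRUE
    res$groups <- groups
    return(res)
  }
  if (length(groups) == 2L) {
    a <- m[groups[[1]][1], ]; b <- m[groups[[2]][1], ]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok) && !all(xor(a[ok], b[ok]))) {
      ## both haplotype groups present/absent together in some offspring:
      ## not a diploid transmission pattern
      res$inconsistent <- TRUE
      res$groups <- groups
      return(res)
    }
  }
  res$groups <- lapply(groups, function(g) sort(c(g, res$shared)))
  res
}

#' Infer linked sequence-label pairs
#'
#' Combines co-segregation evidence from offspring cohorts with perfect
#' association across the parental panel. A pair is supported by
#' `cosegregation` when some parent's transmission clustering puts the two
#' labels in the same haplotype group and no cohort separates them.
#' A pair never tested in any cohort (typically because one label is
#' untypable in progeny) is supported by `f0_association_only` when the
#' two labels co-occur in at least one individual and no individual
#' carries exactly one of them.
#'
#' @param presence an `si_presence`.
#' @param cohorts list of `si_cohort`.
#' @param untypable labels unscorable in progeny.
#' @return object of class `si_linked_pairs`: data.frame with columns
#'   `label1`, `label2`, `support`; attribute `flags` lists cohorts whose
#'   clustering was inconsistent.
#' @export
infer_linked_pairs <- function(presence, cohorts, untypable = character()) {
  bad <- setdiff(untypable, si_labels(presence))
  if (length(bad))
    stop("untypable label(s) not in presence matrix: ",
         paste(bad, collapse = ", "))
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  cogrouped <- list(); separated <- list(); tested <- character()
  flags <- character()
  for (co in cohorts) {
    for (parent in unique(c(co$parent1, co$parent2))) {
      typable <- setdiff(labels_of(presence, parent), untypable)
      if (length(typable) < 2L) next
      tv <- tryCatch(transmission_vectors(co, parent, presence, untypable),
                     error = function(e) NULL)
      if (is.null(tv)) next
      cl <- cluster_cotransmitted(tv)
      if (cl$inconsistent) {
        flags <- c(flags, paste0(co$cohort_id, ":", parent))
        next
      }
      if (cl$possibly_homozygous || !length(cl$groups)) next
      informative <- setdiff(unlist(cl$groups), NULL)
      ## every label pair jointly carried and informatively clustered here
      ## counts as tested
      for (pr in pairs_of(informative)) tested[pair_key(pr[1], pr[2])] <-
        pair_key(pr[1], pr[2])
      for (g in cl$groups) for (pr in pairs_of(g)) {
        key <- pair_key(pr[1], pr[2])
        cogrouped[[key]] <- union(cogrouped[[key]], co$cohort_id)
      }
      if (length(cl$groups) == 2L) {
        g1 <- cl$groups[[1]]; g2 <- cl$groups[[2]]
        for (a in setdiff(g1, g2)) for (b in setdiff(g2, g1)) {
          key <- pair_key(a, b)
          separated[[key]] <- union(separated[[key]], co$cohort_id)
        }
      }
    }
  }
  contradicted <- intersect(names(cogrouped), names(separated))
  if (length(contradicted)) {
    msg <- vapply(contradicted, function(k)
      paste0(gsub("\r", "-", k), " (co-grouped in ",
             paste(cogrouped[[k]], collapse = ","), "; separated in ",
             paste(separated[[k]], collapse = ","), ")"), "")
    stop("contradictory linkage evidence for pair(s): ",
         paste(msg, collapse = "; "))
  }
  coseg <- names(cogrouped)
  ## F0 perfect association for pairs never tested in a cohort
  mat <- presence$mat
  labs <- colnames(mat)
  f0 <- character()
  if (length(labs) >= 2L) {
    cmb <- utils::combn(sort(labs), 2L)
    for (i in seq_len(ncol(cmb))) {
      a <- cmb[1, i]; b <- cmb[2, i]
      key <- pair_key(a, b)
      if (key %in% coseg || key %in% tested || key %in% names(separated)) next
      both <- mat[, a] & mat[, b]
      one <- xor(mat[, a], mat[, b])
      if (any(both) && !any(one)) f0 <- c(f0, key)
    }
  }
  keys <- c(coseg, f0)
  out <- data.frame(
    label1 = vapply(strsplit(keys, "\r"), `[[`, "", 1L),
    label2 = vapply(strsplit(keys, "\r"), `[[`, "", 2L),
    support = c(rep("cosegregation", length(coseg)),
                rep("f0_association_only", length(f0))),
    stringsAsFactors = FALSE)
  out <- out[order(out$label1, out$label2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flags") <- unique(flags)
  class(out) <- c("si_linked_pairs", "data.frame")
  out
}

pairs_of <- function(v) {
  v <- sort(unique(v))
  if (length(v) < 2L) return(list())
  cmb <- utils::combn(v, 2L)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

#' Build the S-haplotype catalog
#'
#' Every linked pair becomes a two-label haplotype; every label belonging
#' to no pair becomes a single-label haplotype. A label may sit in two
#' haplotypes (two pairs sharing it). Haplotype IDs are deterministic:
#' haplotypes are sorted by (class tag of the first label, first label,
#' second label) and numbered `H01`, `H02`, ...; `name_map` can overlay
#' external names (e.g. the S01--S13 convention), keyed by the
#' `+`-joined sorted label set.
#'
#' @param pairs an `si_linked_pairs` (or data.frame with `label1`,
#'   `label2`, `support`).
#' @param presence an `si_presence` supplying the label universe and
#'   class tags.
#' @param name_map optional named character vector, e.g.
#'   `c("B10+B11" = "S01")`.
#' @return object of class `si_catalog`: data.frame with columns
#'   `haplotype`, `label1`, `label2` (`NA` for singletons), `class_tag`,
#'   `support`, `name`.
#' @export
build_catalog <- function(pairs, presence, name_map = NULL) {
  labs <- si_labels(presence)
  tags <- presence$class_tags
  if (is.null(tags)) tags <- stats::setNames(rep("", length(labs)), labs)
  paired <- unique(c(pairs$label1, pairs$label2))
  unknown <- setdiff(paired, labs)
  if (length(unknown))
    stop("linked pairs reference unknown label(s): ",
         paste(unknown, collapse = ", "))
  singles <- setdiff(labs, paired)
  df <- rbind(
    data.frame(label1 = pmin(pairs$label1, pairs$label2),
               label2 = pmax(pairs$label1, pairs$label2),
               support = pairs$support, stringsAsFactors = FALSE),
    if (length(singles))
      data.frame(label1 = singles, label2 = NA_character_,
                 support = "singleton", stringsAsFactors = FALSE))
  df$class_tag <- unname(tags[df$label1])
  df <- df[order(df$class_tag, df$label1, df$label2, na.last = TRUE), ,
           drop = FALSE]
  df <- data.frame(haplotype = sprintf("H%02d", seq_len(nrow(df))), df,
                   stringsAsFactors = FALSE)
  key <- ifelse(is.na(df$label2), df$label1,
                paste(df$label1, df$label2, sep = "+"))
  df$name <- if (!is.null(name_map)) unname(name_map[key]) else df$haplotype
  rownames(df) <- NULL
  class(df) <- c("si_catalog", "data.frame")
  df
}

#' @export
print.si_catalog <- function(x, ...) {
  cat("S-haplotype catalog: ", nrow(x), " haplotypes over ",
      length(stats::na.omit(unique(c(x$label1, x$label2)))), " labels\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

catalog_label_sets <- function(catalog) {
  stats::setNames(lapply(seq_len(nrow(catalog)), function(i)
    stats::na.omit(c(catalog$label1[i], catalog$label2[i]))),
    catalog$haplotype)
}

#' Assign diploid S-locus genotypes
#'
#' Explains each individual's label set by exactly one or two catalog
#' haplotypes (exact cover: the union of the assigned haplotypes' labels
#' must equal the observed set). Individuals explained by a single
#' haplotype are flagged `putative_homozygote` -- never silently doubled;
#' confirmation to `confirmed_homozygote` requires a conforming
#' homozygote-by-heterozygote segregation result
#' (see [confirm_homozygotes()]). Labels belonging to two haplotypes are
#' disambiguated by which partner labels are present.
#'
#' @param presence an `si_presence`.
#' @param catalog an `si_catalog` covering all labels.
#' @return object of class `si_genotypes`: data.frame with columns
#'   `individual`, `hap1`, `hap2`, `status` (`heterozygous`,
#'   `putative_homozygote`, `confirmed_homozygote` or `ambiguous`).
#' @export
assign_genotypes <- function(presence, catalog) {
  sets <- catalog_label_sets(catalog)
  uncovered <- setdiff(si_labels(presence), unlist(sets))
  if (length(uncovered))
    stop("catalog does not cover label(s): ", paste(uncovered, collapse = ", "))
  rows <- lapply(individuals(presence), function(id) {
    L <- sort(labels_of(presence, id))
    cand <- names(sets)[vapply(sets, function(s) all(s %in% L), TRUE)]
    sols <- list()
    for (h in cand)
      if (setequal(sets[[h]], L)) sols[[length(sols) + 1L]] <- c(h, h)
    if (length(cand) >= 2L)
      for (pr in pairs_of(cand))
        if (setequal(union(sets[[pr[1]]], sets[[pr[2]]]), L))
          sols[[length(sols) + 1L]] <- pr
    if (!length(sols))
      stop("individual ", id, ": label set {", paste(L, collapse = ","),
           "} not coverable by <= 2 catalog haplotypes")
    if (length(sols) > 1L)
      return(data.frame(individual = id, hap1 = NA_character_,
                        hap2 = NA_character_, status = "ambiguous",
                        stringsAsFactors = FALSE))
    s <- sort(sols[[1]])
    data.frame(individual = id, hap1 = s[1], hap2 = s[2],
               status = if (s[1] == s[2]) "putative_homozygote"
                        else "heterozygous",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("si_genotypes", "data.frame")
  out
}

#' Upgrade putative homozygotes supported by segregation results
#'
#' A putative homozygote is confirmed when it parents a cohort whose
#' homozygote-by-heterozygote (case 2) segregation test conforms: two
#' offspring genotype classes at frequency 0.5 each and no unexpected
#' class.
#'
#' @param genotypes an `si_genotypes`.
#' @param seg_summary the data.frame returned by [batch_test()].
#' @return the updated `si_genotypes`.
#' @export
confirm_homozygotes <- function(genotypes, seg_summary) {
  ok <- seg_summary[seg_summary$case == "case2_hom_x_het" &
                      seg_summary$conforms, , drop = FALSE]
  confirmed <- unique(c(ok$hom_parent))
  idx <- genotypes$individual %in% confirmed &
    genotypes$status == "putative_homozygote"
  genotypes$status[idx] <- "confirmed_homozygote"
  genotypes
}

#' Genotype (haplotype pair) of one individual
#' @param genotypes an `si_genotypes`.
#' @param id individual ID.
#' @return character vector of the two haplotype IDs (equal for
#'   homozygotes).
#' @export
geno_of <- function(genotypes, id) {
  row <- genotypes[genotypes$individual == id, , drop = FALSE]
  if (nrow(row) != 1L) stop("individual ", id, " not genotyped")
  if (is.na(row$hap1)) stop("individual ", id, " has an ambiguous genotype")
  c(row$hap1, row$hap2)
}
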