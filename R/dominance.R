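## Per-organ expression and dominance of S-haplotypes from cross outcomes.
##
## Under sporophytic SI a pollination fails iff some S-haplotype is both
## expressed in the pollen (phenotype of the diploid donor) and expressed
## in the stigma of the receptor. Cross outcomes therefore constrain which
## haplotypes are expressed or silenced, per genotype and per organ;
## constraint propagation to a fixed point resolves them.

geno_key <- function(h) paste(sort(h), collapse = "/")
geno_haps <- function(key) unique(strsplit(key, "/", fixed = TRUE)[[1]])

#' Consolidate replicate and same-genotype crosses
#'
#' Crosses are grouped by the ordered pair (donor genotype, receptor
#' genotype); replicates and different individuals with identical
#' genotypes are merged. With `method = "strict"` (the default),
#' all-fruit groups are `compatible`, all-no-fruit `incompatible`, and
#' mixed groups `conflicting` (reported but excluded from inference).
#' `method = "majority"` calls the majority outcome and reserves
#' `conflicting` for ties; it is the natural choice for replicated noisy
#' designs.
#'
#' @param crosses an `si_crosses` data.frame.
#' @param genotypes an `si_genotypes` covering every crossed individual.
#' @param method consensus rule, `"strict"` or `"majority"`.
#' @return data.frame of class `si_consensus`: `donor_geno`,
#'   `receptor_geno`, `n_fruit`, `n_no_fruit`, `outcome`.
#' @export
consolidate_crosses <- function(crosses, genotypes,
                                method = c("strict", "majority")) {
  method <- match.arg(method)
  done <- crosses[crosses$result != "not_done", , drop = FALSE]
  if (!nrow(done))
    return(structure(data.frame(donor_geno = character(),
                                receptor_geno = character(),
                                n_fruit = integer(), n_no_fruit = integer(),
                                outcome = character(),
                                stringsAsFactors = FALSE),
                     class = c("si_consensus", "data.frame")))
  dk <- vapply(done$donor, function(id) geno_key(geno_of(genotypes, id)), "")
  rk <- vapply(done$receptor, function(id) geno_key(geno_of(genotypes, id)), "")
  key <- paste(dk, rk, sep = " -> ")
  agg <- lapply(split(seq_len(nrow(done)), key), function(ix) {
    fr <- sum(done$replicates[ix][done$result[ix] == "fruit"])
    nf <- sum(done$replicates[ix][done$result[ix] == "no_fruit"])
    outcome <- if (method == "strict") {
      if (fr > 0L && nf > 0L) "conflicting"
      else if (fr > 0L) "compatible" else "incompatible"
    } else {
      if (fr > nf) "compatible" else if (nf > fr) "incompatible"
      else "conflicting"
    }
    data.frame(donor_geno = dk[ix[1]], receptor_geno = rk[ix[1]],
               n_fruit = fr, n_no_fruit = nf, outcome = outcome,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  class(out) <- c("si_consensus", "data.frame")
  out
}

#' Infer per-organ expression of S-haplotypes
#'
#' Propagates, to a fixed point, the logical consequences of consensus
#' cross outcomes on the expression state of each haplotype within each
#' genotype and organ:
#' \itemize{
#'   \item an incompatible cross whose shared haplotypes reduce to a
#'     single viable candidate `X` forces `X` expressed in the donor's
#'     pollen and the receptor's stigma (this covers the homozygote case:
#'     a homozygote `XX` involved in any incompatibility expresses `X` in
#'     the corresponding organ);
#'   \item a compatible cross sharing `X`, with `X` known expressed on
#'     one side, forces `X` silenced on the other side.
#' }
#' Derivations contradicting an earlier call mark the cell `conflicting`;
#' no rule ever rewrites `expressed` to `silenced` directly. Cells left
#' undetermined are `ambiguous`. Incompatible crosses with no viable
#' shared candidate (including crosses sharing no haplotype at all) are
#' collected as unexplained.
#'
#' @param consensus an `si_consensus` from [consolidate_crosses()].
#' @param genotypes optional `si_genotypes`; adds genotypes never crossed
#'   (their cells stay ambiguous).
#' @return object of class `si_expression`: data.frame with `genotype`,
#'   `organ`, `haplotype`, `state`; unexplained incompatibilities in
#'   `attr(, "unexplained")`.
#' @export
infer_expression <- function(consensus, genotypes = NULL) {
  genos <- unique(c(consensus$donor_geno, consensus$receptor_geno))
  if (!is.null(genotypes)) {
    ok <- !is.na(genotypes$hap1)
    genos <- unique(c(genos, vapply(which(ok), function(i)
      geno_key(c(genotypes$hap1[i], genotypes$hap2[i])), "")))
  }
  state <- new.env(parent = emptyenv())
  cell <- function(g, organ, h) paste(g, organ, h, sep = "\r")
  get_state <- function(g, organ, h) {
    s <- state[[cell(g, organ, h)]]
    if (is.null(s)) "ambiguous" else s
  }
  changed <- FALSE
  set_state <- function(g, organ, h, value) {
    cur <- get_state(g, organ, h)
    if (cur == value || cur == "conflicting") return(invisible())
    state[[cell(g, organ, h)]] <-
      if (cur == "ambiguous") value else "conflicting"
    changed <<- TRUE
    invisible()
  }
  usable <- consensus[consensus$outcome %in% c("compatible", "incompatible"), ,
                      drop = FALSE]
  unexplained <- character()
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(usable))) {
      gd <- usable$donor_geno[i]; gr <- usable$receptor_geno[i]
      shared <- intersect(geno_haps(gd), geno_haps(gr))
      if (usable$outcome[i] == "incompatible") {
        cand <- shared[vapply(shared, function(x)
          get_state(gd, "pollen", x) != "silenced" &&
            get_state(gr, "stigma", x) != "silenced", TRUE)]
        if (!length(cand))
          unexplained <- union(unexplained, paste(gd, "->", gr))
        else if (length(cand) == 1L) {
          set_state(gd, "pollen", cand, "expressed")
          set_state(gr, "stigma", cand, "expressed")
        }
      } else {
        for (x in shared) {
          if (get_state(gd, "pollen", x) == "expressed")
            set_state(gr, "stigma", x, "silenced")
          if (get_state(gr, "stigma", x) == "expressed")
            set_state(gd, "pollen", x, "silenced")
        }
      }
    }
    if (!changed) break
  }
  rows <- do.call(rbind, lapply(sort(genos), function(g) {
    haps <- geno_haps(g)
    expand.grid(genotype = g, organ = c("pollen", "stigma"),
                haplotype = haps, stringsAsFactors = FALSE)
  }))
  rows$state <- mapply(get_state, rows$genotype, rows$organ, rows$haplotype)
  rows <- rows[order(rows$genotype, rows$organ, rows$haplotype), ,
               drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "unexplained") <- unexplained
  class(rows) <- c("si_expression", "data.frame")
  rows
}

expr_state <- function(expr, genotype, organ, haplotype) {
  s <- expr$state[expr$genotype == genotype & expr$organ == organ &
                    expr$haplotype == haplotype]
  if (!length(s)) NA_character_ else s[1]
}

#' Build the per-organ dominance model
#'
#' Within a heterozygous genotype `XY` and an organ, `X` expressed with
#' `Y` silenced means `X` dominant over `Y` in that genotype; both
#' expressed means codominant. Relations are aggregated per organ with
#' their supporting genotypes, and cycles in the aggregated dominance
#' graph are flagged.
#'
#' @param expr an `si_expression`.
#' @return object of class `si_dominance`: list with `relations`,
#'   `codominant`, `unresolved` data.frames, `cycles` (per organ), and
#'   the `expression` calls the model was built from.
#' @export
build_dominance <- function(expr) {
  genos <- unique(expr$genotype)
  rel <- list(); cod <- list(); unres <- list()
  for (g in genos) {
    haps <- geno_haps(g)
    if (length(haps) != 2L) next
    for (organ in c("pollen", "stigma")) {
      sx <- expr_state(expr, g, organ, haps[1])
      sy <- expr_state(expr, g, organ, haps[2])
      row <- data.frame(organ = organ, genotype = g, stringsAsFactors = FALSE)
      if (sx == "expressed" && sy == "silenced")
        rel[[length(rel) + 1L]] <- cbind(row, dominant = haps[1],
                                         recessive = haps[2])
      else if (sy == "expressed" && sx == "silenced")
        rel[[length(rel) + 1L]] <- cbind(row, dominant = haps[2],
                                         recessive = haps[1])
      else if (sx == "expressed" && sy == "expressed")
        cod[[length(cod) + 1L]] <- cbind(row, hap1 = haps[1], hap2 = haps[2])
      else
        unres[[length(unres) + 1L]] <- cbind(row, hap1 = haps[1],
                                             hap2 = haps[2],
                                             state1 = sx, state2 = sy)
    }
  }
  bindrows <- function(lst, template) {
    if (length(lst)) {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else template
  }
  relations <- bindrows(rel, data.frame(organ = character(),
                                        genotype = character(),
                                        dominant = character(),
                                        recessive = character()))
  cycles <- lapply(stats::setNames(nm = c("pollen", "stigma")), function(org) {
    edges <- relations[relations$organ == org, c("dominant", "recessive"),
                       drop = FALSE]
    find_cycle_nodes(edges)
  })
  structure(list(relations = relations,
                 codominant = bindrows(cod, data.frame(organ = character(),
                                                       genotype = character(),
                                                       hap1 = character(),
                                                       hap2 = character())),
                 unresolved = bindrows(unres, data.frame(organ = character(),
                                                         genotype = character(),
                                                         hap1 = character(),
                                                         hap2 = character(),
                                                         state1 = character(),
                                                         state2 = character())),
                 cycles = cycles, expression = expr),
            class = "si_dominance")
}

## nodes on a directed cycle: iteratively strip sources and sinks
find_cycle_nodes <- function(edges) {
  if (!nrow(edges)) return(character())
  repeat {
    nodes <- unique(c(edges$dominant, edges$recessive))
    keep <- edges$dominant %in% edges$recessive &
      edges$recessive %in% edges$dominant
    if (all(keep)) break
    edges <- edges[keep, , drop = FALSE]
    if (!nrow(edges)) return(character())
  }
  unique(c(edges$dominant, edges$recessive))
}

#' @export
print.si_dominance <- function(x, ...) {
  cat("Dominance model: ", nrow(x$relations), " dominance relation(s), ",
      nrow(x$codominant), " codominant pair(s), ", nrow(x$unresolved),
      " unresolved\n", sep = "")
  if (any(lengths(x$cycles) > 0))
    cat("  ! cycles involving: ",
        paste(unlist(x$cycles), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict cross compatibility under the sporophytic rule
#'
#' A cross is incompatible iff some haplotype shared by the two genotypes
#' is expressed both in the donor's pollen and in the receptor's stigma.
#' The prediction is `"undetermined"` when an ambiguous or conflicting
#' expression call could flip the intersection, or when the model does
#' not cover one of the genotypes.
#'
#' @param donor,receptor genotypes: haplotype pairs (character vectors)
#'   or `"X/Y"` keys.
#' @param model an `si_dominance` (or an `si_expression`).
#' @return `"compatible"`, `"incompatible"` or `"undetermined"`.
#' @export
predict_compatibility <- function(donor, receptor, model) {
  expr <- if (inherits(model, "si_dominance")) model$expression else model
  gd <- if (length(donor) > 1L) geno_key(donor) else donor
  gr <- if (length(receptor) > 1L) geno_key(receptor) else receptor
  if (!gd %in% expr$genotype || !gr %in% expr$genotype)
    return("undetermined")
  shared <- intersect(geno_haps(gd), geno_haps(gr))
  uncertain <- FALSE
  for (x in shared) {
    p <- expr_state(expr, gd, "pollen", x)
    s <- expr_state(expr, gr, "stigma", x)
    if (p == "expressed" && s == "expressed") return("incompatible")
    if (p != "silenced" && s != "silenced") uncertain <- TRUE
  }
  if (uncertain) "undetermined" else "compatible"
}

#' Summarize fruit-set rates of a cross table
#'
#' Pollination-level success rates (weighted by replicates) among crosses
#' between individuals sharing at least one putative S-haplotype versus
#' sharing none (the positive controls), plus per-haplotype and
#' per-class breakdowns in the style of a diallel summary: for each
#' haplotype, the success rate of crosses involving the stigma (receptor
#' carries it) or the pollen (donor carries it), split by whether the
#' other individual shares it.
#'
#' @param crosses an `si_crosses`.
#' @param genotypes an `si_genotypes`.
#' @param catalog an `si_catalog` (supplies class tags).
#' @return list with data.frames `overall`, `per_haplotype`, `per_class`.
#' @export
summarize_compatibility <- function(crosses, genotypes, catalog) {
  done <- crosses[crosses$result != "not_done", , drop = FALSE]
  empty <- list(
    overall = data.frame(group = character(), pollinations = integer(),
                         fruit = integer(), rate = numeric()),
    per_haplotype = data.frame(haplotype = character(), organ = character(),
                               shared = logical(), pollinations = integer(),
                               fruit = integer(), rate = numeric()),
    per_class = data.frame(class_tag = character(), pollinations = integer(),
                           fruit = integer(), rate = numeric()))
  if (!nrow(done)) return(empty)
  dh <- lapply(done$donor, function(id) geno_of(genotypes, id))
  rh <- lapply(done$receptor, function(id) geno_of(genotypes, id))
  shared_n <- mapply(function(a, b) length(intersect(a, b)), dh, rh)
  w <- done$replicates
  fruit <- (done$result == "fruit") * w
  rate_row <- function(group, ix)
    data.frame(group = group, pollinations = sum(w[ix]),
               fruit = sum(fruit[ix]),
               rate = if (sum(w[ix]) > 0) sum(fruit[ix]) / sum(w[ix]) else NA_real_)
  overall <- rbind(rate_row("shared_haplotype", shared_n > 0),
                   rate_row("no_shared_haplotype", shared_n == 0))
  per_hap <- list()
  for (h in catalog$haplotype) {
    for (organ in c("pollen", "stigma")) {
      focal <- if (organ == "pollen")
        vapply(dh, function(x) h %in% x, TRUE)
      else vapply(rh, function(x) h %in% x, TRUE)
      other <- if (organ == "pollen")
        vapply(rh, function(x) h %in% x, TRUE)
      else vapply(dh, function(x) h %in% x, TRUE)
      for (sh in c(TRUE, FALSE)) {
        ix <- focal & (other == sh)
        if (!any(ix)) next
        per_hap[[length(per_hap) + 1L]] <-
          data.frame(haplotype = h, organ = organ, shared = sh,
                     pollinations = sum(w[ix]), fruit = sum(fruit[ix]),
                     rate = sum(fruit[ix]) / sum(w[ix]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  per_hap <- if (length(per_hap)) do.call(rbind, per_hap) else
    empty$per_haplotype
  tags <- stats::setNames(catalog$class_tag, catalog$haplotype)
  per_class <- list()
  for (tag in unique(stats::na.omit(tags))) {
    haps <- names(tags)[tags == tag]
    ix <- shared_n > 0 & mapply(function(a, b)
      length(intersect(intersect(a, b), haps)) > 0, dh, rh)
    if (!any(ix)) next
    per_class[[length(per_class) + 1L]] <-
      data.frame(class_tag = tag, pollinations = sum(w[ix]),
                 fruit = sum(fruit[ix]),
                 rate = sum(fruit[ix]) / sum(w[ix]),
                 stringsAsFactors = FALSE)
  }
  list(overall = overall, per_haplotype = per_hap,
       per_class = if (length(per_class)) do.call(rbind, per_class) else
         empty$per_class)
}
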