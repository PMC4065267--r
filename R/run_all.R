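## One-call pipeline: phasing -> segregation -> dominance -> reports.

#' Run the full S-locus pipeline
#'
#' Chains the stages on one set of inputs: linked-pair inference and
#' catalog construction, genotype assignment, Monte-Carlo segregation
#' tests with homozygote confirmation, and (when a cross table is
#' supplied) dominance inference with compatibility summaries. Inputs may
#' be file paths or already-parsed objects. Any stage error aborts with
#' the stage named; a missing cross table only skips the dominance stage
#' with a warning.
#'
#' @param presence `si_presence` or CSV path.
#' @param cohorts list of `si_cohort` or CSV path.
#' @param crosses `si_crosses`, CSV path, or `NULL` to skip dominance.
#' @param untypable labels unscorable in progeny.
#' @param variant_merge_map,class_map passed to [read_presence_matrix()]
#'   when `presence` is a path.
#' @param name_map optional haplotype display names for
#'   [build_catalog()].
#' @param reps,alpha,seed segregation-test parameters.
#' @param out_dir optional directory; when given, all tables are written
#'   as CSV together with a JSON run manifest (inputs, parameters, seed,
#'   versions, per-stage row counts).
#' @return list of class `si_run` with elements `pairs`, `catalog`,
#'   `genotypes`, `segregation`, `consensus`, `expression`, `dominance`,
#'   `summary`, `manifest`.
#' @export
run_all <- function(presence, cohorts, crosses = NULL,
                    untypable = character(),
                    variant_merge_map = NULL, class_map = NULL,
                    name_map = NULL,
                    reps = 100000L, alpha = 0.05, seed = 20131223L,
                    out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inputs <- list(
    presence = if (is.character(presence)) presence else "<object>",
    cohorts = if (is.character(cohorts)) cohorts else "<object>",
    crosses = if (is.character(crosses)) crosses
              else if (is.null(crosses)) NA else "<object>")
  if (is.character(presence))
    presence <- stage("read_presence",
                      read_presence_matrix(presence, variant_merge_map,
                                           class_map))
  if (is.character(cohorts))
    cohorts <- stage("read_cohorts", read_cohorts(cohorts, presence))
  if (is.character(crosses))
    crosses <- stage("read_crosses", read_crosses(crosses, presence))

  pairs <- stage("phasing", infer_linked_pairs(presence, cohorts, untypable))
  catalog <- stage("phasing", build_catalog(pairs, presence, name_map))
  genotypes <- stage("phasing", assign_genotypes(presence, catalog))
  segregation <- stage("segregation",
                       batch_test(cohorts, genotypes, catalog, untypable,
                                  reps = reps, alpha = alpha, seed = seed))
  genotypes <- confirm_homozygotes(genotypes, segregation)

  consensus <- expression_calls <- dominance <- summary_tabs <- NULL
  if (is.null(crosses)) {
    warning("no cross table supplied: dominance stage skipped")
  } else {
    consensus <- stage("dominance", consolidate_crosses(crosses, genotypes))
    expression_calls <- stage("dominance",
                              infer_expression(consensus, genotypes))
    dominance <- stage("dominance", build_dominance(expression_calls))
    summary_tabs <- stage("dominance",
                          summarize_compatibility(crosses, genotypes,
                                                  catalog))
  }
  manifest <- list(
    inputs = inputs,
    parameters = list(untypable = untypable, reps = reps, alpha = alpha,
                      seed = seed),
    versions = list(
      silocus = as.character(utils::packageVersion("silocus")),
      R = paste(R.version$major, R.version$minor, sep = ".")),
    rows = list(individuals = nrow(presence$mat),
                labels = ncol(presence$mat),
                cohorts = length(cohorts),
                linked_pairs = nrow(pairs),
                haplotypes = nrow(catalog),
                crosses = if (is.null(crosses)) 0L else nrow(crosses),
                segregation = nrow(segregation)))
  res <- structure(list(pairs = pairs, catalog = catalog,
                        genotypes = genotypes, segregation = segregation,
                        consensus = consensus,
                        expression = expression_calls,
                        dominance = dominance, summary = summary_tabs,
                        manifest = manifest),
                   class = "si_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' Write a pipeline run to disk
#' @param run an `si_run` from [run_all()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                     row.names = FALSE)
  w(run$pairs, "linked_pairs.csv")
  w(run$catalog, "catalog.csv")
  w(run$genotypes, "genotypes.csv")
  w(run$segregation, "segregation.csv")
  w(run$consensus, "consensus.csv")
  w(run$expression, "expression.csv")
  if (!is.null(run$dominance)) {
    w(run$dominance$relations, "dominance_relations.csv")
    w(run$dominance$codominant, "dominance_codominant.csv")
  }
  if (!is.null(run$summary)) {
    w(run$summary$overall, "summary_overall.csv")
    w(run$summary$per_haplotype, "summary_per_haplotype.csv")
    w(run$summary$per_class, "summary_per_class.csv")
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.si_run <- function(x, ...) {
  r <- x$manifest$rows
  cat("silocus run: ", r$individuals, " individuals, ", r$labels,
      " labels, ", r$cohorts, " cohorts\n", sep = "")
  cat("  catalog: ", r$haplotypes, " haplotypes (",
      sum(x$catalog$support != "singleton"), " linked pairs)\n", sep = "")
  cat("  segregation: ", sum(x$segregation$conforms), "/",
      nrow(x$segregation), " cohorts conform\n", sep = "")
  if (!is.null(x$dominance))
    cat("  dominance: ", nrow(x$dominance$relations), " relation(s), ",
        nrow(x$dominance$codominant), " codominant pair(s)\n", sep = "")
  invisible(x)
}
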