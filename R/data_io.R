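#' silocus: S-locus genetics of sporophytic self-incompatibility
#'
#' Phasing of S-haplotypes from presence/absence typing of SRK-like
#' sequence labels, Monte-Carlo tests of Mendelian segregation in
#' offspring cohorts, inference of pollen/stigma dominance relations from
#' diallel controlled crosses, codon-aware nucleotide-diversity statistics,
#' and a self-incompatibility simulator that generates every input of the
#' pipeline with a known ground truth.
#'
#' @section Main entry points:
#' \itemize{
#'   \item [read_presence_matrix()], [read_cohorts()], [read_crosses()],
#'     [read_codon_alignment()] -- input parsing and validation.
#'   \item [infer_linked_pairs()], [build_catalog()], [assign_genotypes()]
#'     -- S-haplotype phasing.
#'   \item [batch_test()] -- Monte-Carlo Mendelian segregation tests.
#'   \item [consolidate_crosses()], [infer_expression()],
#'     [build_dominance()], [predict_compatibility()] -- dominance.
#'   \item [group_pi()] -- synonymous/nonsynonymous diversity.
#'   \item [simulate_locus()], [emit_dataset()] -- synthetic data.
#'   \item [run_all()] -- the whole pipeline on one set of inputs.
#' }
#'
#' @keywords internal
"_PACKAGE"

## ------------------------------------------------------------------
## Presence/absence matrix of sequence labels per individual
## ------------------------------------------------------------------

#' Construct a presence/absence matrix of sequence labels
#'
#' The central typing object: which SRK-like sequence labels were detected
#' in which (diploid) individual. Rows are individuals, columns sequence
#' labels, cells logical presence.
#'
#' @param mat logical matrix, individuals in rows (rownames = individual
#'   IDs), sequence labels in columns (colnames = label names).
#' @param class_tags optional named character vector mapping label names to
#'   a class tag (e.g. `"A"`, `"B"`, `"C"`, `"ARK3L"`). Class tags are an
#'   external annotation (typically from a phylogenetic analysis done
#'   elsewhere); they are never guessed from label names.
#' @param merge_map optional named character vector recording the
#'   sub-variant merges that produced `mat` (names = sub-variant labels,
#'   values = canonical labels). Informational.
#' @return an object of class `si_presence`.
#' @seealso [read_presence_matrix()]
#' @export
presence_matrix <- function(mat, class_tags = NULL, merge_map = NULL) {
  if (!is.matrix(mat) || !is.logical(mat))
    stop("'mat' must be a logical matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("'mat' must have individual IDs as rownames and labels as colnames")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate individual IDs: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate label columns: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  if (any(rowSums(mat) < 1))
    stop("individual(s) with no present label: ",
         paste(rownames(mat)[rowSums(mat) < 1], collapse = ", "))
  if (!is.null(class_tags)) {
    missing_tags <- setdiff(colnames(mat), names(class_tags))
    if (length(missing_tags))
      stop("class_tags missing for label(s): ", paste(missing_tags, collapse = ", "))
    class_tags <- class_tags[colnames(mat)]
  }
  structure(list(mat = mat, class_tags = class_tags, merge_map = merge_map),
            class = "si_presence")
}

#' @export
print.si_presence <- function(x, ...) {
  cat("S-locus presence matrix: ", nrow(x$mat), " individuals x ",
      ncol(x$mat), " sequence labels\n", sep = "")
  invisible(x)
}

#' Individuals and labels of a presence matrix
#' @param x an `si_presence` object.
#' @return character vector of IDs / label names.
#' @export
individuals <- function(x) rownames(x$mat)

#' @rdname individuals
#' @export
si_labels <- function(x) colnames(x$mat)

#' Labels present in one individual
#' @param x an `si_presence` object.
#' @param id individual ID.
#' @return character vector of label names carried by `id`.
#' @export
labels_of <- function(x, id) {
  if (!id %in% rownames(x$mat)) stop("unknown individual: ", id)
  colnames(x$mat)[x$mat[id, ]]
}

#' Read a presence/absence matrix from CSV
#'
#' Expects a comma-separated file with a header row, one row per
#' individual: an `individual` column, an optional `typed` column, and one
#' 0/1 column per sequence label. Empty cells are accepted as absence only
#' for individuals whose `typed` column says `"complete"`; otherwise they
#' are an error, so that "not typed" is never silently confused with
#' "absent".
#'
#' Sub-variant labels (e.g. `A01a`, `A01b`, differing by a single
#' nucleotide and treated as one allele) are merged into their canonical
#' label via `variant_merge_map`; presence of any sub-variant makes the
#' canonical label present.
#'
#' @param path CSV file path.
#' @param variant_merge_map named character vector: sub-variant label ->
#'   canonical label (e.g. `c(A01a = "A01", A01b = "A01")`). `NULL` for no
#'   merging.
#' @param class_map optional named character vector label -> class tag,
#'   applied after merging.
#' @return an `si_presence` object.
#' @export
read_presence_matrix <- function(path, variant_merge_map = NULL,
                                 class_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty presence matrix file: ", path)
  if (!"individual" %in% names(df)) stop("missing 'individual' column")
  ids <- as.character(df$individual)
  if (anyDuplicated(ids))
    stop("duplicate individual IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  typed <- if ("typed" %in% names(df)) as.character(df$typed) else rep("", nrow(df))
  label_cols <- setdiff(names(df), c("individual", "typed"))
  if (!length(label_cols)) stop("no label columns in ", path)
  raw <- as.matrix(df[, label_cols, drop = FALSE])
  num <- suppressWarnings(apply(raw, 2L, function(col) as.numeric(col)))
  num <- matrix(num, nrow = nrow(df), dimnames = list(ids, label_cols))
  blank <- is.na(raw) | trimws(raw) == ""
  if (any(blank)) {
    bad <- ids[apply(blank, 1L, any) & typed != "complete"]
    if (length(bad))
      stop("missing cells for individual(s) not flagged typed=complete: ",
           paste(bad, collapse = ", "))
    num[blank] <- 0
  }
  if (any(is.na(num)) || !all(num %in% c(0, 1)))
    stop("non-binary cell(s) in presence matrix ", path)
  mat <- num == 1
  merge_log <- NULL
  if (!is.null(variant_merge_map)) {
    unknown <- setdiff(names(variant_merge_map), colnames(mat))
    ## merge-map entries for labels absent from this dataset are an error
    ## only when they cannot be ignored safely: a map naming an unknown
    ## sub-variant most likely indicates a typo
    if (length(unknown))
      stop("merge map names unknown label(s): ", paste(unknown, collapse = ", "))
    mat <- merge_variants(mat, variant_merge_map)
    merge_log <- variant_merge_map
  }
  presence_matrix(mat,
                  class_tags = if (!is.null(class_map)) class_map[colnames(mat)],
                  merge_map = merge_log)
}

## OR-combine sub-variant columns into canonical columns; idempotent.
merge_variants <- function(mat, map) {
  for (canon in unique(map)) {
    subs <- names(map)[map == canon]
    cols <- intersect(c(canon, subs), colnames(mat))
    merged <- rowSums(mat[, cols, drop = FALSE]) > 0
    mat <- mat[, setdiff(colnames(mat), cols), drop = FALSE]
    mat <- cbind(mat, merged)
    colnames(mat)[ncol(mat)] <- canon
  }
  mat[, order(colnames(mat)), drop = FALSE]
}

#' Write a presence matrix to CSV (round-trips with [read_presence_matrix()])
#' @param x an `si_presence` object.
#' @param path output CSV path.
#' @export
write_presence_matrix <- function(x, path) {
  df <- data.frame(individual = rownames(x$mat),
                   typed = "complete",
                   apply(x$mat, 2L, as.integer),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ------------------------------------------------------------------
## Offspring cohorts
## ------------------------------------------------------------------

#' Construct an offspring cohort observation
#'
#' One cohort = the typed progeny of a single parent pair. Offspring are
#' recorded as counts of observed sequence-label combinations (an
#' offspring's combination is the set of typable labels detected in it).
#'
#' @param cohort_id cohort identifier.
#' @param parent1,parent2 parent individual IDs.
#' @param n declared cohort size.
#' @param combos list of character vectors, one per observed combination.
#' @param counts integer vector, same length as `combos`; must sum to `n`.
#' @return an object of class `si_cohort`.
#' @export
cohort_observation <- function(cohort_id, parent1, parent2, n, combos, counts) {
  n <- as.integer(n)
  counts <- as.integer(counts)
  if (n < 1L) stop("cohort size must be >= 1")
  if (length(combos) != length(counts))
    stop("combos and counts differ in length")
  if (sum(counts) != n)
    stop("cohort ", cohort_id, ": counts sum to ", sum(counts),
         " but declared n = ", n)
  combos <- lapply(combos, function(v) sort(unique(as.character(v))))
  keys <- vapply(combos, paste, "", collapse = "+")
  if (anyDuplicated(keys)) stop("cohort ", cohort_id, ": duplicated combination")
  structure(list(cohort_id = as.character(cohort_id),
                 parent1 = as.character(parent1),
                 parent2 = as.character(parent2),
                 n = n, combos = combos, counts = counts),
            class = "si_cohort")
}

#' @export
print.si_cohort <- function(x, ...) {
  cat("Cohort ", x$cohort_id, ": ", x$parent1, " x ", x$parent2,
      ", n = ", x$n, ", ", length(x$combos), " observed combination(s)\n",
      sep = "")
  invisible(x)
}

#' Read offspring cohorts from CSV
#'
#' Expected columns: `cohort_id`, `parent1`, `parent2`, `n`, `combination`
#' (label names joined by `+`), `count` -- one row per observed
#' combination. Per cohort, counts must sum to the declared `n`.
#'
#' @param path CSV file path.
#' @param presence optional `si_presence`; when given, parent IDs are
#'   checked against it.
#' @return list of `si_cohort`, named by cohort ID.
#' @export
read_cohorts <- function(path, presence = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cohort_id", "parent1", "parent2", "n", "combination", "count")
  if (!all(need %in% names(df)))
    stop("cohort file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, factor(df$cohort_id, levels = unique(df$cohort_id))),
                function(d) {
    if (length(unique(d$parent1)) != 1L || length(unique(d$parent2)) != 1L ||
        length(unique(d$n)) != 1L)
      stop("cohort ", d$cohort_id[1], ": inconsistent parent/n rows")
    if (!is.null(presence)) {
      bad <- setdiff(c(d$parent1[1], d$parent2[1]), individuals(presence))
      if (length(bad)) stop("cohort ", d$cohort_id[1],
                            ": unknown parent ID ", paste(bad, collapse = ", "))
    }
    cohort_observation(d$cohort_id[1], d$parent1[1], d$parent2[1], d$n[1],
                       strsplit(as.character(d$combination), "+", fixed = TRUE),
                       d$count)
  })
  out[unique(as.character(df$cohort_id))]
}

#' Write cohorts to CSV (round-trips with [read_cohorts()])
#' @param cohorts list of `si_cohort`.
#' @param path output CSV path.
#' @export
write_cohorts <- function(cohorts, path) {
  rows <- do.call(rbind, lapply(cohorts, function(co)
    data.frame(cohort_id = co$cohort_id, parent1 = co$parent1,
               parent2 = co$parent2, n = co$n,
               combination = vapply(co$combos, paste, "", collapse = "+"),
               count = co$counts)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ------------------------------------------------------------------
## Controlled-cross outcomes
## ------------------------------------------------------------------

#' Read controlled-cross (pollination) outcomes from CSV
#'
#' Expected columns: `donor` (pollen donor ID), `receptor` (pollen
#' receptor ID), `result` (`fruit`, `no_fruit` or `not_done`),
#' `replicates`. `donor == receptor` encodes a self-pollination.
#'
#' @param path CSV file path.
#' @param presence optional `si_presence` for ID validation.
#' @return data.frame of class `si_crosses` with columns
#'   `donor`, `receptor`, `result`, `replicates`.
#' @export
read_crosses <- function(path, presence = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("donor", "receptor", "result", "replicates")
  if (!all(need %in% names(df)))
    stop("cross file must have columns: ", paste(need, collapse = ", "))
  crosses(df$donor, df$receptor, df$result, df$replicates, presence = presence)
}

#' @rdname read_crosses
#' @param donor,receptor,result,replicates vectors forming the cross table.
#' @export
crosses <- function(donor, receptor, result, replicates = 1L,
                    presence = NULL) {
  result <- as.character(result)
  bad <- setdiff(unique(result), c("fruit", "no_fruit", "not_done"))
  if (length(bad))
    stop("unknown cross result(s): ", paste(bad, collapse = ", "))
  replicates <- as.integer(replicates)
  if (any(result != "not_done" & (is.na(replicates) | replicates < 1L)))
    stop("replicates must be >= 1 for performed crosses")
  if (!is.null(presence)) {
    unknown <- setdiff(unique(c(donor, receptor)), individuals(presence))
    if (length(unknown))
      stop("cross references unknown individual(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(data.frame(donor = as.character(donor),
                       receptor = as.character(receptor),
                       result = result, replicates = replicates,
                       stringsAsFactors = FALSE),
            class = c("si_crosses", "data.frame"))
}

#' Write crosses to CSV (round-trips with [read_crosses()])
#' @param x an `si_crosses` data.frame.
#' @param path output CSV path.
#' @export
write_crosses <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ------------------------------------------------------------------
## Codon alignments and region annotations
## ------------------------------------------------------------------

#' Read an in-frame codon alignment from FASTA
#'
#' All records must have identical length, divisible by 3, over the
#' alphabet `A,C,G,T,-,N` (case-insensitive).
#'
#' @param path FASTA file path.
#' @return an object of class `si_codon_alignment`: list with `ids`,
#'   `seqs` (uppercase character vector) and `length`.
#' @export
read_codon_alignment <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  codon_alignment(as.character(set), names(set))
}

#' @rdname read_codon_alignment
#' @param seqs character vector of aligned nucleotide sequences.
#' @param ids sequence identifiers.
#' @export
codon_alignment <- function(seqs, ids = names(seqs)) {
  force(ids)
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("alignment records differ in length")
  if (widths[1] %% 3L != 0L)
    stop("alignment length ", widths[1], " not divisible by 3")
  if (any(grepl("[^ACGTN-]", seqs)))
    stop("alignment contains characters outside {A,C,G,T,-,N}")
  structure(list(ids = as.character(ids), seqs = seqs,
                 length = widths[1]),
            class = "si_codon_alignment")
}

#' @export
print.si_codon_alignment <- function(x, ...) {
  cat("Codon alignment: ", length(x$ids), " sequences x ", x$length,
      " nt (", x$length / 3L, " codons)\n", sep = "")
  invisible(x)
}

#' Read named region annotations (e.g. hypervariable regions HV2/HV3)
#'
#' A whitespace- or tab-separated three-column text file: region name,
#' start, end. Coordinates are 1-based, inclusive, in amino-acid (column)
#' units of the translated alignment.
#'
#' @param path annotation file path.
#' @return data.frame with columns `name`, `start`, `end`.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("name", "start", "end"))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 1L) || any(df$end < df$start))
    stop("invalid region interval(s)")
  df
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key=value`; blank lines and `#` comments ignored.
#' Values are returned as character; callers coerce as needed.
#'
#' @param path config file path.
#' @return named character vector.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) < 2L)) stop("malformed config line(s)")
  stats::setNames(vapply(kv, function(p) paste(p[-1], collapse = "="), ""),
                  vapply(kv, `[[`, "", 1L))
}

#' Path to a bundled example/fixture file
#'
#' The package ships transcriptions of the published F0 typing matrix,
#' the 13 offspring cohorts, the S-haplotype table and a small worked
#' cross example, plus the label class annotation.
#'
#' @param file file name; `NULL` lists the available files.
#' @return full path (or vector of file names).
#' @export
silocus_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "silocus")))
  path <- system.file("extdata", file, package = "silocus")
  if (path == "") stop("no bundled file called ", file)
  path
}
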