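## Codon-aware synonymous/nonsynonymous nucleotide diversity.
##
## Unweighted pathway counting: per codon, each of the nine single-
## nucleotide changes carries 1/3 site; changes creating a stop codon are
## excluded (they reduce the site total). Differences between two codons
## differing at k positions are averaged over all k! minimal substitution
## pathways, excluding pathways traversing a stop codon. Diversity within
## a group is the mean over all unordered sequence pairs of the per-pair
## proportions.

NT <- c("A", "C", "G", "T")

translate_codon <- function(codon, code = Biostrings::GENETIC_CODE) {
  aa <- code[codon]
  if (is.na(aa)) NA_character_ else unname(aa)
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' Each of the three positions contributes up to one site, split among its
#' three possible changes (1/3 site per change). Changes to a stop codon
#' are excluded, so the two counts sum to 3 minus the excluded fraction.
#'
#' @param codon 3-letter nucleotide string (no gap or N).
#' @param code named genetic-code vector (codon -> amino acid, `"*"` for
#'   stop); defaults to the standard code.
#' @return numeric vector `c(syn = ..., nonsyn = ...)`.
#' @export
codon_site_counts <- function(codon, code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be a 3-letter string over A,C,G,T: ", codon)
  aa <- translate_codon(codon, code)
  if (aa == "*") stop("stop codon has no defined site counts: ", codon)
  nts <- strsplit(codon, "")[[1]]
  syn <- 0; nonsyn <- 0
  for (pos in 1:3) for (alt in setdiff(NT, nts[pos])) {
    mut <- nts; mut[pos] <- alt
    maa <- translate_codon(paste(mut, collapse = ""), code)
    if (maa == "*") next                      # excluded from the site total
    if (maa == aa) syn <- syn + 1 / 3 else nonsyn <- nonsyn + 1 / 3
  }
  c(syn = syn, nonsyn = nonsyn)
}

## all permutations of seq_len(k), k <= 3
small_perms <- function(k) {
  switch(k,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

## average (syn, nonsyn) substitutions between two codons over all minimal
## pathways avoiding stop codons; NULL if no pathway is stop-free
codon_path_diffs <- function(ca, cb, code = Biostrings::GENETIC_CODE) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  tot_syn <- 0; tot_nonsyn <- 0; n_paths <- 0L
  for (ord in small_perms(k)) {
    cur <- a; s <- 0; n <- 0; ok <- TRUE
    for (pos in diff_pos[ord]) {
      aa_from <- translate_codon(paste(cur, collapse = ""), code)
      cur[pos] <- b[pos]
      aa_to <- translate_codon(paste(cur, collapse = ""), code)
      if (aa_to == "*") { ok <- FALSE; break }
      if (aa_to == aa_from) s <- s + 1 else n <- n + 1
    }
    if (ok) {
      tot_syn <- tot_syn + s; tot_nonsyn <- tot_nonsyn + n
      n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0L) return(NULL)
  c(syn = tot_syn / n_paths, nonsyn = tot_nonsyn / n_paths)
}

#' Pairwise synonymous/nonsynonymous differences and sites
#'
#' Codons containing a gap, `N`, or a stop codon in either sequence are
#' excluded pairwise (complete-codon deletion); so are codon pairs whose
#' every minimal pathway traverses a stop. Sites are averaged between the
#' two sequences.
#'
#' @param seq_a,seq_b aligned nucleotide strings of equal length,
#'   divisible by 3, frame 0.
#' @param code genetic-code vector.
#' @return list with `syn_diff`, `nonsyn_diff`, `syn_sites`,
#'   `nonsyn_sites`, `n_codons_used`.
#' @export
pairwise_syn_nonsyn <- function(seq_a, seq_b,
                                code = Biostrings::GENETIC_CODE) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequence length mismatch")
  if (nchar(seq_a) %% 3L != 0L) stop("length not divisible by 3")
  nc <- nchar(seq_a) / 3L
  starts <- 3L * (seq_len(nc) - 1L) + 1L
  sd <- 0; nd <- 0; ss <- 0; ns <- 0; used <- 0L
  for (st in starts) {
    ca <- substr(seq_a, st, st + 2L); cb <- substr(seq_b, st, st + 2L)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (translate_codon(ca, code) == "*" ||
        translate_codon(cb, code) == "*") next
    d <- codon_path_diffs(ca, cb, code)
    if (is.null(d)) next
    sa <- codon_site_counts(ca, code); sb <- codon_site_counts(cb, code)
    sd <- sd + d[["syn"]]; nd <- nd + d[["nonsyn"]]
    ss <- ss + (sa[["syn"]] + sb[["syn"]]) / 2
    ns <- ns + (sa[["nonsyn"]] + sb[["nonsyn"]]) / 2
    used <- used + 1L
  }
  list(syn_diff = sd, nonsyn_diff = nd, syn_sites = ss, nonsyn_sites = ns,
       n_codons_used = used)
}

#' Within-group synonymous and nonsynonymous diversity
#'
#' `pi_S` is the mean over all unordered sequence pairs of (synonymous
#' differences / synonymous sites); `pi_N` analogous. By default both are
#' raw proportions; `jukes_cantor = TRUE` applies the Jukes-Cantor
#' multiple-hit correction to each per-pair proportion before averaging.
#' `n_sites` reports the minimum, over pairs, of nucleotide columns
#' retained by the pairwise complete-codon filtering.
#'
#' @param aln an `si_codon_alignment`.
#' @param group sequence IDs (or indices) forming the group; default all.
#' @param group_id label for the output row.
#' @param jukes_cantor apply the JC69 correction (default off).
#' @param code genetic-code vector.
#' @return data.frame of class `si_diversity` with columns `group_id`,
#'   `n_seq`, `n_sites`, `pi_s`, `pi_n`, `ratio`.
#' @export
group_pi <- function(aln, group = NULL, group_id = "all",
                     jukes_cantor = FALSE,
                     code = Biostrings::GENETIC_CODE) {
  ids <- aln$ids
  if (is.null(group)) group <- ids
  if (is.numeric(group)) group <- ids[group]
  missing_ids <- setdiff(group, ids)
  if (length(missing_ids))
    stop("unknown sequence ID(s): ", paste(missing_ids, collapse = ", "))
  if (length(group) < 2L) stop("group must contain at least 2 sequences")
  seqs <- stats::setNames(aln$seqs, ids)[group]
  jc <- function(p) {
    if (!jukes_cantor) return(p)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  cmb <- utils::combn(length(seqs), 2L)
  ps <- numeric(ncol(cmb)); pn <- numeric(ncol(cmb))
  nsites <- integer(ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    pw <- pairwise_syn_nonsyn(seqs[[cmb[1, i]]], seqs[[cmb[2, i]]], code)
    ps[i] <- jc(if (pw$syn_sites > 0) pw$syn_diff / pw$syn_sites else NA_real_)
    pn[i] <- jc(if (pw$nonsyn_sites > 0)
      pw$nonsyn_diff / pw$nonsyn_sites else NA_real_)
    nsites[i] <- 3L * pw$n_codons_used
  }
  pi_s <- mean(ps); pi_n <- mean(pn)
  out <- data.frame(group_id = group_id, n_seq = length(seqs),
                    n_sites = min(nsites), pi_s = pi_s, pi_n = pi_n,
                    ratio = if (!is.na(pi_s) && pi_s > 0) pi_n / pi_s
                            else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("si_diversity", "data.frame")
  out
}

#' Per-column amino-acid variability with region overlay
#'
#' Translates the alignment codon-wise (cells with gaps or `N` are
#' masked) and counts distinct residues per amino-acid column, with their
#' relative frequencies among unmasked cells. Columns falling inside
#' annotated intervals (e.g. the SRK hypervariable regions HV2/HV3) are
#' labelled.
#'
#' @param aln an `si_codon_alignment`.
#' @param regions optional data.frame from [read_regions()] (1-based,
#'   inclusive amino-acid coordinates).
#' @param code genetic-code vector.
#' @return data.frame with columns `column`, `n_residues`, `residues`
#'   (`"X:freq"` pairs joined by `;`), `region` (`NA` outside any
#'   annotated interval).
#' @export
per_column_variability <- function(aln, regions = NULL,
                                   code = Biostrings::GENETIC_CODE) {
  nc <- aln$length / 3L
  aamat <- matrix(NA_character_, nrow = length(aln$ids), ncol = nc)
  for (i in seq_along(aln$seqs)) for (j in seq_len(nc)) {
    codon <- substr(aln$seqs[i], 3L * (j - 1L) + 1L, 3L * j)
    if (!grepl("[^ACGT]", codon))
      aamat[i, j] <- translate_codon(codon, code)
  }
  rows <- lapply(seq_len(nc), function(j) {
    cells <- aamat[, j]
    cells <- cells[!is.na(cells)]
    tb <- sort(table(cells), decreasing = TRUE)
    reg <- NA_character_
    if (!is.null(regions) && nrow(regions)) {
      hit <- regions$name[regions$start <= j & j <= regions$end]
      if (length(hit)) reg <- paste(hit, collapse = ";")
    }
    data.frame(column = j, n_residues = length(tb),
               residues = paste(sprintf("%s:%.4g", names(tb),
                                        as.numeric(tb) / sum(tb)),
                                collapse = ";"),
               region = reg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
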