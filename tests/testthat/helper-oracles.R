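## Independent oracles used to validate the package implementations.

## Site counts by direct enumeration of the nine point mutations.
oracle_site_counts <- function(codon, code = Biostrings::GENETIC_CODE) {
  aa <- unname(code[codon])
  s <- 0; n <- 0
  for (pos in 1:3) for (nt in c("A", "C", "G", "T")) {
    if (substr(codon, pos, pos) == nt) next
    mut <- codon
    substr(mut, pos, pos) <- nt
    maa <- unname(code[mut])
    if (maa == "*") next
    if (maa == aa) s <- s + 1 else n <- n + 1
  }
  c(syn = s / 3, nonsyn = n / 3)
}

## Substitution counts averaged over all minimal pathways, by recursive
## depth-first enumeration (independent of the permutation-table
## implementation in the package).
oracle_path_counts <- function(ca, cb, code = Biostrings::GENETIC_CODE) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  acc <- c(syn = 0, nonsyn = 0, paths = 0)
  rec <- function(cur, remaining, syn, nonsyn) {
    if (!length(remaining)) {
      acc <<- acc + c(syn, nonsyn, 1)
      return(invisible())
    }
    for (pos in remaining) {
      aa_from <- unname(code[paste(cur, collapse = "")])
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_to <- unname(code[paste(nxt, collapse = "")])
      if (aa_to == "*") next
      rec(nxt, setdiff(remaining, pos),
          syn + (aa_to == aa_from), nonsyn + (aa_to != aa_from))
    }
  }
  rec(a, which(a != b), 0, 0)
  if (acc[["paths"]] == 0) NULL else acc[1:2] / acc[["paths"]]
}

## Pairwise proportions computed entirely through the oracles above.
oracle_pairwise <- function(seq_a, seq_b, code = Biostrings::GENETIC_CODE) {
  nc <- nchar(seq_a) / 3L
  sd <- 0; nd <- 0; ss <- 0; ns <- 0
  for (j in seq_len(nc)) {
    ca <- substr(seq_a, 3 * j - 2, 3 * j)
    cb <- substr(seq_b, 3 * j - 2, 3 * j)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (unname(code[ca]) == "*" || unname(code[cb]) == "*") next
    d <- oracle_path_counts(ca, cb, code)
    if (is.null(d)) next
    sa <- oracle_site_counts(ca, code)
    sb <- oracle_site_counts(cb, code)
    sd <- sd + d[["syn"]]; nd <- nd + d[["nonsyn"]]
    ss <- ss + (sa[["syn"]] + sb[["syn"]]) / 2
    ns <- ns + (sa[["nonsyn"]] + sb[["nonsyn"]]) / 2
  }
  list(syn_diff = sd, nonsyn_diff = nd, syn_sites = ss, nonsyn_sites = ns)
}

## random in-frame coding sequence without stop codons
random_coding_seq <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

## mutate a coding sequence at `k` random positions, avoiding stop codons
mutate_coding_seq <- function(seq, k) {
  repeat {
    s <- strsplit(seq, "")[[1]]
    for (pos in sample(length(s), k))
      s[pos] <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1)
    out <- paste(s, collapse = "")
    codons <- substring(out, seq(1, nchar(out), 3), seq(3, nchar(out), 3))
    if (!any(Biostrings::GENETIC_CODE[codons] == "*")) return(out)
  }
}

## exact binomial tail in the direction test_cohort uses
exact_tail <- function(c0, n, p) {
  if (c0 >= n * p) 1 - stats::pbinom(c0 - 1, n, p)
  else stats::pbinom(c0, n, p)
}
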