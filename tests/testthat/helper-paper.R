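## Loaders for the bundled transcriptions of the published tables.

paper_merge_map <- c(A01a = "A01", A01b = "A01")
paper_untypable <- c("B13", "B17", "B18")

paper_class_map <- function() {
  df <- utils::read.csv(silocus_example("label_classes.csv"),
                        stringsAsFactors = FALSE)
  stats::setNames(df$class, df$label)
}

paper_presence <- function()
  read_presence_matrix(silocus_example("f0_presence.csv"),
                       variant_merge_map = paper_merge_map,
                       class_map = paper_class_map())

paper_cohorts <- function(presence = NULL)
  read_cohorts(silocus_example("f1_cohorts.csv"), presence)

## expected haplotypes (label-set keys) and their published S names
paper_haplotype_keys <- function() {
  df <- utils::read.csv(silocus_example("s_haplotypes.csv"),
                        stringsAsFactors = FALSE)
  keys <- ifelse(is.na(df$label2) | df$label2 == "", df$label1,
                 paste(df$label1, df$label2, sep = "+"))
  stats::setNames(df$s_name, keys)
}

## expected F0 genotypes, as "key1 / key2" with keys sorted
paper_expected_genotypes <- c(
  "1"  = "B09+B12 / B10+B11", "2"  = "B09+B12 / B10+B11",
  "3"  = "B10+B11 / B10+B11", "4"  = "A01+A03 / B10+B11",
  "5"  = "A01+A03 / B09+B12", "6"  = "A01+A02 / A01+A03",
  "7"  = "A01+A03 / B06",     "8"  = "A06+A07 / B06",
  "9"  = "B06 / B17+B18",     "10" = "B01+B13 / B06",
  "11" = "B01+B13 / B04+C01", "12" = "A05 / B01+B13",
  "13" = "A05 / B04+C01",     "14" = "A05 / B04+C01",
  "15" = "A05 / B05",         "16" = "A05 / B05",
  "17" = "B04+C01 / B04+C01", "18" = "A01+A02 / B04+C01",
  "19" = "B03 / B06",         "20" = "B03 / B05",
  "21" = "A04 / B01+B13")

## label-set key of a catalog haplotype
catalog_keys <- function(catalog)
  ifelse(is.na(catalog$label2), catalog$label1,
         paste(catalog$label1, catalog$label2, sep = "+"))

## genotype of one individual rendered as "key1 / key2"
genotype_key_string <- function(genotypes, catalog, id) {
  keys <- stats::setNames(catalog_keys(catalog), catalog$haplotype)
  g <- geno_of(genotypes, id)
  paste(sort(unname(keys[g])), collapse = " / ")
}

## truth catalog of the simulator as sorted label-set keys
truth_catalog_keys <- function(truth)
  sort(unname(apply(truth$catalog, 1, function(r)
    paste(sort(stats::na.omit(c(r[["label1"]], r[["label2"]]))),
          collapse = "+"))))
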