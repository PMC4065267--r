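# silocus

S-locus genetics of sporophytic self-incompatibility (SSI), in R.

Plant biologists studying SSI systems (Brassicaceae and relatives) type
their material by PCR for SRK-like sequence variants, raise offspring
cohorts from controlled or open pollinations, and score fruit set in
diallel crossing designs. `silocus` turns those three tables — plus
codon alignments of the sequences themselves — into:

* a phased **S-haplotype catalog**: which sequence labels are linked on
  one haplotype (haplotypes here carry one *or two* linked SRK-like
  sequences, and one sequence can be shared by two distinct haplotypes),
  with diploid genotypes for every individual and explicit
  putative/confirmed homozygote calls;
* a **Monte-Carlo test of Mendelian segregation** per offspring cohort:
  heterozygote × heterozygote cohorts against 0.25/0.25/0.25/0.25,
  homozygote × heterozygote cohorts against 0.5/0.5, with per-class
  one-sided empirical tails from 100,000 simulated cohorts;
* per-organ **expression and dominance relations** among haplotypes,
  inferred from cross outcomes under the sporophytic rule (a cross fails
  iff some shared haplotype is expressed both in the donor's pollen and
  the receptor's stigma), plus compatibility predictions for any
  genotype pair;
* codon-aware **synonymous/nonsynonymous diversity** (π_S, π_N) by
  unweighted pathway counting, with per-column amino-acid variability
  and hypervariable-region overlays;
* a **simulator** that generates every input layer (haplotypes with
  linked labels, diploid panels, Mendelian cohorts, noisy diallel
  crosses) from a known ground truth — the basis of the test suite.

The statistical core in one line each: segregation uses the add-one
empirical tail `p = (1 + #{simulated ≥ observed}) / (reps + 1)` per
genotype class against the multinomial null; dominance is a sound
constraint propagation of cross outcomes to a fixed point over
`expressed/silenced` states per (genotype, organ, haplotype); diversity
is Nei–Gojobori-style counting, averaging substitutions over all minimal
codon pathways and sites over 1/3-site mutation fractions with
stop-changes excluded.

## Worked example

The package ships transcriptions of a published 21-individual panel:
the F0 presence/absence matrix, its 13 offspring cohorts, and a small
worked cross example. Three labels (`B13`, `B17`, `B18`) could not be
typed in progeny, and sub-variants `A01a`/`A01b` are treated as one
allele:

```r
library(silocus)

cm <- read.csv(silocus_example("label_classes.csv"))
run <- run_all(
  presence  = silocus_example("f0_presence.csv"),
  cohorts   = silocus_example("f1_cohorts.csv"),
  crosses   = silocus_example("worked_example_crosses.csv"),
  untypable = c("B13", "B17", "B18"),
  variant_merge_map = c(A01a = "A01", A01b = "A01"),
  class_map = setNames(cm$class, cm$label),
  reps = 100000, seed = 20131223)
print(run)
#> silocus run: 21 individuals, 20 labels, 13 cohorts
#>   catalog: 13 haplotypes (8 linked pairs)
#>   segregation: 11/13 cohorts conform
#>   dominance: 1 relation(s), 1 codominant pair(s)
```

The 20 sequence labels phase into 13 S-haplotypes, 8 of them linked
pairs; pairs containing a progeny-untypable label are supported by
perfect association in the panel only, and reported as such:

```r
run$catalog[c(1, 2, 6, 12, 13), c("haplotype", "label1", "label2", "support")]
#>    haplotype label1 label2             support
#> 1        H01    A01    A02       cosegregation
#> 2        H02    A01    A03       cosegregation
#> 6        H06    B01    B13 f0_association_only
#> 12       H12    B10    B11       cosegregation
#> 13       H13    B17    B18 f0_association_only
```

(Note `A01` sitting in two haplotypes: H01 and H02 are distinct
functional haplotypes sharing one sequence.) Eleven of the thirteen
cohorts conform to Mendelian expectations; the two deviating ones are
open-pollination cohorts, one deviating for one genotype class and one
for two:

```r
run$segregation[!run$segregation$conforms,
                c("cohort_id", "parent1", "parent2", "n", "case", "n_flagged")]
#>   cohort_id parent1 parent2  n            case n_flagged
#> 5       c05       9       4 21 case1_het_x_het         2
#> 7       c07      10       4  6 case1_het_x_het         1
```

The three homozygote × heterozygote cohorts conform with no unexpected
genotype class, confirming individuals 3 and 17 as homozygotes. The
bundled cross example (individuals 3 and 4: reciprocal crosses plus both
self-pollinations) resolves organ-specific dominance — the haplotype
shared by both individuals is silenced in the heterozygote's pollen but
expressed in its stigma, i.e. recessive in pollen only:

```r
subset(run$expression, genotype == "H02/H12")
#>    genotype  organ haplotype     state
#> 17  H02/H12 pollen       H02 expressed
#> 18  H02/H12 pollen       H12  silenced
#> 19  H02/H12 stigma       H02 expressed
#> 20  H02/H12 stigma       H12 expressed
run$dominance$relations
#>    organ genotype dominant recessive
#> 1 pollen  H02/H12      H02       H12
```

A thin command-line wrapper with the same stages lives in
`inst/scripts/silocus.R`:

```sh
Rscript inst/scripts/silocus.R run-all \
  --presence f0_presence.csv --cohorts f1_cohorts.csv \
  --crosses crosses.csv --untypable B13,B17,B18 \
  --merge A01a=A01,A01b=A01 --reps 100000 --seed 1 --out out/
```

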