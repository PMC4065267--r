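---
title: "Methods: S-locus genetics of sporophytic self-incompatibility"
author: "silocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: S-locus genetics of sporophytic self-incompatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In sporophytic self-incompatibility (SSI), as found across Brassicaceae, a
single genomic region — the S-locus — controls the rejection of self
pollen. Each S-haplotype encodes a pollen-coat ligand (SCR) and a stigma
receptor kinase (SRK); a pollination fails when some haplotype's
specificity is *expressed* both on the pollen side (a phenotype of the
diploid pollen **donor**, hence "sporophytic") and in the stigma of the
receptor. Because the pollen phenotype is sporophytic, haplotypes can
dominate or silence one another within a heterozygote, independently in
pollen and stigma.

Typing surveys of such systems produce four kinds of data, and `silocus`
ingests all of them:

1. a presence/absence matrix of SRK-like **sequence labels** per diploid
   individual (PCR typing; a haplotype may carry one *or two* tightly
   linked labels, so an individual can show up to four labels);
2. **offspring cohorts**: counts of label combinations among the typed
   progeny of known parent pairs;
3. a **diallel cross table**: fruit set per ordered (pollen donor, pollen
   receptor) pair, with replicates;
4. in-frame **codon alignments** of the sequence labels themselves.

From these the package phases S-haplotypes, tests Mendelian segregation,
infers per-organ dominance, and computes synonymous/nonsynonymous
diversity. A simulator generates all four layers from a known ground
truth, which is how the pipeline is validated.

# Phasing S-haplotypes

## Transmission vectors and co-transmission clustering

Within a cohort, the one or two labels riding on one parental haplotype
are transmitted together. For each parent and each label it carries,
`transmission_vectors()` records the presence pattern of the label across
the cohort's offspring classes. A label carried by *both* parents cannot
be attributed to either and is recorded as missing, never guessed. This
attribution rule is the package's own decision: typing data do not say
which parent contributed a label both parents carry, and informative
crossing designs avoid the situation.

`cluster_cotransmitted()` groups labels with identical patterns (on
jointly non-missing positions). Three special patterns matter:

* a label present in **every** informative offspring is consistent with
  membership in *both* of the parent's haplotypes — this is the
  shared-label case (one label occurring in two distinct haplotypes) —
  and is attached to both groups;
* if **all** labels are always present the parent may simply be
  homozygous; the clustering is then uninformative and says so rather
  than emitting pairs;
* a label seen in *no* offspring may ride on a haplotype that happened
  never to be transmitted; it is set aside.

More than two residual groups, or two non-complementary groups, violate
diploid transmission; the cohort is flagged inconsistent, never forced.

## Two support tiers for linked pairs

`infer_linked_pairs()` aggregates over all cohorts and parents. A pair is
supported by **cosegregation** when some clustering co-groups it and no
cohort separates it; co-grouped in one cohort but separated in another is
a hard error naming both cohorts. Pairs that were never *testable* in any
cohort — typically because one label cannot be scored in progeny — can
still be recovered from the parental panel alone: if the two labels
co-occur in at least one individual and no individual carries exactly one
of them, the pair is reported with the lower **f0_association_only**
tier. The tier is deliberately conservative labelling, not a different
algorithm: perfect association in a small panel can arise by chance, and
downstream consumers should know which pairs rest on it.

## Catalog and genotypes

`build_catalog()` turns pairs into two-label haplotypes and all remaining
labels into singletons, ordered deterministically by (class tag, first
label, second label) and numbered `H01`, `H02`, ...; an external name map
can overlay conventional names. `assign_genotypes()` then explains each
individual's label set as an exact cover by one or two haplotypes. A
shared label is disambiguated by which partner labels are present.
Individuals explained by a single haplotype are flagged
`putative_homozygote` — never silently doubled into a confirmed
homozygote; confirmation requires the segregation evidence below
(`confirm_homozygotes()`). Multiple covers are reported as ambiguous, no
cover is an error.

# The Monte-Carlo segregation test

Two crossing schemes arise at a single-locus with complete typing:

* **case 1**, heterozygote × heterozygote: four offspring genotype
  classes, each expected at frequency 0.25;
* **case 2**, homozygote × heterozygote: two classes at 0.5 (applied when
  one parent is a putative/confirmed homozygote and at most two genotype
  classes were observed).

For a cohort of size $n$, `simulate_null()` draws 100,000 multinomial
cohorts under the case's expectation. `test_cohort()` computes, per
expected class, a one-sided Monte-Carlo tail probability in the direction
of the observed deviation, with the add-one correction
$p = (1 + \#\{\text{simulated counts as-or-more extreme}\})/(\text{reps}+1)$
so that $p$ is never zero. A class is flagged at $\alpha = 0.05$; no
multiple-testing correction is applied across classes or cohorts.
Unobserved expected classes are tested like any other (lower tail).
Offspring falling in a genotype class the cross cannot produce reject the
cross hypothesis outright — under the null such classes have probability
zero — which is how the "more than two genotypes" alternative of case 2
is assessed.

The tail convention, $\alpha$, and the absence of a correction are the
package's own reconstruction: they are the convention under which the
bundled example tables reproduce their published reading (eight of ten
heterozygote × heterozygote cohorts conforming, two deviating, all
homozygote × heterozygote cohorts conforming), which is the only
calibration those tables provide.

All tests are deterministic given `seed`; `batch_test()` derives one seed
per cohort from it.

## Numerical note: validating the estimator against the exact binomial

The marginal of one class under the multinomial null is
$\mathrm{Bin}(n, 0.25)$ (or $0.5$), so each Monte-Carlo tail has an exact
oracle. The test suite compares the two across all cohort sizes 5–50 and
all observable counts. Two numerical realities shape that comparison:
the add-one estimator has a resolution of one simulation draw
($1/(\text{reps}+1)$), which dominates the nominal standard error
$\sqrt{p(1-p)/\text{reps}}$ in the far tails; and across ~2,600
comparisons a fraction of about 0.3% *must* exceed three standard errors
by pure chance at any number of replicates. The suite therefore
standardizes each deviation with a one-draw resolution floor on the
standard error, bounds the share of >3-s.e. points by its own sampling
bound, and requires every point to stay within five floored standard
errors.

# Dominance inference

## Expression states by constraint propagation

Expression is modelled **per genotype**, per organ, per haplotype, with
states `expressed`, `silenced`, `ambiguous` (undetermined) and
`conflicting`. Global statements ("X is recessive in pollen") are
summaries, never primary calls — the same haplotype may behave
differently in different genotypes.

`consolidate_crosses()` first merges replicates and different individuals
with identical genotypes into one consensus outcome per ordered genotype
pair; mixed outcomes are `conflicting` and excluded from inference
(`method = "majority"` instead takes the majority call, the natural
choice for deliberately replicated noisy designs). Non-reciprocal
outcomes are used only in the direction observed, never symmetrized.

`infer_expression()` then propagates two sound rules to a fixed point:

* an **incompatible** cross constrains its shared haplotypes: at least
  one must be expressed in the donor's pollen *and* the receptor's
  stigma. When all but one shared haplotype is already silenced on
  either side, the remaining one is forced expressed on both. (A
  self-incompatible homozygote `XX` is the degenerate case: `X` is
  forced expressed in both organs.)
* a **compatible** cross sharing `X` forbids `X` being expressed on both
  sides: if one side is known expressed, the other is forced silenced.

Each cell moves monotonically `ambiguous → {expressed, silenced} →
conflicting`, so the iteration terminates. No rule ever rewrites
`expressed` into `silenced` directly; contradictory derivations surface
as `conflicting`, and incompatibilities with no viable shared haplotype
(including crosses sharing none) are reported as unexplained rather than
bent into the model.

`build_dominance()` reads pairwise relations off the states (`X`
expressed with `Y` silenced = `X` dominant in that genotype and organ;
both expressed = codominant), aggregates them per organ and flags cycles
in the aggregated graph.

## Prediction

`predict_compatibility()` applies the sporophytic rule: incompatible iff
some shared haplotype is expressed in the donor's pollen and the
receptor's stigma. The call is `undetermined` whenever an `ambiguous` or
`conflicting` cell could flip that intersection or a genotype is not
covered — the prediction never resolves what the data did not.

# Synonymous and nonsynonymous diversity

The codon-aware statistics use unweighted pathway counting. Each of a
codon's nine single-nucleotide changes carries 1/3 of a site; changes
creating a stop codon are excluded, so a codon's synonymous +
nonsynonymous sites equal 3 minus the excluded fraction. Between two
codons differing at $k$ positions, differences are averaged over all $k!$
minimal substitution pathways, excluding pathways traversing a stop; if
every pathway is blocked the codon pair is excluded. Codons containing a
gap, `N`, or a stop in either sequence are removed pairwise
(complete-codon deletion), and sites are averaged between the two
sequences.

Within a group, $\pi_S$ is the mean over all unordered pairs of
(synonymous differences / synonymous sites), $\pi_N$ analogously; the
reported `n_sites` is the minimum over pairs of retained nucleotide
columns. Proportions are raw by default; `jukes_cantor = TRUE` applies
the JC69 multiple-hit correction per pair before averaging. The default
is raw because the upstream tooling this mirrors does not document which
option historical analyses used, and raw proportions are the conservative
common denominator. The genetic code defaults to the standard table and
is overridable.

`per_column_variability()` translates the alignment codon-wise (gap/`N`
cells masked), counts distinct residues per column with their
frequencies, and overlays named intervals such as the SRK hypervariable
regions HV2/HV3 — coordinates are supplied by the user, 1-based and
inclusive, in amino-acid columns.

The implementation is validated against an independent recursive
pathway-enumeration oracle on random 30-codon pairs, to $10^{-12}$.

# The simulator

`sim_config()` defaults describe the study design the pipeline targets:
13 S-haplotypes of which 8 carry a linked label pair and one label is
shared between two same-class haplotypes (so 20 labels in total), a panel
of 21 diploid individuals with 2 homozygotes, 13 offspring cohorts with
sizes 5–50, a pollination failure rate of 0.29 on compatible crosses and
an SI leakage rate of 0.09 on incompatible ones (the complements of the
~71% positive-control and ~9% shared-haplotype fruit-set rates such
surveys report).

Design choices worth knowing:

* **Transmission is purely Mendelian** (each offspring receives one
  haplotype per parent at 0.5). No SI filtering operates within a
  compatible cross, because all pollen from one donor shares one
  sporophytic phenotype; this is exactly what makes the 0.25/0.5
  expectations valid.
* **Cohort parent pairs** are chosen greedily to cover every haplotype
  with at least one *heterozygous* cohort parent, preferring pairs whose
  parents share no sequence label. Both preferences mirror an informative
  crossing design: a homozygous parent transmits its labels to every
  offspring (no signal), and a label carried by both parents is
  unattributable in progeny. Without them, shared-label haplotypes are
  frequently unrecoverable through no fault of the phasing.
* **Dominance schemes** per organ: `codominant` (all expressed),
  `linear` (a random strict rank order), or `class_levels` (class A
  dominant over class B, codominance within a class, matching the
  recurring observation that recessive haplotypes concentrate in one
  sequence class).
* Untypable labels are masked **only** in cohort observations, never in
  the parental presence matrix, mirroring progeny typing failures.

What the simulator does **not** emulate: typing error in the parental
matrix (false positives/negatives), partial typing, population structure
or relatedness among panel members, multi-generation dynamics and
frequency-dependent selection, and quantitative dominance modifiers.
Green recovery tests therefore certify the inference logic under faithful
typing, not robustness to corrupted presence calls.

# Validation problem sizes

The test suite validates at these sizes, chosen to exercise the same
regime as the target study while keeping the default run fast:

* **parameter recovery**: 200 seeded configurations with 5–8 haplotypes
  (half carrying linked pairs, one shared label), 15–24 individuals, one
  homozygote, and one 25-offspring cohort per haplotype, at zero noise.
  The catalog must be recovered exactly in ≥95% of configurations,
  wrong pairs must never carry cosegregation support, and every resolved
  dominance relation must match the simulated ranks;
* **consensus calling**: one 40-individual diallel at the default noise
  rates with 3 replicates per cross; majority consensus must miscall
  latent compatibility less often than single replicates;
* **segregation oracle**: all cohort sizes 5–50, both cases, 100,000
  replicates, against the exact binomial;
* **diversity oracle**: 100 random 30-codon pairs against recursive
  pathway enumeration.

Expression resolution on simulated diallels is data-limited, not
solver-limited: a haplotype at the bottom of the pollen hierarchy, for
example, is only resolvable when the panel contains its homozygote (the
analogue of the recessive-haplotype homozygotes such panels tend to
contain, since recessive haplotypes reach higher frequencies). The
recovery tests therefore assert soundness of every resolved call rather
than a fixed resolution percentage.

# Known limitations

* Phasing assumes the presence matrix itself is error-free; a single
  false presence call can make an individual's label set uncoverable
  (which is reported, not repaired).
* The F0-association tier cannot distinguish a true linked pair from a
  chance perfect association among rarely-carried labels; it is labelled
  accordingly.
* The segregation test is reconstructed (tail convention, threshold); a
  study that states its own convention should set `alpha` and interpret
  flags accordingly.
* Expression calls are per genotype; the package deliberately refuses to
  extrapolate a relation observed in one genotype to another.
* Diversity statistics implement unweighted pathway counting only; no
  maximum-likelihood codon models are provided.
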