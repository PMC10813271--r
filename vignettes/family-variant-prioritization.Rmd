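---
title: "Family-based variant prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fampri)
```

## The problem and the model

Familial non-medullary thyroid carcinoma (FNMTC) — follicular-cell thyroid
cancer in two or more first-degree relatives without a syndromic cause —
behaves like a low-penetrance dominant trait with strong genetic
heterogeneity: susceptibility variants tend to be private to a single
family. Discovery therefore proceeds by exome sequencing a pedigree and
asking which variants (a) segregate with the phenotype, (b) are rare enough
in the relevant population to be plausible for a disease with incidence on
the order of 10^-4^, and (c) look damaging to protein function.

`fampri` operationalizes that reasoning as a deterministic filter cascade
over a genotype matrix (per-variant alternate-allele dosage, 0/1/2, with
missing kept distinct from 0), an annotation table (region and function
class, four population allele-frequency columns, and SIFT / PolyPhen2 HDIV /
MutationTaster scores and calls, as produced by a dbNSFP-style annotator),
and a pedigree. The model is autosomal-dominant throughout; recessive,
compound-heterozygous and X-linked analyses are out of scope.

## The filter cascade

Stages run in a fixed order, each a set-shrinking predicate, with an audit
count recorded after each:

1. **Affected intersection.** Keep a variant only if every affected member
   carries it (dosage 1 or 2). A *missing* genotype in an affected member
   excludes the variant: carriage cannot be confirmed. This is the
   conservative choice for a discovery screen and is deliberate — the
   alternative (treating missing as compatible) would admit variants whose
   segregation was never observed.
2. **Control exclusion.** Drop a variant carried by any designated control.
   A missing control genotype does *not* drop the variant (absence of
   evidence). Controls are designated explicitly rather than inferred from
   affection status, because in real families only confidently unaffected,
   sufficiently old members are safe controls for a late-onset phenotype.
   In the worked example the elderly control II2 is the sole cascade
   control, while the young unaffected offspring III9 is used for
   validation-stage confirmation only — a young non-carrier proves little
   for a low-penetrance trait, and this split mirrors how such studies
   actually treat the two.
3. **Region filter.** Keep `exonic` and `splicing` variants.
4. **Function filter.** Drop `synonymous_SNV`.
5. **Zygosity filter.** Drop variants homozygous-alternate in *all*
   affected members. Under a dominant model a fully homozygous site across
   all patients is far more likely a reference artifact or a common
   haplotype than a causal dominant allele. The phrase is operationalized
   per variant, not per gene.
6. **Frequency screen.** Drop a variant whose maximum non-missing screened
   frequency exceeds 0.001, *strictly*: a frequency of exactly 0.001 is
   kept. The screened fields default to the East Asian columns only
   (`af_1000g_eas`, `af_exac_eas`), because the family under study is East
   Asian and the continental columns are the ones that discriminate: a
   variant can be globally rare but common in EAS and vice versa. Rows with
   no catalogued frequency pass (`na_policy = "pass"`): absence from the
   catalogues is itself evidence of rarity. Both choices are configurable
   in `cascade_config()`.

Stages 3–6 are pairwise independent predicates, so their order cannot
change the final set (a property the tests verify); the order above is kept
for interpretable audit counts. The cascade is idempotent: run on its own
survivors it is a fixed point.

## Pathogenicity banding and the hazard score

The three predictors are banded as published: SIFT calls D (deleterious) at
score ≤ 0.05; PolyPhen2 HDIV calls D at ≥ 0.957, P (possibly damaging) in
[0.453, 0.956] and B at ≤ 0.452; MutationTaster's A and D categories are
harmful calls, N and P are polymorphism calls. The PolyPhen2 bands leave
the open intervals (0.452, 0.453) and (0.956, 0.957) unassigned; scores
falling there are assigned to the lower, more benign band — the
conservative reading.

The composite hazard score is a per-category weight sum:

$$H = \underbrace{1[\mathrm{SIFT}=D]}_{0\ \mathrm{or}\ 1}
    + \underbrace{1[\mathrm{PP2}=D] + \tfrac12\,1[\mathrm{PP2}=P]}_{0,\ 0.5\ \mathrm{or}\ 1}
    + \underbrace{1[\mathrm{MT}\in\{A,D\}]}_{0\ \mathrm{or}\ 1}$$

A missing call contributes 0: no evidence is not evidence of harm. The
weighting was chosen as the simplest per-category rule consistent with the
banding semantics — each predictor contributes at most 1, and PolyPhen2's
intermediate category contributes half. MutationTaster "P" ("polymorphism
automatic") is weighted 0 despite the letter it shares with PolyPhen2's
"possibly damaging".

Categorical calls shipped in the annotation table take precedence over
re-banding from scores; banding fills in missing calls only (MutationTaster
has no score-to-band rule, so a missing MT call stays missing). Annotators
ship both, and the shipped call may encode transcript-selection decisions
the raw score does not.

Ranking is by H descending, then PolyPhen2 score descending, then SIFT
score ascending (lower = more deleterious; missing last), then gene symbol.
The ranking is advisory: the package never auto-selects a single gene,
because the last step of such a study — picking the gene to take into the
laboratory — also weighs biological plausibility and novelty.

## Cosegregation probability

For a variant observed in `m` informative meioses — genotyped carrier
offspring of a genotyped carrier parent — the probability of chance
cosegregation is $(1/2)^m$. Founders are not meioses; a genotyped
non-carrier offspring is not counted either, because the convention
implemented counts *carrier transmissions* observed, the exponent that
standard supporting-evidence arithmetic uses. An alternative convention
also counts the observed non-transmission to an unaffected non-carrier
offspring (which would give $m + 1$); the package documents but does not
adopt it. In the built-in family template, the carrier parent II3 with
carrier offspring III3, III5 and III7 gives m = 3 and probability 0.125,
rendered `"12.5%"` — supporting evidence only, which is why cohort
screening and functional follow-up exist.

## Cohort screening

`screen_cohort()` counts carriers of a variant in an independent cohort
matrix; `population_lookup()` checks a frequency-table extract. Two
conventions matter: the *absent* claim is driven by the carrier count (the
per-sample presence/absence a Sanger validation reports), and missing
genotypes are excluded from the allele-frequency denominator. A variant
absent from a frequency table returns an absent flag, not an error.

## The synthetic-data generator

`generate_study()` emits a complete, runnable study: VCF, PED, annotation
TSV, a cohort VCF and a truth JSON. It emulates the study conditions the
cascade assumes:

* **Pedigree**: the built-in `fig1` template — a two-generation family with
  an affected parent (II3), three affected and one unaffected offspring,
  an elderly unaffected control (II2) in the parental generation, and
  ungenotyped founders/spouse — six genotyped members in all. Custom
  templates are accepted as member tables.
* **Causal variant**: planted heterozygous in the carrier founder and
  assigned to descendants so that carrier status matches affection with
  probability `penetrance` (default 1.0, the fully penetrant design the
  recovery guarantees assume). Its annotation row is exonic,
  nonsynonymous, uncatalogued in all four frequency fields, with
  deleterious-profile predictor draws: SIFT ~ U(0, 0.05),
  PolyPhen2 ~ U(0.957, 1), MutationTaster D with probability 0.9, else N —
  so most causal draws score 3 and all score at least 2.
* **Background**: 5,000 variants by default, allele-frequency mixture 20%
  uncatalogued / 20% rare U(0, 0.001] / 60% common U(0.001, 0.2] — an
  after-intersection exome skews common, since the affected-intersection
  step has already happened upstream of what the annotation catalogues
  describe. Uncatalogued variants are simulated at founder frequency
  5 × 10^-4^ ("not catalogued" means unobserved, not impossible), so rare
  background survivors exist and specificity is testable. Regions follow
  an exome-realistic mix (55% exonic, 5% splicing, the rest non-coding);
  40% of exonic background variants are synonymous. Background predictor
  scores are benign-leaning (SIFT uniform, PolyPhen2 Beta(1, 4),
  MutationTaster 70% N / 10% P / 15% D / 5% A).
* **Genotypes**: founders drawn from Hardy–Weinberg at the variant's
  frequency; each offspring receives one allele per parent with
  probability dosage/2; a member with an unrecorded parent draws that
  allele from the population. No linkage disequilibrium between background
  variants, no genotyping error, and no missingness are simulated;
  missing-genotype behavior is tested by direct injection instead. Passing
  the recovery tests therefore shows the pipeline's logic is correct under
  clean Mendelian data, not that it is robust to call-rate or QC artifacts
  in real exomes.
* **Determinism**: one integer seed drives every draw; identical
  configuration and seed give byte-identical output files.

The expected number of background survivors has a closed form — the product
of the per-variant genotype-pattern probability (computable by exact
enumeration over founder genotypes and Mendelian transmission) and the
deterministic annotation predicates — and the test suite checks observed
counts against that expectation within binomial error.

## Numerical and degenerate-input choices

* Variant identity is `chrom:pos:ref:alt` with the `chr` prefix stripped,
  1-based positions, SNVs only; multiallelic VCF records are an error, not
  silently split. Duplicate ids are an error.
* `NA` is serialized as the literal token `NA` in all TSVs.
* An empty variant set runs the whole cascade and returns an empty, valid
  candidate table with all-zero audit counts.
* An all-missing cohort yields an `NA` allele frequency rather than 0/0.
* Cosegregation rejects negative or non-integer m; m = 0 returns 1 (empty
  product).
* Alignment-column conservation excludes gaps from the denominator and is
  exact-identity based (no substitution-matrix similarity): the claim being
  assessed is literal preservation of a residue across species.

## Problem sizes used by the test suite

The randomized checks run at sizes chosen to make the statistical
assertions sharp while keeping the suite fast on one core: the brute-force
cascade oracle at 500 variants × 12 samples × 50 trials; hazard-score
monotonicity over all 3 × 4 × 5 predictor-category combinations; causal
recovery and background-survivor calibration over 200 simulated studies of
5,000 background variants each; Hardy–Weinberg calibration on 10,000
founders.

## Known limitations

* Dominant, fully genotyped-nuclear-family logic only; no LOD-score or
  Bayesian cosegregation framework (the $(1/2)^m$ arithmetic is the
  supporting-evidence convention, not a full linkage analysis).
* Predictor scores and population frequencies are *inputs*; the package
  never computes annotations, and its conclusions inherit their quality.
* The hazard score is a transparent tally, not a calibrated pathogenicity
  probability; equal scores are not equal posteriors.
* SNVs only; indel normalization and multiallelic splitting are upstream
  problems.
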