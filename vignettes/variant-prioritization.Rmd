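---
title: "Family-based rare-variant prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedprio)
```

## The problem

In a multigenerational family in which a disease recurs in a pattern
consistent with autosomal-dominant inheritance, a new causal variant can be
sought by sequencing a handful of affected and unaffected relatives and
asking three questions of every variant observed:

1. **Is it rare?** A dominant, highly penetrant disease allele cannot be
   common in the population, so any variant with an appreciable frequency in
   ExAC, gnomAD or the 1000 Genomes panel is excluded.
2. **Could it damage the protein?** Only protein-altering consequence
   classes (missense, stop gain, frameshift, splice, in-frame indel) are
   retained.
3. **Does it co-segregate?** Under the dominant model every affected
   relative should carry at least one copy and every unaffected relative
   none; a single exception disqualifies the variant.

Survivors are then ordered by a *cumulative damaging score*: a weighted
count of in-silico deleteriousness predictors whose thresholds the variant
meets. `pedprio` implements this pipeline end to end, and ships a
gene-dropping simulator so the whole analysis can be validated on synthetic
families with a known answer.

## The co-segregation model

Affection status and genotype are compared member by member. With
alternate-allele count $g_i \in \{0, 1, 2\}$ and affection $y_i$:

* $y_i$ affected and $g_i \ge 1$: **consistent** (heterozygous carriers
  suffice under dominance);
* $y_i$ unaffected and $g_i = 0$: **consistent**;
* any other informative combination: **violation**;
* unknown affection or missing genotype: **uninformative**.

A variant *segregates* when there are zero violations and at least
`min_informative` informative members (default 2, the smallest number that
can represent both an affected carrier and an unaffected non-carrier; the
threshold exists so that a variant genotyped in nobody is never called
segregating). The verdict is purely consistency-based: no LOD score or
likelihood is computed, because the sample sizes this design targets (a
handful of sequenced relatives in one family) do not support linkage-style
likelihood comparisons, and the consistency rule is the decision actually
applied when filtering candidates. By construction
`n_consistent + n_violations = n_informative` always, and the verdict is
invariant to member ordering — both properties are enforced by tests against
a brute-force enumeration oracle on all $3^n$ genotype assignments of small
pedigrees.

Two phenotype-coding decisions matter. Prodromal cases (amnestic mild
cognitive impairment in the dementia setting this package grew out of) are
coded *affected*: in a family segregating a fully penetrant allele they are
early manifestations of the same genotype, and coding them unknown would
discard the most informative young carriers. Members of genuinely uncertain
status are coded *unknown* and are permanently uninformative — a
conservative choice that can only reduce, never inflate, the evidence for
segregation. Deceased or ungenotyped members are simply uninformative; no
genotype is imputed from relatives.

## The filter cascade

Stages run in the order **consequence → rarity → segregation** (cheapest
check first; the per-variant verdicts are order-independent, so the order
affects only the funnel log, never the survivors). Each stage logs
`(n_in, n_pass, n_fail)` with `n_in = n_pass + n_fail` and each stage fed by
the previous stage's passes — an invariant the tests check on randomized
inputs.

* **Rarity.** A variant fails when *any* present database frequency is
  `>= maf_threshold`. The default threshold 0.001 is a reconstruction of
  common practice for dominant disorders, not a measured value; it is
  configurable. A variant absent from every database *passes flagged*
  (`missing_af_policy = "pass_flagged"`): a never-observed allele is
  consistent with being rare, and failing it would systematically discard
  exactly the novel variants the analysis exists to find. The flag is
  carried into the report so these candidates remain visible as such.
* **Consequence.** Whitelist membership; a missing consequence fails,
  since the variant cannot be shown to alter the protein.
* **Known-gene screen.** The established genes for the phenotype (default
  APP, PSEN1, PSEN2) are *reported*, never filtered: in the workflow this
  package models, those genes are excluded by targeted sequencing before
  any genome-wide search, so a hit there is a red flag to surface, not a
  candidate to rank.

## The cumulative damaging score

A *criterion* is one tool's damaging rule: `numeric_below` (e.g.
SIFT < 0.05), `numeric_above` (e.g. CADD phred > 20), or `label_in` (e.g.
MutationTaster in {A, D}). All inequalities are strict — the rules are
written as strict inequalities, so boundary values are unsatisfied. The
score of a variant is the sum of the weights of its satisfied criteria;
`n_tools_deleterious` counts satisfied criteria with weights ignored.
Missing annotations contribute nothing and are flagged per tool, so a
sparsely annotated variant is neither advantaged (it cannot score on tools
it lacks) nor silently penalized (the report shows *why* its score is low).

The default registry has 14 unit-weight criteria: SIFT < 0.05,
PolyPhen2 > 0.8, CADD phred > 20, CADD raw > 2, GERP++RS > 4,
M-CAP > 0.025, LoFtool < 0.5, and damaging-label rules for Condel, DANN,
FATHMM, LRT, MetaLR, MutationTaster and PROVEAN. CADD phred and raw are
deliberately two criteria (both rules are stated independently), which is
why the default registry has 14 entries for 13 underlying tools. The label
vocabularies are the conventional dbNSFP-style codes and are fully
remappable; DANN in particular is distributed as a numeric score in some
annotation sources and can be reconfigured as `numeric_above` with a
user-chosen threshold. The maximum score is always *derived* as the sum of
weights, never hard-coded: published analyses of this kind sometimes quote
score ranges (e.g. 0–20) implying additional or re-weighted criteria in
their full registry, and the registry is therefore a config file, not a
constant. The package ships one such weighted reconstruction
(`inst/extdata/criteria20_synthetic.json`, 14 criteria with weights summing
to 20) used by the worked example; its weights are the package's own
construction, chosen to reproduce a published ordering, and are labelled
synthetic accordingly.

Ranking is by descending score, ties broken by descending CADD phred (the
most widely used single calibrated scale), then ascending (chrom, pos) for
determinism. Ranks are 1-based and dense; rows identical on the full sort
key share a rank.

## Variant and annotation ingest

Coordinates are 1-based throughout, as in VCF. Multi-allelic sites are
split on ingest — one record per ALT allele, with genotypes recoded as
counts of *that* allele — and genotypes are treated as unphased (`0|1` ≡
`0/1`). Records are reduced to minimal representation by trimming the
shared suffix, then the shared prefix while advancing the position and
keeping an anchor base; this is idempotent and leaves SNVs untouched. Full
left-alignment through repetitive flanking sequence additionally requires
the reference genome, which this pipeline deliberately never loads; callers
emitting GATK-normalized VCFs already satisfy it. The annotation join is by
the canonical `chrom:pos:ref:alt` key after normalization; VCF records
without an annotation row receive an all-missing profile rather than an
error. Population-frequency column names default to `ExAC_AF`, `gnomAD_AF`,
`KG1000_AF` and are remappable in the filter config.

## What the simulator emulates — and what it does not

`simulate_family_dataset()` generates the statistical structure the
analysis assumes:

* a **pedigree template** (`ad23`: four generations, 23 members, with the
  seven conventionally sequenced members — five affected, an unaffected
  aunt and cousin — in fixed relationships; the full topology is a
  synthetic reconstruction satisfying the documented composition of 8
  affected / 11 unaffected / 4 unknown);
* one **causal variant** planted heterozygous in a founder (default the
  affected founder `I-1`, absent from the population) and transmitted by
  gene dropping: each non-founder receives one allele drawn uniformly from
  each parent's two;
* **background variants** (default 500), unlinked, with founder genotypes
  drawn by Hardy–Weinberg at allele frequencies from Beta(0.5, 50) — a
  rare-variant site-frequency profile with median ≈ 0.5% and a long tail,
  so that a realistic majority of background variants fail the rarity
  filter and the remainder exercise the segregation stage;
* **phenotypes** from carrier state under `penetrance` (default 1) and
  `phenocopy_rate` (default 0) — the fully penetrant dominant regime the
  design assumes; a config switch (`fixed_phenotypes`) keeps the template's
  recorded statuses instead;
* **annotation profiles** drawn per criterion on the damaging side (causal)
  or benign side (background) of each rule, flipped with probability
  `annotation_noise` (default 0.1), numeric values uniform within the
  side's window on the tool's documented scale (e.g. benign SIFT ~
  U(0.05, 1));
* only the **sequenced subset** (default the seven members above) appears
  in the emitted VCF, and a truth file names the planted key.

Everything is reproducible under the config seed, and two runs with the
same seed write byte-identical files (the VCF writer emits deterministic
plain text for exactly this reason).

The simulator does *not* emulate linkage disequilibrium between background
variants, realistic genomic coordinates or sequence context, mutation-rate
heterogeneity, sequencing error, or ascertainment of the family through its
proband. Consequently, passing tests demonstrate that the pipeline's logic
is correct under its own model — Mendelian transmission, independent rare
background, class-separated predictor profiles — not that the method is
robust to correlated annotations or cryptic relatedness in real cohorts.

## Numerical and degenerate-input choices

* Strict inequalities everywhere in criteria; frequency `>= threshold`
  fails rarity (a boundary allele is not rare).
* Empty genotype maps, empty VCFs and empty candidate sets are valid
  inputs: the pipeline returns an empty ranked report with a zero funnel
  and exit status success — absence of candidates is a finding.
* Homozygous alternate genotypes count as carriers (one individual, one
  carrier) and are Mendelian-legal in the simulator.
* Ties in ranking are resolved deterministically as described; two truly
  identical records share a dense rank.
* Sub-seeds for replicate runs are formed by small integer offsets from the
  user seed, keeping every seed well inside 32-bit range.

## Problem sizes used in validation

The shipped validation uses full enumeration of all $3^n$ genotype
assignments on pedigrees of up to 7 members against an independent
consistency oracle; 1,000 random profiles against an independent score
summation; 10,000-offspring transmission and 10,000-carrier penetrance
calibrations (3-SD binomial bands); an exact-enumeration null calibration
of the segregation pass probability on a 6-member family at allele
frequency 0.2 over 600 variants; and 200 seeded end-to-end replicates of
the default 501-variant dataset, in which the planted variant is required
to reach rank 1 in at least 95% of runs. These sizes were chosen to give
3-SD statistical resolution on every calibrated quantity while keeping the
whole suite around a minute on a single core.

## Known limitations

* Dominant model only; recessive, X-linked and compound-heterozygous
  designs are out of scope, as are kinship estimation and relationship
  checking from genotypes.
* The consistency verdict treats the pedigree as error-free: one genotyping
  error in one member disqualifies a true variant. With `min_informative`
  members in the low single digits this is the intended strictness, but
  users with larger families may wish to inspect `violating_ids` rather
  than rely on the boolean.
* Predictor scores are consumed, never recomputed or calibrated; the
  package takes no position on the validity of any individual tool.
* The weighted example registry and the 23-member pedigree topology are
  documented synthetic reconstructions (see the files' headers); analyses
  of real families should supply their own registry and PED.
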