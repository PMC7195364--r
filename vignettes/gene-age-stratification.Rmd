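---
title: "Gene-age stratification and stress-expression enrichment: methods"
author: "agestrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-age stratification and stress-expression enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestrat)
```

## The problem

Comparative transcriptomics of stress adaptation keeps running into the
same obstacle: the genes that respond to stress are disproportionately
genes of unknown function, and genes of unknown function are
disproportionately *young* — restricted to a genus or species, or recently
duplicated. To quantify that association one needs a principled way to
assign an evolutionary age to every protein-coding gene of a focal
species, and unbiased statistics for asking whether differential
expression concentrates in particular age strata. `agestrat` provides
both, plus a simulator that generates data with known ground truth so the
whole pipeline can be validated end to end.

## The model

### Species ladder

All dating is relative to a **species ladder**: an ordered sequence of
rungs, each a set of taxa, with rung 1 the focal species alone and deeper
rungs diverging earlier from the focal lineage. Divergence times in
million years (Myr) may be attached per rung; they are metadata for
interpretation and for adaptation rates, not inputs to the sorting itself.
Labels default to Roman numerals with I the oldest rung — the convention
in the yeast literature, where group V means species-specific and group I
means conserved out to filamentous fungi.

The ladder must satisfy: rung 1 = {focal}; rung species sets pairwise
disjoint; every species appearing in the orthogroup table mapped to
exactly one rung (an unmapped species is an error, not a warning — it
would silently shift ages); divergence times non-decreasing with depth.

### Age assignment

The input is an orthogroup table: a partition of genes across species into
groups descending from single ancestral genes, as produced by OrthoFinder.
Genes are assigned in three subsets, in order:

1. **WGD.** Ohnolog pairs from a whole-genome duplication are taken as an
   explicit input list and form their own group. We deliberately do not
   infer ohnologs from synteny — that is a hard problem with dedicated
   tools, and the WGD group only exists for species that underwent one;
   for other species the list is simply omitted and no WGD group appears.

2. **Single-copy genes** (focal copy number 1) are dated by *origin*: the
   deepest rung in which at least one species carries any member of the
   gene's orthogroup. A gene with no ortholog outside the focal species
   dates to rung 1. This is phylostratigraphy with orthogroups as the
   homology unit.

3. **Multi-copy genes** (focal copy number `n >= 2`, not in the WGD list)
   are dated by *duplication timing*: scanning rungs bottom-up, the
   deepest rung in which at least one species carries exactly `n`
   members. The rationale: if a congener kept the same copy number, the
   duplication predates the split; if every distant relative has one copy,
   the duplication postdates those splits. When no species matches `n`
   anywhere, the duplication is dated to rung 1 — absence of an equal copy
   number anywhere means it postdates every sampled split.

Genes measured by RNA-seq but placed in no orthogroup are treated as
species-specific singletons (rung 1, copy number 1): they are measured
genes and belong in denominators.

### Copy-number matching: design choices

Two points in the duplication rule were genuinely open and we fixed them
as follows.

*Per-species matching.* "Same copy number" is evaluated per single
species (at least one species in the rung with exactly `n` members), not
aggregated at clade level. Clade-level aggregation (e.g. averaging copy
number across a rung) would blur single-species losses into fractional
copy numbers with no clean interpretation.

*Non-monotone profiles.* Copy numbers can fluctuate across rungs (e.g.
3 copies in the congener rung, 1 in the next, 3 again further out —
convergent amplification or differential loss). The default `"oldest"`
rule dates to the deepest match anywhere, reading a distant exact match
as evidence of an old duplication. The alternative
`"youngest_contiguous"` rule follows the unbroken run of exact matches
from rung 2 outward and stops at the first break, reading the distant
match as convergence. Both are implemented (`dup_rule=`); neither is
asserted as uniquely correct, and on clean (simulated, lossless) data
they agree.

### Conservation classes

Independently of the ladder, genes partition into **single-core**,
**multi-core** and **non-core** against a set of query species. The
default reads "no ortholog in any query" as absence from *at least one*
query species (`noncore_mode = "any"`); the stricter reading (absent from
*all* queries) is available as `"all"`. The partition is exhaustive and
mutually exclusive by construction, and growing the query set can only
move genes toward non-core — both properties are tested.

## Enrichment statistics

DE flags use strict cutoffs `|log2FC| > 1` and `FDR < 0.01`; strictness
matters only at exact boundary values but is part of the contract (a gene
at exactly log2FC = 1 is not DE). The normalized enrichment ratio per
group is `(DE_g/n_g) / (DE_tot/n_tot)`; it satisfies the identity
`sum_g (n_g/n_tot) * ratio_g = 1` exactly, which the tests assert on
arbitrary inputs — any implementation drift breaks it. Each group is
tested against *all* remaining measured genes (not against a reference
group) with a two-sided Fisher exact test; the two-sided p sums all
hypergeometric outcomes at the observed margins no more probable than the
observed table. Unadjusted p-values are reported alongside
Benjamini–Hochberg adjustment across the groups of a condition, since
five groups per condition is a small but real multiplicity. The WGD
group, when present, participates in the normalization denominator: it is
a measured group of genes like any other.

When a condition has no DE genes at all the ratio is undefined; rows are
still emitted with `NA` ratios rather than dropped, so downstream joins
see every group.

Replicate noise is filtered by relative standard deviation: a gene is kept
only if sd/mean ≤ 1 (sample sd, n−1 denominator) in every condition under
comparison, and genes with zero mean in any condition are removed (their
RSD is undefined; a gene silent in one condition contributes no usable
contrast). TPM is the standard length-then-depth normalization; columns
sum to 10^6 by construction and the tests check it to 1e−6 relative.

Bootstrap confidence intervals of the median use the percentile method.
The default is 10,000 resamples; the seed is an explicit argument and the
helper restores the caller's RNG state, so seeded calls are reproducible
without side effects. Constant and single-value inputs collapse to a
degenerate interval rather than erroring.

## Adaptation rates

For each protein the closest homolog from a congeneric species is the hit
with maximal bitscore (ties: higher percent identity, then lexicographic
subject id — a deterministic, row-order-independent choice). Queries whose
best hit scores below 50 bits are excluded: a marginal hit is not evidence
of genuine homology and would inject noise exactly where identities are
lowest. The rate is `(100 − %identity) / divergence_Myr`, so doubling the
divergence time halves every rate exactly — a scale consistency the tests
assert. Identity is taken from the hit table as produced upstream (the
local-alignment convention of BLAST tabular output); for small FASTA
inputs the package can compute identity itself by global
Needleman–Wunsch alignment with identity = matches / alignment columns
including internal gaps. The two conventions differ systematically
(global-alignment identity penalizes terminal length differences), which
is why the in-package route is a documented dialect, not a drop-in
replacement. Reciprocal-best-hit filtering is not applied by default —
best-hit-only matches the "closest homolog" notion — but the hit table
interface makes an RBH pre-filter trivial to apply upstream.

## The simulator

The generator emulates the structure the sorting method assumes: each
gene originates at a rung drawn from `origin_probs` and is present as a
single copy in at least one species of every rung from its origin down to
the focal species; with probability `dup_prob` it carries one duplication
at a rung uniform between origin and present, after which species at or
below that rung carry two copies; each non-focal species independently
loses the gene with probability `loss_rate`. One duplication at most per
gene keeps the ground truth unambiguous for the copy-number dating rule;
multi-duplication histories are an extension, not the default. Losses
never hit the focal species, so every simulated gene stays measurable.
DE status is planted per condition with probability
`de_prob_by_group[age rung]`, and the emitted log2FC/FDR values are
constructed to sit strictly on the correct side of the default cutoffs,
so flagging recovers the planted truth exactly — the simulator validates
sorting and enrichment, not DE model fitting, which is why FDR values are
drawn directly rather than derived from simulated p-value pipelines.

Defaults were chosen once as the study conditions and are not tuned:
a 5-rung ladder with two species per non-focal rung and divergence times
(0, 20, 100, 325, 400) Myr — congener, family, old subphylum ancestor,
filamentous outgroup; origin probabilities youngest→oldest
(0.02, 0.03, 0.15, 0.25, 0.55), making ~5% of genes young, the fraction
typical of a well-annotated yeast genome; `dup_prob` 0.3; DE
probabilities (0.30, 0.20, 0.10, 0.05, 0.02) youngest→oldest, a planted
15-fold youngest/oldest contrast; `lfc_magnitude` 2 (validated ≥ 1, or
the construction contract above would be unsatisfiable).

What the simulator does **not** emulate: sequence evolution (presence is
drawn, not inferred from alignments), orthology-inference errors other
than whole-gene loss (no mis-clustering, no fission/fusion of
orthogroups), copy numbers above 2, gene conversion between ohnologs,
and realistic count distributions (no negative-binomial RNA-seq noise).
Passing validation therefore shows the *sorting and statistics* are
correct given a faithful orthogroup table; it does not certify robustness
to orthology-tool artifacts on real proteomes.

## Validation and problem sizes

The test suite validates each operation against an independent oracle:
the Fisher test against exhaustive hypergeometric enumeration from
binomial coefficients; age assignments against a per-gene brute-force
rung scan; overlap counts against direct membership enumeration; and a
hand-enumerated 12-gene genome whose conservation partition (4/4/4) and
per-gene age labels are written out explicitly in the test helper.

Statistical properties run at sizes chosen to make the checks sharp while
keeping the suite quick: null calibration uses 1000 simulated genomes of
2000 genes with age-independent DE probability 0.1 (mean ratio within
1 ± 0.05; Fisher rejections at p < 0.05 within [0.03, 0.07] — Fisher is
conservative for small discrete groups, which is visible as a rate below
the nominal 0.05 but inside the band); age recovery uses 1000 genes with
30% duplicates across loss rates {0, 0.05, 0.1, 0.2} (perfect at zero
loss, non-increasing with loss); the planted gradient uses 5000 genes
(youngest/oldest contrast within 3 binomial standard errors of the
planted 15); bootstrap coverage uses 1000 replicates of n = 50 standard
normal samples with 1000 inner resamples (coverage 95% ± 2% — the
percentile interval for a median of n = 50 is slightly lumpy because the
bootstrap median distribution is discrete, another reason the band is
two-sided).

## Numerical and degenerate-input choices

- Fisher ties are resolved with the conventional 1e−7 relative tolerance
  when comparing table probabilities; p-values are clamped to ≤ 1.
- Degenerate Fisher margins (an empty row or column) give p = 1.
- `median_ci` on constant input returns a zero-width interval.
- TPM errors on an all-zero sample rather than returning NaN columns.
- Empty simulated genomes (`n_genes = 0`) produce structurally valid
  empty tables.
- All validation failures raise a typed condition (`agestrat_error`),
  which the CLI maps to exit status 2; programming errors propagate.

## Known limitations

Age resolution is bounded by the ladder: everything deeper than the
oldest rung collapses into group I, and a sparse rung (one sequenced
species) makes that rung's dating fragile to a single loss. Duplication
dating assumes copy-number conservation signals timing; lineage-specific
re-amplification violates that and is exactly where the two `dup_rule`
variants disagree. The non-core class conflates "too young to have
orthologs" with "lost in queries" and "orthology tool failed"; the
conservation partition is honest about presence, not about mechanism.
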