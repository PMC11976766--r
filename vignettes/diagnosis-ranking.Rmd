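---
title: "Ranking candidate genetic diagnoses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate genetic diagnoses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dxrank` ranks candidate molecular diagnoses in a rare-disease proband by a
predicted probability of being disease-causing. This vignette records the
model, its assumptions, the tunable parameters, and the design decisions
taken where more than one defensible choice existed. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The candidate unit

A *candidate diagnosis* is either a single variant or an ordered
compound-heterozygous pair of variants in one gene. Pairs are proposed when
the pedigree phases two proband-het variants to different parental origins
(or at least one is de novo); pairs proven in cis are excluded, and without
parental genotypes every het pair in a gene is kept but flagged unphased.
Candidates are only formed for variants with a gene assignment: an
intergenic call cannot constitute a Mendelian diagnosis in this framework.

Before enumeration, two cohort-level filters run: variants with population
allele frequency strictly above 0.05 are removed (records with no AF
annotation are kept — absence of evidence is not evidence of commonness),
and variants carried by strictly more than 13 alternate alleles across the
whole cohort are removed as platform artifacts. Both thresholds are
configurable (`dxrank_config()`); both use strict inequalities, so AF =
0.05 and count = 13 survive. The two filters commute.

## The four features

**Pathogenicity.** A logistic regression over triggered ACMG/AMP criteria.
The criteria engine is a deliberately minimal, fully documented 14-rule
table driven by a generic annotation bundle (consequence, population AF,
in-silico damage score, de novo status, prior classifications, gene-level
flags). Thresholds, with defaults: PM2 rarity `rare_af = 1e-3`; BS1
`bs1_af = 0.01`; BA1 `ba1_af = 0.05`; PP3/BP4 damage-score cuts 0.7 / 0.3;
BS2 at ≥ 5 healthy homozygotes. The threshold structure makes the
mutually exclusive pairs (PM2 vs BS1/BA1, PP3 vs BP4, PP5 vs BP6)
structurally impossible to co-trigger. A missing annotation makes the
dependent criterion abstain with a warning — never crash, never guess. The
default regression weights are fitted once per session on an internal
synthetic criteria corpus with a fixed seed (4,000 profiles whose labels
are drawn from a logistic in classical evidence points: very strong 8,
strong 4, moderate 2, supporting 1, benign negative); externally fitted
weights can be loaded from a `key=value` file. Scoring is restricted to
disease-associated genes (those with disease links in the annotation set);
other variants get score 0, class VUS, and a flag. The five-tier class
uses the standard combining rules, with any pathogenic+benign conflict
resolved to VUS.

**Phenotypic similarity.** Information content is computed from the
disease corpus: `IC(t) = −ln(count(t)/N)` with `count(t)` the number of
diseases annotated to `t` or any descendant. Unannotated terms get
add-one smoothing so similarities stay finite on sparse corpora. Term
similarity is Resnik (max IC over common ancestors); set similarity is the
best-match average over both directions, with the condition's per-term
frequency (parsed from `k/n`, percentage, or frequency-modifier terms
mapped to their range midpoints) weighting the condition-side
contributions in both numerator and denominator. The gene-based and
condition-based scores are each normalized by the annotation set's
self-similarity (clamped at 1, since a patient set can in principle exceed
the profile's own average self-similarity when the profile mixes high- and
low-IC terms) and combined by `max` (configurable to `mean`). `max` was
chosen because gene-level and disease-level annotations have different
coverage: whichever description the patient matches should carry the
signal. Genes with no phenotype annotation score 0 with an explicit flag —
a statement of ignorance, not of dissimilarity.

**Inheritance match.** Segregation is inferred from the family genotypes
under complete penetrance: de novo (affected het/hemizygous, genotyped
healthy parents reference), AR homozygous (healthy parents both carriers),
isodisomy (exactly one carrier parent, the other genotyped reference),
X-linked hemizygous, Y-linked (affected father transmits), dominant
inherited (affected parent carries). Any genotyped healthy relative
carrying a disease-sufficient genotype vetoes the pattern. With missing
parental genotypes the inference degrades gracefully — proband-only calls
are compatibility statements (het → dominant-compatible, hom/hemizygous →
recessive-compatible) flagged `inferred`, and one-parent families keep
partial inference with the same flag. The boolean feature is then a set
intersection between the pattern's compatible modes (de novo maps to AD on
autosomes and to XLD/XLR on chrX, where de novo hemizygous disease is
common) and the gene's expected modes; `unknown` never matches, so the
feature is conservative by construction.

**Quality.** FILTER == "PASS" (case-insensitive) → 1, anything else → 0.
A missing FILTER (".") counts as non-PASS by default ("anything other than
PASS"), configurable via `missing_filter_is_pass` since some pipelines
emit "." for calls that were never subjected to filtering.

## Classifiers, ranking, uncertainty

Four model kinds sit behind one interface: `linear` (weighted logistic),
`ensemble` (bagged logistic, default 20 members), `bayes`
(Gaussian/Bernoulli naive Bayes), `mlp` (one hidden layer of 4 tanh units
fitted by BFGS). Class imbalance — one causative among thousands of
candidates — is handled by inverse-frequency observation weights rather
than resampling, preserving determinism and ranking calibration. All
stochastic steps take explicit seeds. Hyperparameters are package
defaults, documented but not claimed to reproduce any external system.

Ranking is by predicted probability, with ties broken by pathogenicity,
then phenotypic similarity, then genomic coordinate — deterministic across
runs. Leave-one-proband-out cross-validation holds out every candidate of
one proband, trains on the rest, and records the best rank among the
held-out proband's causative-labeled candidates; CDF@K is the fraction of
probands with causative rank ≤ K.

Predictive uncertainty treats the ensemble members as a sample of
plausible classifiers: total uncertainty is the binary entropy of the mean
probability, aleatoric the mean member entropy, epistemic their difference
(non-negative by Jensen's inequality, clamped at 0 against floating-point
dust). Non-ensemble models have one member and hence zero epistemic
uncertainty by construction.

## Pointwise reliability

For each feature, the training *borders* are the instances of each class
closest to the opposite class (all ties included) plus the global
min/max. A test candidate "would become a border" on a feature when it
falls outside the training range or strictly inside the between-class
margin. "Strictly between the two classes' border values" is ambiguous
when a class occupies several disjoint regions along a feature; we
resolved it with label-free insertion semantics: the feature counts iff
the candidate is strictly closer than the current class-to-class minimum
distance to *both* classes, i.e. inserting it under either hypothetical
label would strictly displace that feature's borders. This agrees with the
stored-border interval rule in the unimodal case, makes boolean features
(both values present in both classes) never count, and is exactly what the
append-and-recompute oracle in the test suite verifies. The reliability
score is `rel(x) = 1 − m_x/m` with `m = 4` features here, so scores live
on the grid {0, 0.25, 0.5, 0.75, 1} and "fraction with rel = 1" is an
exact count, not a tolerance comparison.

## The synthetic world

The generator exists so that every claim in the test suite is computable
offline. It emulates: a single-rooted phenotype DAG (~200 terms) with
genes annotated to coherent subtrees and one disease per gene with
frequency-weighted terms and an inheritance mode; proband-centric family
VCFs whose background genotypes are Hardy–Weinberg draws at the site's
allele frequency, conditioned on the proband carrying the allele and on
Mendelian consistency (no background de novo events); a rare-skewed AF
spectrum with a 15% common fraction (removed by the AF filter) and 10%
missing AF; 98% PASS calls; cohort artifact variants injected at total
allele counts 13 and 14 to straddle the artifact threshold; and one
planted causative per family whose genotypes exactly satisfy the requested
inheritance pattern, whose annotations trigger loss-of-function criteria,
and whose disease terms seed the proband's HPO list (4 disease-derived + 2
noise terms by default). The default 7,700 variants per proband matches a
realistic post-calling candidate load; tests and the acceptance script
scale this down (500/proband, 20 trios) to fit a single-CPU time budget
and say so explicitly.

It does **not** emulate: linkage disequilibrium or realistic site spectra,
sequencing errors or genotype-quality gradients (quality is a coin flip on
FILTER), incomplete penetrance, imprinting, mosaicism, or background de
novo mutations. A green end-to-end test therefore establishes that the
machinery is correct and that the features separate when the signal is
present — not that real-cohort performance numbers transfer.

`feature_separation` interpolates the planted signal: at 1 the causative
is a rare, PASS, loss-of-function, phenotype-matched variant; at 0 its
annotations, AF, FILTER and the proband's phenotype terms are drawn from
the background distributions. One channel cannot be nulled: the causative
genotypes must still satisfy the requested inheritance pattern (that is
the generator's contract), so at separation 0 the inheritance-match bit
remains informative and the causative's rank is uniform only within the
inheritance-compatible candidate subset. The corresponding test asserts
non-pinning (median LOPO rank well above 1) rather than exact uniformity.

## Numerical and degenerate-input choices

* IC uses natural log; entropies use log2 (bits). Both stated in the docs.
* `bma_similarity` raises a distinct error on empty sets rather than
  returning 0: an empty phenotype list is an input defect, not a finding.
* Obsolete ontology terms are remapped via `replaced_by` wherever term
  lists enter; unknown terms error in `resnik` but are dropped with a
  warning when reading annotation corpora.
* Multi-allelic VCF sites are decomposed per alt allele; shared ref/alt
  prefixes/suffixes are trimmed (full left-alignment would need the
  reference genome, which this package deliberately does not require).
* Haploid genotype calls are hemizygous only for male samples on X/Y (sex
  from the pedigree); elsewhere they are treated as homozygous calls.
* The proband defaults to the first affected pedigree member and must be
  overridden explicitly in families where an affected parent is listed
  first (the simulator does this for Y-linked families).
* `glm.fit` rather than `glm` backs the logistic fits: several hundred
  fits run inside a LOPO ensemble and the model-frame machinery dominates
  runtime otherwise.

## Known limitations

* The criteria engine covers 14 of the 28 ACMG/AMP criteria; criteria
  requiring curated resources (PS3 functional data, PP1 cosegregation
  counts, BP1/BP7, etc.) are out of scope, as are splice- and
  structural-variant-specific evidence types.
* Compound-het aggregation (pathogenicity = min, quality = AND,
  similarity = gene score) is a design choice; the weakest-link rule for
  pathogenicity reflects that both variants must be functional hits.
* Mitochondrial inheritance is not modeled.
* Phenotype scores are only as good as the annotation corpus; genes
  without annotations rank last regardless of variant evidence, matching
  the framework's stated dependence on known gene–phenotype associations.
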