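---
title: "Methods: weighted burden and carrier tests for rare-variant panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted burden and carrier tests for rare-variant panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the tunable parameters,
the numerical choices, and the scope of the synthetic-data generator —
the things a reviewer or maintainer needs to interpret a green test
suite correctly.

## The analysis model

The package targets candidate-gene rare-variant association in a large,
heavily imbalanced case/control cohort. Three granularities of test share
one covariate model (sex plus 20 genotype-derived principal components,
consumed as inputs):

1. **Gene-wise weighted burden.** Qualifying variants are those with
   minor allele frequency (MAF) ≤ `maf_cap` (default 0.01) in *both*
   cases and controls. Each receives
   `overall_weight = functional_weight × maf_weight`, where the
   functional weight encodes predicted severity (stop gained 100,
   missense 5, full table below) and the MAF weight decreases linearly
   from `maf_weight_max = 10` at MAF 0 to `maf_weight_min = 1` at the
   cap. Per-subject scores sum dosage × weight over the gene; a logistic
   regression of case status on score plus covariates is tested with a
   1-df likelihood-ratio test (LRT) of the score coefficient and
   summarised as a signed log p-value, `SLP = sign(β̂)·(−log10 p)`.
2. **Category tests.** Within each gene, per-subject allele counts of
   each variant category (LOF, protein altering, splice site, intronic,
   synonymous) enter one *joint* logistic model with the covariates.
   Each category's odds ratio is `exp(β̂)` with a Wald p-value; when the
   category's alleles occur fewer than 50 times in the sample, Fisher's
   exact test on the carrier-by-status 2×2 table replaces the Wald test
   (the asymptotics are unreliable there). SLPs are signed by whether
   the mean count is higher in cases.
3. **Carrier tests.** Curated variants seen in ≥ 20 subjects are tested
   individually on the 2×2 carrier table with Pearson's chi-squared
   (1 df, **no continuity correction** — required to match published
   statistics computed the same way); rarer listed variants are pooled
   per gene, counting a subject once however many pooled variants they
   carry. The frameshift aggregation unions carriers of all frameshift
   variants in a gene.

The case definition is a disjunction of three indicators: self-report,
any ICD-10 code matching a configured prefix (dots stripped on both
sides, so `G431` and `G43.1` are equivalent), and use of a configured
condition-specific medication. It is monotone — adding an indicator can
never turn a case into a control — and the seven-way indicator breakdown
partitions the cases.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `maf_cap` | 0.01 | rare-variant inclusion threshold, per stratum |
| `maf_weight_max/min` | 10 / 1 | MAF-weight endpoints at MAF 0 / cap |
| `functional_weight` | 100 (LOF terms), 5 (missense, inframe), 3 (splice region), 1 (synonymous, intronic, UTR) | severity weights, overridable by JSON |
| `wald_min_occurrences` | 50 | category test: Wald above, Fisher below |
| `min_carriers` | 20 | carrier tests: individual above, pooled below |

**MAF-weight functional form.** Only the two endpoints (10 near zero, 1
at 0.01) are pinned by the method the package reimplements; the curve in
between is not recoverable. We use linear interpolation — the simplest
monotone form through both anchors — and document it as an assumption.
Any strictly decreasing alternative through the same endpoints would be
admissible; the weight-rescaling invariance of the SLP limits the
consequences of this choice to the relative weighting of very rare
versus merely rare variants.

**Functional-weight table.** Only the stop-gained (100) and missense (5)
anchors are fixed; the remaining defaults follow the severity ordering
(frameshift and canonical splice variants treated as LOF at 100, inframe
indels with missense at 5, splice region 3, synonymous/intronic/UTR 1)
and are fully overridable via `read_weight_config()`.

**Test statistic.** The burden p-value is from the LRT, which is more
stable than the Wald test when the score distribution is dominated by a
few high-weight carriers; the Wald p is reported alongside as a
diagnostic. The SLP sign comes from the fitted coefficient (i.e. "higher
in cases" *after* covariate adjustment); raw score means per stratum are
also reported.

## Numerical choices and degenerate inputs

- Fitting is IRLS (`glm.fit`) with a 50-iteration cap. Standard errors
  come from the inverse Fisher information at the optimum. The LRT
  statistic is clamped at 0 against tiny negative deviance differences.
- A constant score, or a score aliased with the covariates, yields
  SLP 0 with `flag = "degenerate"` rather than an error or a dropped
  gene. Non-convergence and suspected complete separation
  (|β̂| > 15) are flagged, never silently removed.
- Zero-variance covariate columns (e.g. sex in a single-sex subset) are
  dropped before fitting; collinear category-count columns are pruned
  with a warning and reported as NA rows.
- The carrier chi-squared returns `chi2 = 0, p = 1` for tables with a
  zero margin instead of dividing by zero.
- Missing genotypes contribute 0 to burden scores and count as
  non-carriers, and subjects are retained — dropping subjects
  per-variant would change n from test to test. This is a declared
  convention, not an inference about how any published analysis handled
  missingness. MAF denominators, by contrast, use non-missing subjects
  only.
- Dosage is counted against the ALT allele at read time (deterministic
  I/O) and folded to the minor allele in the weighting step; in the rare
  case that ALT is the major allele, dosages are flipped to `2 − g`.
- VCF reading parses the GT column directly with a tabular reader whose
  memory scales with the file. A generic VCF reader was measured to
  attempt a 16 GB allocation on a 20,000-sample, 50-variant file;
  agreement with `VariantAnnotation::readVcf()` is asserted on small
  fixtures in the test suite instead.

## The synthetic cohort generator

`sim_config()` defaults state the emulated world: 200,627 subjects,
target prevalence 0.036, 55.1% female with a female case odds ratio of
3.0 (which reproduces a ~78% / ~54% female share in cases / controls), a
10-gene panel of ~30 rare variants each with a consequence mix dominated
by missense, and MAF drawn as `0.01 · Beta(0.5, 4)` — mass concentrated
near zero, as for rare exome variants. Case liability is
`logit(P) = c + β·score + log(OR_female)·sex (+ optional PC1 loading and
per-category count effects)`, with the intercept `c` solved by `uniroot`
so the expected prevalence hits the target (an unattainable target is an
error, not a clamp). Phenotype indicators are then assigned to cases
with probabilities 0.70 / 0.25 / 0.40 (self / ICD / medication,
independent, falling back to self-report if none fires) and decoy
non-qualifying codes are scattered over the whole cohort, so
`classify_cohort()` recovers the simulated status *exactly* — which the
tests assert with zero tolerance. The indicator mixture is a declared
default: the true source breakdown in any particular biobank is a
real-data quantity the generator does not claim to match.

All draws come from one seeded stream in a fixed order (sex → PCs → per
gene: consequences, MAFs, dosages → intercept → status → indicators →
decoys → missingness mask), so the same seed reproduces byte-identical
fixtures.

**What the generator does not emulate** — and therefore what a green
test does *not* establish: linkage disequilibrium between variants
(variants are independent; the burden statistics are additive, so LD
affects power, not validity), departures from Hardy-Weinberg dosages,
relatedness/kinship structure, genotype-calling artefacts or structured
missingness (only a uniform missing rate is available), and PCs that
actually derive from the genotypes (they are i.i.d. normal covariates
here, so the PC adjustment is exercised mechanically, not
population-genetically).

## What the acceptance suite establishes

Desk-scale checks reproduce published carrier contingency statistics,
the SLP↔p correspondence and printed carrier frequencies exactly. The
gene-wise burden analysis on the real cohort is *not* reproducible
without the restricted genotypes, so the suite substitutes properties:
type-I error of the burden SLP within [0.03, 0.07] at nominal 0.05 over
500 null simulations (n = 20,000), recovery of a known burden log-odds
effect (β = 0.1, n = 50,000, 200 replicates) within 3 Monte-Carlo
standard errors, agreement of the LRT with a brute-force
maximum-likelihood oracle to 1e-6 on a 30-subject fixture, and
invariance of the SLP under rescaling of all weights. Monte-Carlo loops
use the simulator's true case status directly; the equivalence of
classified and true status is itself a zero-discordance criterion.

## Known limitations

- Panel-oriented: nothing prevents large panels, but there is no
  exome-wide mode, no mixed-model/kinship adjustment, and no
  multiple-testing correction beyond annotating the Bonferroni threshold
  for the panel size.
- Multiallelic VCF records are rejected (split them upstream), and
  phased/polyploid genotypes are out of scope.
- PolyPhen/SIFT scores are carried through annotations but do not
  modulate the default weights.
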