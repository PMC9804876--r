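# burdenscan

Rare-variant association testing for candidate-gene panels in heavily
imbalanced case/control cohorts — the setting of biobank-scale exome
studies where a few percent of participants carry a composite clinical
phenotype and the variants of interest are individually rare
(MAF ≤ 0.01).

It is written for statistical geneticists who want the classic weighted
burden / collapsing workflow as a reproducible pipeline, and it ships a
synthetic cohort generator so every stage can be exercised and tested
without access-controlled genotype data.

## The statistics

**Case definition.** A subject is a case if they self-reported the
condition, carry an ICD-10 code matching a configured prefix (e.g.
`G43.*` for migraine, dots ignored), or report a condition-specific
medication; everyone else is a control.

**Weighted burden test (per gene).** Each qualifying variant *v* — minor
allele frequency ≤ 0.01 in both cases and controls — gets a weight

```
w_v = f(consequence_v) × m(MAF_v),   m(p) = 1 + 9·(0.01 − p)/0.01
```

where `f` is a consequence-severity table (stop gained 100, missense 5,
… fully configurable) and `m` falls linearly from 10 for variants with
MAF near 0 to 1 at MAF = 0.01. The subject score is
`s_i = Σ_v g_iv · w_v` with `g_iv` the minor-allele dosage. Case status
is regressed on `[s, sex, PC1…PC20]` by maximum-likelihood logistic
regression; the score coefficient is tested with a 1-df likelihood-ratio
test and reported as a **signed log p-value**,
`SLP = sign(β̂) · (−log10 p)` — positive when the burden is higher in
cases.

**Category tests (per gene).** Per-subject allele counts of each variant
category (LOF, protein altering, splice site, intronic, synonymous)
enter one joint logistic model with the same covariates; the odds ratio
per category is reported with a Wald p-value, or Fisher's exact test on
the carrier 2×2 table when the category's alleles occur fewer than 50
times.

**Carrier tests (per variant).** Curated variants observed in ≥ 20
subjects are tested individually on the carrier-by-status 2×2 table with
Pearson's chi-squared (1 df, no continuity correction); rarer listed
variants are pooled per gene (a subject carrying several pooled variants
counts once). A frameshift aggregation unions the carriers of all
frameshift variants in a gene.

## Worked example

Simulate a 20,000-subject cohort with a modest burden effect
(`burden_beta = 0.002` log-odds per score unit) over two genes, write it
to VCF + TSV, and run the full pipeline back over the files:

```r
library(burdenscan)

cfg <- sim_config(n_subjects = 20000,
                  genes = list(sim_gene("ATP1A2", 25), sim_gene("KCNK18", 25)),
                  burden_beta = 0.002, seed = 42)
sim   <- simulate_cohort(cfg)
paths <- render_fixture(sim, "demo")

cohort <- classify_cohort(read_cohort(paths[["cohort"]]))
phenotype_summary(cohort)
#> 748 cases (79.1% female), 19252 controls (54.1% female)

vset <- annotate_variants(read_genotypes(paths[["vcf"]], cohort$subject_id),
                          read_annotations(paths[["anno"]]))
wv  <- weight_variants(vset, cohort$is_case)
gene_burden_test(wv, cohort)
#>    gene      slp       beta n_qualifying_variants flag
#>  ATP1A2 9.282611 0.00243199                    25   ok
#>  KCNK18 3.403961 0.00168785                    25   ok

frameshift_aggregate("KCNK18", vset, cohort)
#> 11/748 case carriers vs 76/19252 control carriers,
#> chi2 = 19.24, p = 1.15e-05
```

Reading the output: the simulated cohort reproduces the intended
structure (3.7% prevalence, strong female excess among cases). Both
genes carry a true burden effect, and the SLPs (9.28 and 3.40, i.e.
p ≈ 10⁻⁹·³ and 10⁻³·⁴) detect it, with β̂ close to the simulated 0.002
per score unit. The frameshift aggregation picks up the carrier excess
among cases that the liability model induced through the
high-weight loss-of-function variants.

The same run is available as a single command:

```sh
Rscript inst/cli/burdenscan.R simulate --n 20000 --seed 42 --out demo/
Rscript inst/cli/burdenscan.R all --vcf demo/genotypes.vcf \
    --anno demo/annotations.tsv --cohort demo/cohort.tsv \
    --frameshift-genes KCNK18 --out demo/results/
```

which writes `gene_results.tsv`, `category_results.tsv`,
`variant_results.tsv` and a `manifest.json` with input hashes for
reproducibility.

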