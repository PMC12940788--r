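# chsprofiler

Integrated immune–molecular classification of chondrosarcoma cohorts,
for bioinformaticians and biostatisticians analysing combined
immunohistochemistry (IHC) and targeted-panel sequencing data from bone
sarcoma studies.

Chondrosarcoma (ChS) is a chemo- and radio-resistant bone malignancy
whose prognosis spans from indolent grade 1 tumours to dedifferentiated
disease with around 10% three-year survival. The package implements a
reusable version of a classification workflow that ties the tumour
immune microenvironment to the mutational landscape and to outcome:

- **Immunophenotyping** — 20 IHC markers × {central, peripheral} tumour
  regions (cells/mm²) are log-transformed, standardized, and clustered
  with Ward's D2 on Euclidean distances. The cluster number is chosen by
  a majority vote of nine internal validity indices, and stability is
  assessed by bootstrap resampling scored with the adjusted Rand index
  (ARI). Clusters are named by total immune density: IMP1 "cold" <
  IMP3 "intermediate" < IMP2 "hot". PD-L1 is scored 0/1/2 at the 1% and
  30% positivity cut points; a tertiary lymphoid structure call requires
  CD3, CD20 and LAMP3 jointly.
- **Variant consensus cascade** — per-sample call sets from three caller
  dialects (TS, GATK/Mutect2, Ion Reporter) pass staged filters:
  GATK-branch thresholds (SNP/MNP: DP ≥ 15, AF ≥ 0.015, TLOD ≥ 14;
  INDEL: DP ≥ 70, 0.35 ≤ AF ≤ 0.55), the caller merge
  (TS ∩ GATK) ∪ IR, pool-of-normals subtraction, post-filtration
  (AF ≥ 0.05, DP ≥ 50), and annotation-based pathogenicity rules
  (impact/ClinVar, SIFT + PolyPhen-2 or AlphaMissense, 1000 Genomes
  AF ≤ 0.05, ≥ 5 supporting reads with ≥ 2 per strand). Every removal is
  ledgered with its stage. TMB = final variant count / 1.7 Mb.
- **Cohort statistics** — gene-by-subtype Fisher exact tests with BH
  correction, Kruskal–Wallis TMB contrasts, pairwise mutation
  co-occurrence, pathway deregulation against a curated gene→pathway map.
- **Survival** — Kaplan–Meier and log-rank; univariate Cox screening
  with FDR; LASSO-penalized Cox (`glmnet`, 10-fold event-stratified CV,
  one-standard-error λ) with an unpenalized refit supplying hazard
  ratios and Wald CIs for the selected covariates.
- **Immunograms** — six per-patient axes in [0, 1]: suppressive-cell
  density, IDH1 status, TMB status, PD-L1 presence, remaining-marker
  density, and immune-checkpoint density.
- **Synthetic cohort generator** — produces all study inputs (density
  tables, caller VCFs, a pool-of-normals VCF, CNV and clinical tables)
  with known ground truth: three latent immunophenotypes,
  grade-dependent mutation frequencies (IDH1/2 combined 41%),
  stage-tagged contaminants, and exponential proportional-hazards
  survival calibrated to 3-year subtype anchors (91.3/77.3/40.7/11.4%)
  with configured true hazard ratios (IMP2: 3.3, IDH1: 3.8).

## Worked example

```r
library(chsprofiler)

cohort <- generate_cohort(generator_config(seed = 1))

fit <- fit_immunophenotypes(cohort$densities)
fit$k
#> [1] 3
table(fit$imp)
#> IMP1 IMP2 IMP3
#>   40   30   29
adjusted_rand_index(fit$imp, cohort$truth$patients$imp)
#> [1] 1

profiles <- lapply(cohort$clinical$patient_id, function(id) {
  cc <- cohort$callers[[id]]
  run_cascade(cc$ts, cc$gatk, cc$ir, cohort$pool)
})
names(profiles) <- cohort$clinical$patient_id
tmb <- vapply(profiles, `[[`, numeric(1), "tmb")
median(tmb)
#> [1] 2.352941
```

The clustering recovered the three latent phenotypes exactly (ARI 1),
and the cascade's median TMB of 2.35 mut/Mb is the configured cohort
median of 4 retained variants over the 1.7 Mb panel. The per-stage
removal ledger for any sample is in `profiles[[id]]$ledger`, and the
multivariate survival model is one call away
(`lasso_cox(...)` on `build_covariates(...)`; see the methods vignette
for the full sequence).

A complete run writing all per-stage outputs:

```r
run_pipeline(generator_config(seed = 1), out_dir = "run1")
```

or from a shell: `Rscript inst/scripts/run_pipeline.R --out run1 --seed 1`.

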