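# tridosha

One-vs-rest genotype association and constitutional-type classification
for three-group cohorts.

## The problem

Ayurvedic practice classifies healthy individuals into three dominant
constitutional types (*Prakriti*): Vata, Pitta and Kapha. A genome-wide
study of such a cohort has no case/control split — instead each group is
tested against the pooled other two (V vs PK, P vs VK, K vs VP). This
package reimplements that full analysis as tested, reusable R code for
anyone analysing a multi-group genotype cohort with a one-vs-rest design:

- **I/O** — PLINK text PED/MAP and BED gene intervals; a `geno_table`
  container (samples × markers minor-allele dosage matrix with marker and
  sample metadata). Minor-allele polarity is fixed once on the whole
  cohort, so per-group frequencies may exceed 0.5, exactly as published
  association tables print them.
- **QC** — per-sample call-rate filtering (≥ 0.95), exact Hardy–Weinberg
  testing in the controls of each comparison (removal at p < 0.001),
  windowed greedy LD pruning (r² > 0.75), Mendelian-inconsistency rates
  for trios, and a masking/concordance harness for pluggable imputation
  engines.
- **Association** — the allelic χ² test on 2×2 allele tables,
  χ² = n(ad−bc)²/(r₁r₂c₁c₂), with odds ratio (undefined at any zero
  cell), plus adaptive permutation: labels are reshuffled until either the
  budget (10⁶) is exhausted or a binomial confidence bound shows the
  marker is not significant, in which case it is dropped early. The
  *true-positive filter* keeps markers that both sit below the p ceiling
  and survive the full permutation budget.
- **Stratification** — smartpca-style PCA on normalized genotypes
  (posterior allele-frequency scaling), iterative σ ≥ 6 outlier removal on
  eigenvectors 1–10, projection of external samples, per-eigenvector
  pairwise group ANOVA, EIGENSTRAT adjustment ((N−k−1)ρ² on residualized
  genotype and phenotype), and the genomic-control λ diagnostic
  (median χ² / 0.4549).
- **Classifier** — the genotype-frequency weight model: the weight of
  genotype *g* at a panel marker in group *p* is its within-group
  frequency f_p(g); a sample's group score is the panel sum, standardized
  over the training cohort (Z_V, Z_P, Z_K). With Δ_pq = Z_p − Z_q and
  R_p the product of group p's two Δ values, a sample is assigned to p
  iff both Δ are positive and R_p ≥ 3.
- **Annotation** — genic/non-genic status by inclusive 10 kb
  flanking-window overlap with gene intervals (bedtools `window`
  semantics).
- **Simulation** — a Balding–Nichols generator (two ancestries,
  configurable Fst, planted group-specific frequency shifts, missingness)
  that makes every stage testable end to end without any external data.

Everything takes and returns tibbles (or a `geno_table`), chains with the
pipe, and has `tidy()`/`glance()`/`autoplot()` methods where a model
object is involved.

## Worked example

```r
library(tridosha)

sim <- simulate_cohort(sim_config(n_markers = 400, frac_associated = 0.05,
                                  effect_delta = 0.35, fst = 0.02, seed = 7))
sim$table
#> <geno_table> 205 samples x 400 markers
#>   groups: K=65, P=60, V=80
#>   missing: 3.41%

res <- run_prakriti_pipeline(
  sim$table, pipeline_config(p_ceiling = 1e-4, max_perms = 2000, seed = 7))
res$log[, c("stage", "message")]
#> 1 qc       199 of 205 samples pass call rate >= 0.95
#> 2 assoc    1198 association records; 31 permuted
#> 3 panel    31 records pass; 20 distinct panel markers
#> 4 pca      panel LD pruning kept 20 of 20 markers
#> 5 classify 81 of 199 samples assigned (40.7%)
```

Six samples fall below the 95% call-rate threshold; of the 400 simulated
markers (each tested in three comparisons, hence 1198 records after
per-comparison HWE filtering), 31 records pass the permutation stage and
collapse to a 20-marker panel — the generator planted effects at 20
markers. Classification then assigns 41% of samples, almost all to their
true group:

```r
res$classification$summary
#>   call           n fraction
#> 1 K             30    0.151
#> 2 P             26    0.131
#> 3 UNASSIGNED   118    0.593
#> 4 V             25    0.126
```

The package also ships a transcription of the published association
summary of the study it reimplements (131 rows over the three
comparisons). Reconstructing every row's allele counts from the printed
group frequencies and group sizes 80/60/65 and recomputing the statistics
reproduces the table at printed precision, and the true-positive filter
returns the published panel of 52 distinct SNPs:

```r
check_reported_associations()$summary
#>   n_rows n_reconcilable max_dev_chi max_dev_or max_rel_dev_p or_na_agrees panel_size
#> 1    131            131     0.00496   0.000811       0.00308 TRUE                52
```

## Vignette

`vignettes/tridosha-methods.Rmd` documents the statistical model, every
tunable threshold with its default and provenance, what the simulator
does and does not emulate, and the package's numerical conventions.
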