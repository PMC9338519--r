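# bincfdr

Covariate-aware multiple testing for GWAS: **bincfdr** folds a binary
auxiliary annotation (is the SNP in a regulatory-factor binding site? is it
non-synonymous? does it sit in an active chromatin state?) into GWAS
p-values using the binary conditional false discovery rate (cFDR), and
returns *v-values* that are uniformly distributed under the null hypothesis.
Because v-values behave exactly like p-values, they drop straight into
standard FDR-controlling procedures such as Benjamini–Hochberg, and the
transformation can be applied iteratively to leverage several annotations in
turn. The package is aimed at statistical geneticists who have per-SNP
summary statistics and one or more binary functional annotations, and want
more power at a controlled FDR.

## The method

For SNPs `i = 1..m` with p-values `p_i ∈ (0,1]` and binary covariates
`q_i ∈ {0,1}`, the cFDR is `Pr(H0 | P ≤ p, Q ≤ q)`. With a binary
covariate the support of `(P, Q)` is two lines, and rejection regions take
the form

    L(p0, p1) = (P ≤ p0, Q = 0) ∪ (P ≤ p1, Q = 1).

The two thresholds are chosen to equalise the estimated null/overall
density ratio across strata,

    f(p1, 1)/f0(p1, 1) = f(p0, 0)/f0(p0, 0),

where each side is estimated by `p · Pr(Q = q | H0) / (ecdf_q(p) · Pr(Q = q))`
with continuity-corrected stratum ECDFs, `Pr(P ≤ p | H0) ≈ p`, and
`Pr(Q = 1 | H0)` estimated from the null-enriched region `p > 1/2`. The
coordinate of the observed stratum is fixed at `p_i` and the other
coordinate is solved through a monotone envelope of the step-function
ratio. The v-value is the null mass of the region,

    v_i = p0 · (1 − q0) + p1 · q0,      q0 = Pr(Q = 1 | H0),

which is uniform on (0,1] under the null. Estimation uses
leave-one-group-out fold removal (group = chromosome or LD block), so
rejection rules are never fitted on the SNPs they are applied to.

The package also ships a block-LD GWAS simulator (AR(1) LD blocks,
case-control Z-scores with a fine-mapping effect-size prior) and an
evaluation harness measuring sensitivity, specificity and empirical false
discovery proportions across iterations, including the documented failure
mode of repeatedly leveraging the same functional mark.

## Worked example

Simulate a GWAS (24 LD blocks × 400 SNPs, 5000 cases/controls), build three
annotation layers enriched in functional regions, and leverage them
iteratively:

```r
library(bincfdr)
study <- simulate_study(sim_config(), seed = 42)
labels <- truth_labels(study)
q <- simulate_covariate("B", study$functional, n_cols = 3, seed = 43)
fit <- iterate_cfdr(study$p, q, study$block)
fit
#> Iterative binary cFDR: 3 iterations, 9600 SNPs
#> SNPs with FDR < 0.05 per iteration:
#> iter0 iter1 iter2 iter3
#>   886   951  1022  1142
```

Each iteration promotes additional SNPs past the FDR threshold (886 before
leveraging, 1142 after three informative annotations). Power and error,
judged against the simulation's r²-based truth labels:

```r
rbind(before = sensitivity_specificity(bh_adjust(study$p), labels),
      after  = sensitivity_specificity(fit$fdr[, 3], labels))
#>        sensitivity specificity
#> before       0.378           1
#> after        0.415           1
empirical_fdr(fit$fdr[, 3], labels)
#> [1] 0.0429
```

Sensitivity rises from 0.378 to 0.415 while the specificity proxy stays at
1 and the realised false discovery proportion (0.043) stays under the
nominal 0.05. For real data, `read_sumstats()` reads a tab-separated table
with columns `snp`, `p`, `q`, `group`, and `annotate_with_bed()` builds the
binary covariate from a BED track. A command-line wrapper is installed at
`exec/bincfdr` with verbs `run`, `simulate`, `evaluate` and `annotate`.

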