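# cnvherit

Partitioning additive genetic variance between SNP- and CNV-derived genomic
relationship matrices, with joint SNP + CNV association mapping by the
relaxed LASSO.

## What this package is for

Copy number variants (CNVs) are called from the same SNP arrays used for
genomic evaluation of cattle and other livestock, but most association and
prediction work uses only the SNP genotypes. `cnvherit` is for quantitative
geneticists who want to ask, using deregressed estimated breeding values
(dEBVs) of sires as pseudo-phenotypes:

1. How much additive genetic variance does a CNV-derived genomic
   relationship matrix (GRM) capture, alone and next to a SNP-derived GRM?
2. Can a joint SNP + CNV penalized regression locate trait-associated
   variants that the SNP set alone would miss, and how much variance do
   those CNVs explain?

The package covers the full path from raw inputs to QTLs:

* **Quality control** — animal and SNP call-rate filters (strict `< 95%`
  rules), autosome/position completeness, removal of SNPs with
  opposing-homozygote Mendelian conflicts in more than 2% of parent-progeny
  pairs, and exclusion of animals with an effective record contribution
  below 1.
* **CNV consensus** — PennCNV-style call files from two callers are merged:
  calls for the same animal and direction are one event when both endpoints
  agree within 1 SNP; calls spanning fewer than 3 SNPs are dropped; loci
  carried by fewer than 3 animals within breed are dropped; rare double
  copy classes are collapsed for association coding.
* **GRMs** — VanRaden method 1,
  `G = (M − P)(M − P)' / (2 Σ p_i (1 − p_i))`, for SNP codes, two CNV
  recoding procedures (double classes at −1 with mixed loci split in two,
  or deletion/normal/duplication at −1/0/+1) and the combined marker set;
  principal components of any GRM for stratification covariates.
* **Variance components** — weighted average-information REML for the
  mixed model `dEBV = μ + Za + Wb + e` with `a ~ N(0, G_SNP σ²_g)`,
  `b ~ N(0, G_CNV σ²_c)`, `e ~ N(0, D⁻¹σ²_e)`, where the diagonal of `D`
  holds the weights `w = (1 − h²)/((c + (1 − r²)/r²) h²)`; a boundary
  log-likelihood ratio test (0.5 χ²₀ + 0.5 χ²₁) of the CNV component; and
  a two-step procedure that refits the step-one residual (intercept added
  back) against the CNV GRM.
* **Association** — an L1-penalized regression of the weighted dEBVs on
  all SNPs and CNV carrier indicators jointly, with unpenalized GRM
  principal components; cross-validated penalty choice; unpenalized joint
  refit of the selected set (relaxed LASSO) giving allele substitution
  effects `a_i`; per-CNV variance explained `2 p_i (1 − p_i) a_i² / σ²_g`;
  and a single-variant mixed-model t-test under the SNP-GRM covariance.
* **QTLs** — ±50 kb windows around associated variants, merged within
  variant type when within 50 kb (CNV distances from span edges),
  cross-referenced across types, and annotated with overlapping genes from
  a user-supplied BED/GFF3 file.
* **Synthetic data** — `simulate_population()` generates multi-breed sire
  populations with a *known* SNP/CNV variance split, Mendelian-consistent
  parent-progeny pairs, reliability-driven dEBV noise, dual-caller CNV
  files with 1-SNP endpoint jitter, and injectable Mendelian errors, so
  every stage can be tested against ground truth.

## Worked example

```r
library(cnvherit)

cfg <- sim_config(n_animals = 400, n_snps = 600, n_chrom = 5, n_cnv_loci = 20,
                  cnv_carrier_freq_range = c(0.02, 0.08), seed = 42)
sim <- simulate_population(cfg)
sim$panel
#> <snp_panel> 400 animals x 600 SNPs (1 breed)
#>   chromosomes: 1-5; missing: 1.00%

## dual-caller CNV consensus
caller_a <- tempfile(); caller_b <- tempfile()
emit_caller_files(sim, caller_a, caller_b)
calls <- consensus_merge(read_rawcnv(caller_a, sim$panel$map, "callerA"),
                         read_rawcnv(caller_b, sim$panel$map, "callerB"))
loci <- build_loci(calls, sim$panel$animals, sim$panel$map) |>
  collapse_copy_classes()
loci
#> <cnv_locus_set> 20 loci x 400 animals
#>   type            n
#> 1 deletion        9
#> 2 duplication     8
#> 3 mixed           3

## relationship matrices
panel <- impute_missing(sim$panel)
g_snp <- compute_grm(code_snps(panel))
g_cnv <- compute_grm(code_cnvs_proc1(loci))
g_snp
#> <grm> 400 animals, 600 markers (coding 'snp'), denominator 216.995
#>   mean diagonal 0.9855

## weighted two-GRM REML
traits <- add_weights(sim$traits, h2 = 0.3)
fit <- fit_reml(traits$debv, list(snp = g_snp, cnv = g_cnv),
                weights = traits$weight)
tidy(fit)
#>   component estimate proportion boundary
#> 1 snp        0.242       0.786  FALSE
#> 2 cnv        0.00738     0.0239 FALSE
#> 3 residual   0.126       0.190  FALSE

red <- fit_reml(traits$debv, list(snp = g_snp), weights = traits$weight)
likelihood_ratio_test(fit, red)
#>   statistic    df p_value
#> 1      7.00     1 0.00408
```

The simulation put `var_snp = 0.25` and `var_cnv = 0.01` into the breeding
values; the joint fit recovers 0.242 and 0.0074, and the boundary-mixture
test detects the (small but real) CNV variance at p = 0.004.

```r
## joint SNP + CNV relaxed LASSO with PC covariates
design <- build_design(panel, loci, grm_pca(g_snp, 5), grm_pca(g_cnv, 5),
                       traits, k_pcs = 5)
lasso <- fit_lasso(design, cv_folds = 10, seed = 7)
assoc <- relaxed_refit(design, lasso) |>
  variance_explained(sigma_g2 = cfg$var_total_genetic)
dplyr::filter(tibble::as_tibble(assoc), type == "cnv")
#>   variant_id    type  chrom debiased_beta     se       p_value var_fraction
#> 1 locus0003     cnv       1        0.406  0.0670 0.00000000503      0.0294
#> 2 locus0007     cnv       2        0.126  0.0689 0.0692             0.00282
#> 3 locus0011     cnv       3       -0.159  0.0551 0.00423            0.00725
#> 4 locus0015_del cnv       4        0.0721 0.0552 0.193              0.00149
#> 5 locus0020     cnv       5        0.0606 0.0519 0.245              0.00105

qtls <- build_qtls(dplyr::select(tibble::as_tibble(assoc), variant_id, type,
                                 chrom, pos_bp, start_bp, end_bp))
```

`var_fraction` is `2 p_i (1 − p_i) a_i² / σ²_g` with `p_i` the carrier
proportion; summing it over a trait's associated CNVs gives the cumulative
CNV share of the genetic variance. `annotate_qtls(qtls, "genes.bed")`
reports the genes overlapping each ±50 kb window by at least 1 bp.

## The raw CNV call dialect

`read_rawcnv()` parses PennCNV-style text, one call per line:

```
chr1:10500-20400 numsnp=5 length=9,901 state2,cn=1 A17 startsnp=s01 endsnp=s05
```

Required fields: the `chr<chrom>:<start>-<end>` span, `numsnp=`, `cn=`
(copy number 0/1/3/4; `cn=2` records are rejected as non-calls) and the
sample identifier; `length=`, `state` and the start/end SNP names are
optional. Spans are resolved against the SNP map; calls whose span contains
no mapped SNP are rejected and counted.

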