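---
title: "Partitioning additive genetic variance between SNP and CNV relationship matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning additive genetic variance between SNP and CNV relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Copy number variants (CNVs) — deletions and duplications of genomic
segments — are called from the same SNP arrays used for genomic evaluation
of livestock, yet most association and prediction work uses only the SNP
genotypes. If CNVs sit in strong linkage disequilibrium with flanking SNPs
they add nothing; if not, SNP-only analyses can miss causal variation.
`cnvherit` implements a pipeline to ask, on deregressed estimated breeding
values (dEBVs) of sires: how much additive genetic variance does a
CNV-derived genomic relationship matrix (GRM) capture next to a SNP-derived
GRM, and can a joint SNP + CNV penalized regression locate associated
variants that SNPs alone would miss?

The pipeline has two arms.

**Variance components.** The mixed model is

    dEBV = mu + Z a + W b + e

with `a ~ N(0, G_SNP sigma_g^2)`, `b ~ N(0, G_CNV sigma_c^2)` and
`e ~ N(0, D^{-1} sigma_e^2)`, where `D` is the diagonal matrix of dEBV
weights. Single-random-effect versions of the same model estimate the
variance captured by each GRM alone and by a combined SNP+CNV GRM. A
log-likelihood ratio test compares the two-GRM model against the SNP-only
model, and a two-step procedure refits the step-one residual (with the
intercept added back) against the CNV GRM.

**Association.** A LASSO regression of the weighted dEBVs on all SNPs and
CNVs jointly, with the top principal components of both GRMs as unpenalized
covariates, selects variants; the selected set is refit by ordinary
weighted least squares (the relaxed LASSO) to debias the allele
substitution effects `a_i`. Each associated CNV's contribution is
summarised as `2 p_i (1 - p_i) a_i^2 / sigma_g^2` and re-analysed singly by
a mixed-model t-test under the SNP-GRM covariance. Associated variants are
expanded to ±50 kb QTL windows, merged within variant type when within
50 kb of each other, and intersected with a user-supplied gene annotation.

## Model assumptions

* dEBVs are treated as pseudo-phenotypes whose residual precision per
  animal is proportional to its weight
  `w = (1 - h^2) / ((c + (1 - r^2)/r^2) h^2)`, with `r^2` the EBV
  reliability, `h^2` the trait heritability and `c` the fraction of genetic
  variance not captured by markers (default 0.9). The weight grows with
  reliability and shrinks with heritability.
* GRMs follow VanRaden's first method,
  `G = (M - P)(M - P)' / (2 * sum(p_i (1 - p_i)))`, with marker codes
  -1/0/+1 and `P` the allele-frequency centring matrix. Allele frequencies
  are estimated from the sample itself, anchored to the +1-coded allele;
  monomorphic markers are excluded from numerator and denominator.
* CNV copy classes are double-deletion, single-deletion, normal,
  single-duplication, double-duplication. Procedure 1 codes double classes
  -1, single classes 0 and normal +1, splitting mixed loci (segregating as
  both deletion and duplication) into one deletion and one duplication
  locus. Procedure 2 keeps one locus per CNV with deletion -1, normal 0,
  duplication +1. Procedure 1 behaves like a genotype coding and its
  implied allele frequency is well defined; for procedure 2 the frequency
  of the +1-coded allele of a three-state locus is ambiguous — the mean
  coded value is used and flagged in the output, and procedure-2 GRMs of
  rare-carrier panels are noticeably flatter as a result.

## The synthetic population

Real genotype and dEBV data of the motivating application are proprietary,
so every stage is exercised against `simulate_population()`, which draws:

* per-breed, per-SNP allele frequencies uniform on `maf_range`, genotypes
  binomial; non-founder animals receive one gamete by Mendelian
  transmission from a recorded founder parent so the pedigree pair list is
  conflict-free until `inject_mendelian_errors()` tampers with it;
* CNV loci spanning 5–12 SNPs, placed at least 4 SNPs apart so that a
  1-SNP endpoint jitter can never bridge two loci or push a true call below
  the 3-SNP consensus filter, with carriers drawn at low frequency and
  classes skewed 9:1 toward single deletions/duplications;
* true breeding values as a SNP polygenic part plus a CNV part, each
  rescaled so its sample variance equals `var_snp` and `var_cnv` exactly;
* dEBVs as `tbv + e_i`, `e_i ~ N(0, sigma_g^2 (1 - r_i^2)/r_i^2)` with
  per-animal reliabilities uniform on `reliability_range` — at `r^2 = 1`
  the dEBV equals the true breeding value by construction;
* two caller files in a PennCNV-style text dialect in which every true call
  appears in both files, each endpoint independently shifted by one SNP
  with probability `caller_endpoint_jitter_prob`, plus 2-SNP decoy calls.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
independent draws; an optional block mode is out of scope for the default
checks), intensity-level CNV signal and caller error modes other than
1-SNP endpoint jitter, selection and multi-generation pedigree structure,
and X/Y chromosomes. Passing tests therefore demonstrate the correctness
of the statistical machinery under the stated sampling model, not the
behaviour of CNV callers on real intensity data.

## Numerical choices

* **REML.** Average-information updates with an
  expectation-maximisation fallback whenever an AI proposal would decrease
  the restricted log-likelihood or leave the non-negative orthant, so the
  log-likelihood trace is non-decreasing by construction. Components pinned
  at the variance floor (`1e-8 * var(y)`) with a downhill gradient are
  frozen out of the AI system for that iteration, which removes boundary
  thrashing. Convergence is a relative log-likelihood change below `1e-8`,
  capped at 200 iterations; non-convergence is flagged, never silent.
  Rank-deficient or indefinite GRMs (probed by Cholesky) receive a `1e-6`
  diagonal ridge, recorded on the fit.
* **Variance proportions.** The residual enters the denominator either as
  `sigma_e^2 / mean(w)` (the harmonic mean of the per-animal residual
  variances `sigma_e^2 / w_i`) or unchanged; both conventions are reported
  because the choice is not determined by the model.
* **LRT.** The tested variance lies on the boundary of its space under the
  null, so the reference distribution defaults to the equal mixture
  `0.5 chi^2_0 + 0.5 chi^2_1`; plain `chi^2_1` is available by flag.
* **LASSO.** The penalty is the L1 norm of the marker coefficients: only
  the L1 geometry produces exact zeros and hence a selection rule, which
  the relaxed refit requires. Coordinate descent runs over a warm-started
  decreasing grid of 100 `lambda` values from `lambda_max` (the smallest
  penalty zeroing all markers, computed after projecting out the
  unpenalized columns) down to `1e-3 lambda_max` (`1e-2` when markers
  outnumber animals), with active-set cycling and a convergence tolerance
  of `1e-10` on scaled coefficient changes. `lambda` is chosen by seeded
  10-fold cross-validation at the error minimum (a one-standard-error rule
  is available). The exploratory and fold paths run at a looser tolerance
  with a per-`lambda` sweep budget and a deviance-based early stop —
  prediction errors are insensitive to the last digits of the
  coefficients, and the ill-conditioned saturated tail of the path is
  never selected — while the path up to the selected `lambda` is re-solved
  at the tight tolerance. Karush-Kuhn-Tucker conditions are checkable on
  every returned solution via `check_kkt()`.
* **Weights in the design.** The response and all columns are premultiplied
  by `sqrt(w)`, which preserves the weighted least-squares objective;
  marker columns are then standardized to mean 0, variance 1, and effects
  are back-transformed to the original marker scale after the refit.
* **Single-variant re-analysis.** The null-model variance components are
  reused across markers (the P3D shortcut); an exact per-marker REML route
  is available by flag and is the route that reduces exactly to ordinary
  least squares when the GRM is the identity.
* **Consensus spans.** Calls from the two callers match when both
  endpoints agree within 1 SNP index; a matched pair is emitted once with
  the union extent of the two spans. The union keeps the merge symmetric in
  the two callers and preserves each caller's endpoint evidence — keeping
  one caller's span can discard the very endpoint that links an animal's
  call to the other carriers' spans under the 1-SNP locus tolerance and
  thereby split a true locus. Loci are the transitive closure of the
  pairwise span match; the locus span is the modal member span (ties to
  the smallest), and per-animal class conflicts resolve by the call with
  more SNPs, then deletion before duplication.
* **QTL windows.** "Within 50 kb" is inclusive (`gap <= 50000`); CNV
  distances are measured from span edges; windows floor at 1 bp; SNP- and
  CNV-QTLs never merge across type but overlapping windows are
  cross-referenced as one shared region.

## Design choices where the design was genuinely open

* The Mendelian conflict rule is strictly opposing homozygotes over
  parent-progeny duos; pairs with a missing genotype leave that SNP's
  denominator. Heterozygous parents can never conflict.
* Filter order is fixed: animal call rate, SNP call rate (computed on
  retained animals), positional completeness, Mendelian, then the
  effective-record-contribution cut on the trait table; the order is
  recorded in the QC report.
* Missing genotypes are imputed by the within-breed per-SNP mean before
  coding. At the sub-5% missingness the call-rate filters guarantee, the
  perturbation of `G` is negligible relative to haplotype-based
  imputation, and the method is deterministic.
* In the association design, collapsed CNV loci are coded as 0/1 carrier
  indicators and a mixed locus contributes one deletion and one
  duplication column, consistent with GRM procedure 1; `p_i` in the
  variance-explained formula is the carrier proportion.
* The intercept and principal-component columns are never penalized: they
  are adjustments, not candidate variants.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen once as follows: GRM
equivalence on 20 x 50 coded matrices against a naive double-loop oracle;
REML recovery at n = 500 with 1,000 SNPs and 20 replicates, cross-checked
against a closed-form eigen-rotation profile likelihood; the null-CNV
property at n = 950 (the study's per-breed sample size) with a 60-locus
rare-carrier CNV panel — a Fisher-information analysis at the null showed
the sampling spread of the CNV variance estimate grows with panel size
(sd roughly proportional to sqrt(L), because a GRM built from many rare,
independent loci approaches an identity-like structure aliased with the
residual), so the panel size was set where the theoretical spread gives
the bound `sigma_c_hat <= 0.02` about 98% power; LRT size with 200
replicates at n = 200; LASSO power with one causal CNV explaining 5% of a
unit genetic variance at n = 1000 over 20 replicates; and QTL merging
against a naive pairwise oracle on 1,000 random variant sets.
`scripts/acceptance.R` runs the full pipeline on one simulated breed of
950 sires, 800 SNPs and 25 CNV loci with `var_snp = 0.25`,
`var_cnv = 0.01`, `var_total = 0.30`.

## Known limitations

* The CNV variance component of a rare-carrier panel is weakly identified
  against the residual when the panel is large relative to the carrier
  structure; boundary estimates are reported with flags rather than
  standard errors.
* The simulator's independent-SNP model understates the selection
  uncertainty a LASSO faces under real linkage disequilibrium; selection
  frequencies on real data will be less stable than the packaged power
  checks suggest.
* Procedure-2 CNV GRMs inherit the three-state allele-frequency ambiguity
  described above; conclusions should rest on procedure 1 (as the primary
  coding) with procedure 2 as a sensitivity check.
* Gene annotation must be supplied on the same assembly as the variant
  positions; no liftover is performed.
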