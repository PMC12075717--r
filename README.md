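# mrpath

Two-sample Mendelian randomization (MR) and two-step mediation analysis on
GWAS summary statistics, for studies that ask not only *whether* an
exposure (for example, the abundance of a gut-microbial taxon) causally
affects a disease outcome (for example, colorectal-cancer risk) but also
*how much of that effect runs through a measurable mediator* (for example,
an immune-cell phenotype). Everything operates on per-variant summary
statistics — no individual-level genotypes — and the package ships a
synthetic-data generator with known causal structure, so every stage of
the pipeline can be exercised and calibrated without downloading any
external GWAS.

Intended users: statistical geneticists and epidemiologists running
exposure panels (microbiome taxa, immune phenotypes, metabolites, ...)
against disease outcomes with the standard two-sample MR toolkit.

## The model

A genetic variant *j* qualifies as an instrumental variable for exposure
*X* when it is associated with *X*, independent of confounders of the
*X*→*Y* relation, and affects the outcome *Y* only through *X*. Under
these assumptions, with per-variant associations (β̂_Xj, se_Xj) and
(β̂_Yj, se_Yj) estimated in non-overlapping samples, each variant gives a
Wald ratio β̂_Yj / β̂_Xj, and the inverse-variance weighted (IVW)
estimator pools them:

    β̂_IVW = Σ w_j (β̂_Yj/β̂_Xj) / Σ w_j ,   w_j = β̂_Xj² / se_Yj² ,

equivalently weighted regression of β̂_Yj on β̂_Xj through the origin.
Violations are probed with MR-Egger regression (a free intercept absorbs
directional pleiotropy), the weighted median (consistent when ≥ 50% of
weight is valid), weighted/simple modes, Cochran's Q, the Egger intercept
test, MR-PRESSO (simulation-based residual-sum-of-squares global, outlier
and distortion tests), leave-one-out influence analysis, and
reverse-direction MR.

For a mediation chain *X* → *M* → *Y*, two-step MR estimates β₁ (effect
of *X* on *M*, instruments from *X*'s GWAS), β₂ (effect of *M* on *Y*,
instruments from *M*'s GWAS) and the total effect β_all (*X* on *Y*), then
decomposes by product of coefficients:

    β₁₂ = β₁ × β₂ ,   β_dir = β_all − β₁₂ ,
    mediated proportion = β₁₂ / β_all × 100% ,

with a first-order delta-method standard error for β₁₂. When β₁₂ and
β_all disagree in sign the proportion is negative and the result is
flagged as suppression rather than silently reported by magnitude.

Instrument selection follows the conventional five-filter pipeline:
association p < 1e-5, greedy LD clumping (r² < 0.001 within 10,000 kb),
exclusion of variants associated with the outcome (p < 1e-5), optional
explicit exclusion lists, minor allele frequency ≥ 0.01, and per-variant
F = (β/se)² > 10. Harmonization aligns outcome effects to the exposure's
effect allele and drops palindromic (A/T, C/G) variants by default.

## Worked example

```r
library(mrpath)

# A synthetic study with a known mediation chain: beta1 = -0.19,
# beta2 = -0.05, direct effect 0.147, so the true total effect is
# 0.1565 (~ log 1.17) and the true mediated proportion ~ 6.1%.
study <- simulate_study(sim_preset("paper-mediation"), seed = 42)

sel <- select_instruments(study$exposure, study$outcome, study$ld)
hd  <- harmonize(sel$instruments, study$outcome)
mr_all(hd, seed = 1)

med <- run_mediation(study$exposure, study$mediator, study$outcome,
                     ld = study$ld, seed = 1)
med
```

which prints (26 of the 60 simulated variants survive selection):

```
MR estimates exposure -> outcome
IVW (26 SNPs): beta = 0.1330 (SE 0.0238), OR = 1.142 [1.090, 1.197], p = 2.28e-08
MR-Egger (26 SNPs): beta = 0.1636 (SE 0.0585), OR = 1.178 [1.044, 1.329], p = 0.01
Weighted median (26 SNPs): beta = 0.1512 (SE 0.0324), OR = 1.163 [1.092, 1.239], p = 3.04e-06
Weighted mode (26 SNPs): beta = 0.1624 (SE 0.0459), OR = 1.176 [1.075, 1.287], p = 0.000402
Simple mode (26 SNPs): beta = 0.1647 (SE 0.0556), OR = 1.179 [1.057, 1.315], p = 0.00306

Mediation: exposure -> mediator -> outcome
  beta1 (exposure->mediator)  =  -0.1191 (SE 0.0563)
  beta2 (mediator->outcome)   =  -0.0528 (SE 0.0067)
  beta_all (total effect)     =   0.1330 (SE 0.0238)
  beta12 (mediated effect)    =   0.0063 (SE 0.0031, 95% CI 0.0003..0.0123)
  beta_dir (direct effect)    =   0.1267
  mediated proportion         =     4.73%
```

The five estimators agree on a risk-increasing total effect of about
OR 1.14–1.18 (the generative truth is 1.17), and the decomposition
attributes a single-digit percentage of it to the mediator (4.7% in this
one study; the true value is 6.1%, and the replicate mean recovers it —
see below). `sensitivity_report(hd, seed = 1)` on the same pair reports
Cochran's Q p = 0.96, Egger intercept p = 0.57 and a PRESSO global p =
0.96, i.e. no evidence of heterogeneity or pleiotropy, as expected for a
correctly specified simulated study.

A thin command-line wrapper covers the same workflow
(`inst/cli/mrpipe.R`; subcommands `simulate`, `mr`, `mediate`, `screen`,
`report`).

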