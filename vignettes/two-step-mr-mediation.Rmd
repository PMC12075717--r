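---
title: "Two-sample MR and two-step mediation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR and two-step mediation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

This vignette is the package's account of its statistical machinery: the
models, the conventions chosen where the literature offers several, the
synthetic-data generator used for calibration, and the limits of what the
validation shows.

## The causal model and its assumptions

Two-sample MR treats genetic variants as instrumental variables for a
heritable exposure. A variant qualifies when (1) it is robustly associated
with the exposure, (2) it shares no confounder with the exposure–outcome
relation, and (3) it affects the outcome only through the exposure (the
exclusion restriction). Because the variant–exposure and variant–outcome
associations come from *different* GWAS samples, only per-variant summary
statistics are required, and weak-instrument bias acts toward the null
rather than toward the confounded association.

All effects are on the per-allele scale of the underlying GWAS; for binary
outcomes they are log-odds, and estimates are also reported as odds ratios
with 95% intervals.

For mediation, the package implements the two-step (product of
coefficients) decomposition. Three MR analyses are run: exposure→mediator
(β₁, instruments from the exposure GWAS), mediator→outcome (β₂,
instruments from the mediator GWAS), and exposure→outcome (β_all). Then

* mediated effect β₁₂ = β₁β₂, with first-order delta SE
  √(β₁²·se₂² + β₂²·se₁²);
* direct effect β_dir = β_all − β₁₂ (by subtraction, so the
  decomposition is conservative of the total by construction);
* mediated proportion = 100·β₁₂/β_all, *signed*.

The proportion only has its usual reading when the indirect and total
effects share a sign. When they do not (suppression), the package reports
the negative percentage together with `direction_consistent = FALSE`
instead of quietly taking magnitudes; a positive-looking "proportion
mediated" from opposite-signed paths is an artefact, not a mediation
estimate. The direct effect is obtained by subtraction only — a
multivariable-MR direct effect is a different estimand and out of scope.

## Instrument selection

Filters run in a fixed order — association p-value, LD clumping,
outcome-association exclusion, explicit exclusion list, MAF, F-statistic —
because clumping is order-sensitive: only variants that survive the
p-filter should compete as index variants. Every input variant receives
exactly one disposition (`kept`, `failed-p`, `clumped-out-by:<id>`,
`outcome-associated`, `excluded-list`, `failed-maf`, `failed-f`) so the
usual "n variants after each step" audit trail is reconstructible from the
report alone.

Defaults, with rationale:

| parameter | default | meaning |
|---|---|---|
| `p_instrument` | 1e-5 | sub-genome-wide threshold typical for low-powered exposure panels (microbiome, immune phenotypes); strict `<` |
| `clump_r2` / `clump_kb` | 0.001 / 10,000 kb | near-independence of instruments; inclusive ± window on the same chromosome |
| `p_outcome_exclude` | 1e-5 | drop instruments directly associated with the outcome (exclusion-restriction guard) |
| `min_maf` | 0.01 | excludes rare variants whose effect estimates are unstable |
| `min_f` | 10 | conventional weak-instrument bound, F = (β/se)² per variant, strict `>` |

Clumping is the standard greedy index-variant scan: repeatedly keep the
remaining variant with the smallest p (ties broken lexicographically by
identifier, for determinism) and remove everything in LD with it
(r² ≥ threshold) within the window. The kept set is verified in tests
against a brute-force enumeration of maximal independent sets. The LD
matrix is an *input* (square or long TSV); computing LD from a reference
panel is out of scope, and analyses should record which panel produced it.

Harmonization matches variants by identifier only (summary-statistic
builds disagree on positions often enough that chrom/pos clashes are
logged as warnings, not errors), aligns the outcome record to the
exposure's effect allele (swapped orientation ⇒ β negated, eaf
complemented), and drops all palindromic variants by default — the
blanket-removal convention. An optional `palindromic = "infer"` mode keeps
a palindromic variant when both studies put its allele frequency clearly
on the same side of 0.5 (bound 0.42), flipping when the frequencies sit on
opposite sides; frequencies near 0.5 stay ambiguous and are dropped.
Allele sets that disagree even after considering a swap (including
strand-complement pairs) are conservatively dropped as mismatches.

## Estimator conventions

Several of the named estimators admit variants; the package's choices:

* **IVW** defaults to the multiplicative random-effects model: the
  fixed-effect SE is inflated by √(Q/(J−1)), floored at 1, so
  heterogeneity widens intervals but can never narrow them. A
  `"fixed"` switch exists. P-values are two-sided normal.
* **MR-Egger** first orients every pair so β_X ≥ 0 (the intercept is
  only meaningful on the exposure-increasing orientation), fits WLS with
  weights 1/se_Y², floors the residual scale at 1, and uses t-inference
  on J−2 degrees of freedom for both slope and intercept.
* **Weighted median**: sorted Wald ratios, normalized inverse-variance
  weights, linear interpolation of the cumulative-weight midpoints at
  1/2. The SE is a parametric bootstrap (default 1000 resamples of both
  β_X and β_Y from their sampling distributions); a seed is required for
  reproducible pipelines.
* **Modes**: argmax of a normal-kernel density over the ratios, bandwidth
  φ·0.9·min(sd, IQR/1.349)·J^(−1/5) (modified Silverman; φ = 1 by
  default). The weighted variant scales kernels by normalized IV weight.
  If all ratios coincide the common ratio is returned directly. The
  argmax is located on a 512-point grid and polished with `optimize()`
  between the neighbouring grid points.
* Per-variant ratio SEs use the first-order delta approximation
  se_Y/|β_X|; the second-order correction is omitted, as is usual when
  instruments have passed an F filter.
* Minimum instrument counts: IVW runs from J = 1 (where it *is* the Wald
  ratio), Egger/median/modes from J = 3, MR-PRESSO from J = 4;
  `mr_all()` reports methods below their minimum as not computed rather
  than failing the battery.

## Sensitivity diagnostics

Cochran's Q uses the ratio form with weights 1/se_ratio², which is
algebraically the WLS residual form (tested to 1e-10). The Egger
intercept test re-exports the intercept of the Egger fit (t on J−2).

MR-PRESSO is implemented from its algorithmic description: for each
variant the expected outcome effect is the leave-one-out IVW prediction;
the observed weighted RSS is compared with parametric replicates that
redraw both exposure and outcome effects. Two Monte-Carlo p-value
conventions coexist deliberately:

* the **global** test uses the add-one estimator
  (1 + #{RSS\* ≥ RSS_obs})/(n_sim + 1), so it is bounded below by
  1/(n_sim+1) and never exactly zero;
* the **per-variant outlier** test uses the plain empirical proportion,
  which can reach zero — the original method's convention. With add-one
  per-variant p-values, Bonferroni correction at J = 30 and n_sim = 500
  would have a floor of 30/501 ≈ 0.06 and could never flag anything at
  the 0.05 level; a detection test must be able to return p = 0.

Outliers are variants whose Bonferroni-adjusted (×J, capped at 1)
empirical p falls below the significance level. Removal runs at most one
round; the distortion test compares the raw-vs-corrected IVW difference
with the distribution of that difference when random pseudo-outlier sets
of the same size are removed (1000 subsets, add-one p).

Leave-one-out recomputes IVW omitting each variant and flags sign or
significance (0.05) flips relative to the full estimate.

## The candidate screen

`evaluate_pair()` is a pure function of precomputed estimates, so saved
results replay to byte-identical decisions. A pair passes when the IVW p
is below 0.05; at least one of MR-Egger and weighted median is also
significant (the corroboration rule, used *instead of* multiplicity
correction across the exposure panel — an FDR switch exists but is off by
default); the three estimates agree in sign and their 95% intervals
pairwise overlap (the package's operationalization of "consistent
direction and magnitude"); Q, intercept and PRESSO raise no alarms (an
outlier finding is tolerated when the once-corrected estimate keeps its
sign and the distortion test is quiet); and reverse MR — the identical
pipeline with roles swapped — finds nothing at 0.05. When the outcome
trait yields no instruments at all, the reverse rule is recorded as not
applicable rather than failed: absence of instruments is absence of
evidence for reverse causation, not evidence against the pair.

## The synthetic-data generator

`simulate_study()` draws summary statistics directly in summary space —
two-sample MR consumes nothing else, and this keeps a full
selection-to-decomposition replicate in the low milliseconds. Per variant:
MAF uniform on [0.1, 0.4]; true exposure effects γ_j ~ N(0, γ_sd²); the
mediator inherits β₁γ_j and adds its own instruments δ_j ~ N(0, δ_sd²)
(zero exposure effect); the outcome receives
(β_direct + β₁β₂)γ_j + β₂δ_j + sign(γ_j)·α_j. Observed effects add noise
with se = 1/√(2·maf·(1−maf)·n), the standardized-trait approximation; for
a binary outcome n is an effective sample size. P-values are Wald,
floored at 1e-300.

Two modelling points deserve emphasis:

* **Mediator-specific instruments.** Without variants that act on the
  mediator directly, step 2 of two-step MR is unidentified: instruments
  inherited from the exposure carry the direct path, and their
  mediator→outcome ratio is (β_direct+β₁β₂)/β₁, not β₂. Real immune- or
  molecular-trait GWAS provide exactly such mediator-specific variants,
  so the mediation presets include 30 of them alongside the 30 exposure
  instruments. Sample sizes (exposure 5×10⁵, mediator 2×10⁴, outcome
  1×10⁵) are chosen so exposure instruments are strong (typical F in the
  hundreds) while their mediator-side associations stay below the
  instrument threshold — cross-contamination of the step-2 instrument
  set is then a sub-0.1% event per variant.
* **Pleiotropy orientation.** α_j is defined on the exposure-increasing
  allele. Had it been added in raw effect-allele space, a directional
  mean would cancel under MR-Egger's orientation step and no intercept
  test could detect it; on the oriented scale, "directional" means what
  the Egger model assumes.

Named presets fix the study conditions used throughout validation:
`null` (no effect), `effect` (direct effect log 1.17 — the size of a
modest taxon–disease association), `balanced-pleiotropy` (α sd 0.005,
mean 0), `directional-strong` (α mean 0.01), `single-outlier` (one
variant displaced by 10 outcome SEs), `paper-mediation`
(β₁ = −0.19, β₂ = −0.05, direct 0.147 ⇒ total ≈ log 1.17, true mediated
proportion ≈ 6.1% — the magnitude of a microbiota→immune-cell→colorectal-
cancer pathway), and `suppression` (β₁₂ and β_all of opposite sign).

What the generator does **not** emulate: realistic LD (blocks with
constant within-block r² only), genome-scale variant counts, sample
overlap between the three GWAS, population stratification, binary-trait
likelihood effects beyond the effective-n SE approximation, and
winner's-curse structure beyond what instrument selection itself induces.
Passing calibration here shows the estimators and decision logic are
implemented correctly under their own assumptions — not that any real
microbiome–immune–cancer triplet satisfies those assumptions.

## Numerical choices and degenerate inputs

* Wald ratios are undefined at β_X = 0; such variants are rejected with
  an explicit error (the F filter removes them upstream in practice).
* Monte-Carlo p-values: add-one convention wherever a test's lower bound
  matters (PRESSO global, distortion); empirical proportion for the
  per-variant outlier test (see above).
* All p-values are floored at 1e-300 so they remain in (0, 1] even for
  z-scores whose tail probability underflows.
* Clumping ties (equal p) break lexicographically by identifier;
  all randomness flows from one root seed split deterministically per
  stage/replicate, so identical configuration + seed reproduces every
  numeric output byte for byte.
* Bandwidth degeneracy: when the ratio IQR is zero but the SD is not,
  the SD is used; when all ratios coincide, the mode is the common ratio.
* Egger requires non-constant exposure effects; a numerically singular
  design raises an explicit error.

## Validation scale

The test suite calibrates at sizes chosen to give tight Monte-Carlo
bounds while keeping a desk-machine run short: IVW type-I error and
coverage on 1000 null replicates (J = 30); Egger intercept rejection on
500 balanced-pleiotropy replicates; PRESSO planted-outlier detection over
100 seeds at n_sim = 500 plus 200 null replicates; mediation-proportion
recovery over 500 replicates (mean within ±2 percentage points of the
true 6.1%). `scripts/acceptance.R` re-runs a slightly smaller version of
the same battery from scratch at any seed.

## Known limitations

* β_dir is a subtraction estimand; no multivariable MR, no multiple
  mediators jointly.
* The corroboration rule controls false positives only heuristically;
  with large exposure panels the optional FDR switch is worth enabling.
* First-order delta SEs (ratio and product) understate uncertainty for
  weak instruments or β_all near zero; the mediated proportion has no
  formal CI here.
* LD handling assumes the supplied r² matrix matches the GWAS ancestry;
  proxy-variant search and liftover between genome builds are out of
  scope.
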