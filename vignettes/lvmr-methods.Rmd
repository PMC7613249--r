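---
title: "Methods: Mendelian randomization of lipids on left-ventricular phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization of lipids on left-ventricular phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmr)
```

## The scientific question and the estimation problem

Whether serum lipids causally alter cardiac structure is hard to answer
observationally: lipid levels are measured years before cardiac imaging,
statin therapy intervenes in between, and shared risk factors confound the
association. Mendelian randomization (MR) treats a weighted genetic risk
score (GRS) as an instrumental variable: because alleles are randomized at
conception, a valid instrument is associated with lifetime exposure but
independent of confounders, and affects the outcome only through the
exposure. `lvmr` implements both arms of a complete MR study of lipids
(LDL and HDL cholesterol, triglycerides) on left-ventricular (LV)
end-diastolic volume, ejection fraction and mass, together with the
observational comparators whose discordance with MR is itself a finding of
interest.

## Preprocessing model

Lipids are handled in mg/dl internally, converting at 38.67 mg/dl per
mmol/l for cholesterol (molar mass 386.65 g/mol) and 88.57 for
triglycerides; `round_presentation()` applies half-up rounding only for
display (39, 34, 15 mg/dl for 1, 0.87, 0.38 mmol/l of cholesterol; 89, 90
for 1 and 1.02 mmol/l of triglycerides). Missing direct LDL is recovered by
the Friedewald relation `LDL = TC − HDL − TG/5`, valid only when
triglycerides do not exceed a ceiling. The ceiling defaults to 155 mg/dl;
sources sometimes quote it with a parenthetical "4 mmol/l" that is not the
same quantity (155 mg/dl ≈ 1.75 mmol/l), so the mg/dl figure governs here
and the ceiling is a configurable argument. A negative Friedewald value is
returned as missing, not clamped to zero: an impossible concentration should
not silently enter a regression. Statin users' measured LDL is multiplied by
1.43 to estimate the untreated level — only LDL is adjusted, never HDL or
triglycerides — and systolic blood pressure gains 15 mm Hg under
antihypertensive treatment. Covariates enter models as natural logs for BMI,
HbA1c and MET-minutes (the MET log uses a +1 offset, configurable, so zero
activity is well-defined), with body surface area from the Du Bois formula
`0.007184 · height^0.725 · weight^0.425`.

## Instruments

`clump_variants()` performs greedy LD clumping: discard associations at or
above the significance threshold (default genome-wide 5×10⁻⁸), then
repeatedly promote the smallest-p remaining variant and delete everything in
LD with it at r² ≥ 0.01. Ties on p break lexicographically by variant id —
an arbitrary but documented rule chosen so the selection is deterministic
and invariant to input row order. The LD matrix is an explicit input;
estimating it from a reference panel is out of scope. Scores are weighted
allele sums; missing dosages are mean-imputed per variant (standard
polygenic-score practice, switchable to complete-case). Instrument strength
is reported as the simple-regression R² of measured exposure on the score
with `F = (n−2)R²/(1−R²)` — the single-regressor form, since the instrument
is one score, not the individual variants — and F ≤ 10 flags a weak
instrument.

## One-sample estimation

`tsls()` is textbook two-stage least squares: exposure on instrument and
covariates, then outcome on fitted exposure and covariates, with standard
errors from residuals taken at the point estimate with the *observed*
exposure. Homoskedastic errors are the default, with an HC0 robust option,
and confidence intervals use normal quantiles throughout (at n ≈ 17,000 the
t/z distinction is immaterial). `tsls_multi()` fits the just-identified
system with k exposures and k scores jointly, so each lipid's effect is
conditioned on the other scores. The Durbin–Wu–Hausman test uses the
augmented-regression form — outcome on exposure, first-stage residual and
covariates, with the squared t of the residual term referred to χ²₁ —
which is numerically stabler than differencing covariance matrices and
asymptotically equivalent. The statin analysis regresses *unadjusted*
measured LDL on the standardized score, statin use and their product; a
negative product term means statin users gain less measured LDL per unit of
genetic risk.

Power uses the closed-form normal approximation for a continuous outcome:
the standardized minimum detectable effect is
`(z_{1−α/2} + z_{power}) / √(n·R²_gx)`, converted to natural units by
`sd_outcome / sd_exposure`; `power_at_effect()` is its exact inverse (the
package tests the round trip to 10⁻⁶ and the Monte-Carlo rejection rate at
the computed minimum).

## Two-sample estimation

`harmonize()` aligns outcome to exposure effect alleles, flipping signs and
complementing frequencies for swapped codings and resolving strand flips by
complementation. Palindromic (A/T, C/G) variants cannot be oriented by
strand, so they are oriented by allele-frequency agreement and *dropped*
when the exposure frequency lies within 0.5 ± 0.08 — a conventional window;
the harmonization details are a design choice here, not something the study
design dictates. Unresolvable allele pairs are excluded per-variant with a
warning rather than failing the analysis.

The estimators all consume per-variant pairs (γ_j, Γ_j) with SEs:

- **IVW**: weighted regression of Γ on γ through the origin with weights
  1/σ²_Γ — algebraically the inverse-variance-weighted mean of Wald ratios.
  The default reports multiplicative random-effects SEs (inflation
  `max(1, √(Q/(J−1)))`); whether fixed or multiplicative is reported is a
  toggle since either convention appears in practice. `penalized` downweights
  outlying ratios by `min(1, 20·q_j)` with q_j the upper χ²₁ tail of the
  variant's heterogeneity contribution; `robust` swaps least squares for a
  Tukey-bisquare M-estimator (tuning constant 4.685, IRLS to 10⁻⁸, scale by
  MAD). The constants follow the robust-penalized IVW literature and are
  exposed as arguments.
- **MR-Egger**: variants oriented to γ > 0 (required for identifiability of
  the intercept), weighted regression *with* intercept; the intercept
  estimates directional pleiotropy and is flagged at p < 0.10.
- **Weighted median**: inverse-variance weighted quantile of the ordered
  ratios interpolated at cumulative weight ½; consistent when ≥ 50% of
  weight is valid. SEs by parametric bootstrap resampling both summary sets
  from their normal sampling distributions (default 1,000 draws, seeded).
- **Weighted mode**: argmax of a weighted normal-kernel density of the
  ratios on a 512-point grid spanning the ratios ± 3 bandwidths; bandwidth
  is the modified Silverman rule `0.9·min(sd, mad)·J^{−1/5}` times a
  multiplier φ (default 1). Consistent under plurality validity.
- **Multivariable MR**: weighted multiple regression of Γ on the k exposure
  effect columns without intercept; k = 1 reduces exactly to fixed IVW.
- **MR-PRESSO**: the global test compares the observed weighted residual
  sum of squares around leave-one-out IVW fits to a parametric null in
  which γ*_j ~ N(γ_j, σ_γj) and Γ*_j ~ N(γ_j·β_{(−j)}, σ_Γj); the
  exact resampling scheme is not fixed by the study design, so this
  parametric form is adopted and documented. Outliers are flagged by
  per-variant empirical p-values (computed without a continuity term so the
  Bonferroni cut α/J stays attainable at moderate simulation counts), and
  the distortion test compares the raw-versus-corrected shift in β against
  the shift expected when the flagged slots are refilled by resampling from
  the non-outliers.
- **MR-Steiger**: variance explained in exposure versus outcome,
  `Σ_j 2·eaf_j(1−eaf_j)·β²_j / var(trait)`; direction is supported when the
  exposure R² is larger, with a p-value from Fisher-transformed √R²
  correlations with variance `1/(n_exp − 3) + 1/(n_out − 3)`.

P-values are two-sided normal throughout the estimators. The joint decision
rule — an effect is called causal only when both the one-sample and
two-sample arms reach p < 0.05, strictly — lives in the pipeline, not the
estimators.

## What the synthetic-data generator emulates

`sim_params()`/`simulate_cohort()` generate the study conditions:

- n = 17,000 individuals, 101 biallelic variants in Hardy–Weinberg
  proportions with MAF uniform on (0.05, 0.5), 15% palindromic allele pairs
  to exercise harmonization;
- per-allele effects rescaled so the true score explains a target fraction
  of exposure variance (default 10.8%, the LDL figure; 7.3% and 5.0%
  correspond to the HDL and triglyceride instruments);
- the structural model `X = μ + Gγ + a_x·U + ε_x`,
  `Y = βX + a_y·U + Gα + ε_y` with a single standard-normal confounder U —
  minimal structure sufficient to reproduce sign-flipping observational
  bias. With the defaults (a_x = 1, a_y = −1, σ_x = 0.5, β = 0.5) the
  omitted-variable bias `a_x·a_y·(1−R²)/(a_x² + σ_x²) = −0.71` exceeds β in
  magnitude, so the naive regression is sign-flipped by construction. The
  mechanism behind the real discordance is not asserted; the loadings are
  free parameters.
- statin assignment by a logistic model on the standardized true score
  (intercept −1.6, slope 0.5: about 17% users, rising with genetic risk),
  with measured LDL equal to true LDL divided by 1.43 for users, so the
  multiplicative statin adjustment is its exact inverse. Real-world
  heterogeneity in statin response is deliberately out of scope.
- the exposure mean of 150 gives an LDL-like positive scale so
  multiplicative adjustments stay in-domain; all estimators are invariant
  to it.
- `simulate_two_sample()` draws two non-overlapping cohorts (defaults
  188,577 exposure and 16,923 outcome, the sizes of the consortium datasets
  this layout mirrors) and summarizes each variant by simple regression;
  `analytic = TRUE` returns the noiseless population values so ratio
  identities hold exactly. Pleiotropy enters as direct effects α on a
  configurable fraction of variants (balanced or directional).

What it does *not* emulate: linkage disequilibrium between instrument
variants (an explicit r² matrix drives clumping tests instead), imputation
uncertainty, assay error structure, time-varying exposure, or selection
into the imaging substudy. Passing recovery tests on this generator shows
the estimators are correct under their stated assumptions, not that those
assumptions hold in any real cohort.

## Numerical and testing choices

All randomness flows from one integer seed through a fixed splitting
scheme, so cohorts, bootstraps and simulations are bit-reproducible.
Bootstrap and null-simulation counts default to 1,000 and are arguments
everywhere. Degenerate inputs error loudly with typed conditions:
zero-variance instruments, single-stratum statin flags, rank-deficient
designs (naming the columns), sub-minimum variant counts per estimator
(2 for IVW, 3 for Egger/median/mode, 4 for MR-PRESSO, k+1 for
multivariable MR).

The test suite checks each estimator against an independent oracle (Wald
ratio identities, weighted-mean closed forms, brute-force clumping over
small panels, normal-equation OLS), then property-style invariants
(order invariance, scale equivariance, affine invariance of R², coverage),
and finally statistical calibration by Monte-Carlo: type-I error of 2SLS,
the endogeneity test and the PRESSO global test at 500 null replicates each
(run at n = 400 per replicate and 20–25 variants — sizes chosen so the
suite completes in about a minute while keeping the binomial standard error
of a 5% rate under 1%), the Egger intercept at its 0.10 level, empirical
power at the computed minimum detectable effect, and Steiger directionality.
Recovery checks on the full 101-variant, 17,000-person configuration assert
estimates within three standard errors of the generating truth; the
realized instrument R² is asserted as a mean over 20 seeds at n = 17,000,
since a single seed's R² has a sampling SD of about 0.005.

Two robustness contracts deserve a note on their fixtures. The weighted
median's 50%-validity guarantee concerns the *population* median of ratios;
with 45% invalid weight all shifted in one direction, the finite-noise
weighted median sits at an upper quantile of the valid cluster, a bias
proportional to the ratio noise that no bootstrap SE absorbs — so the
recovery fixture uses large sign-balanced pleiotropy, which is the regime
the guarantee actually covers. Similarly the weighted mode's plurality
property presumes separated ratio clusters; its fixture shifts ratios (not
raw outcome effects) so clusters stay tight, and the distortion-test
fixture uses a detectable but low-leverage outlier, since an outlier with
enough leverage to move the estimate is exactly what the distortion test
should flag.

## Known limitations

Estimators assume independent (clumped) variants; correlated-instrument IVW
is not provided. LIML/GMM, many-weak-instrument corrections,
contamination-mixture estimators and bidirectional MR are out of scope. The
power formula is the two-sided normal approximation for continuous
outcomes. Observational inference is normal-theory, appropriate at cohort
scale but approximate for small n.
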