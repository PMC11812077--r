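---
title: "Predicting body condition score across lactation with a multiple-trait random-regression test-day model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting body condition score across lactation with a multiple-trait random-regression test-day model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Body condition score (BCS) tracks a dairy cow's body fat reserves and is a
key management indicator, but scoring is manual and therefore rare: in
routine Walloon first-parity recording it is observed at only a fraction of
the monthly milk-recording visits, often once per lactation. Milk yield
(MY), fat percentage (FP) and protein percentage (PP), by contrast, are
recorded at every visit. `bcsrr` implements a multiple-trait
random-regression test-day model (RR-TDM) that treats the four traits
jointly so that a single BCS record per cow, plus all her milk records,
yields a BCS prediction at every herd-test date of the lactation.

## The model

For the vector of test-day observations stacked over the four traits,

$$y = Xb + Ut + QW_1h + W_2p + Za + e,$$

with

* $b$ — fixed effects, per trait: the overall mean; herd ×
  test-year-period (HTY; test years 2014–2016 vs 2017–2022); herd × test
  season (HTMp; winter = Jan–Mar, spring = Apr–Jun, summer = Jul–Sep,
  autumn = Oct–Dec); age-at-calving class × calving season × major
  lactation stage (AS; stages DIM 5–50, 51–200, 201–365); and minor
  lactation stage (LS; DIM 5–15, twenty-nine 10-day classes over 16–305,
  and two 30-day classes over 306–365), which models the average lactation
  curve;
* $t$ — random herd-test-day (contemporary group) effects, one intercept
  per trait, covariance $D \otimes I$ ($D$ is $4\times4$);
* $h$ — random herd × calving-year-period regression coefficients
  (calving years 2014, 2015–2017, 2018–2022), covariance $HY \otimes I$;
* $p$ — permanent-environment regression coefficients per cow,
  covariance $P \otimes I$;
* $a$ — additive-genetic regression coefficients per pedigree animal,
  covariance $G \otimes A$ with $A$ the numerator relationship matrix;
* $e$ — residuals, covariance $R$ ($4\times4$) per record, homogeneous
  over the lactation.

$h$, $p$ and $a$ load on second-order Legendre polynomials of days in milk
(DIM), standardized from $[5, 365]$ to $[-1, 1]$; each of $HY$, $P$, $G$
is therefore $12\times12$ (4 traits × 3 coefficients, stored trait-major).
The printed model equation shows the covariate matrix $Q$ only in front of
$W_1h$, but $P$ and $G$ being $12 \times 12$ forces $p$ and $a$ to be
random regressions as well, so the same covariates are folded into $W_2$
and $Z$; $t$ stays intercept-only, matching the $4\times4$ $D$.

Records with missing BCS (the vast majority) enter the equations through
the inverse of the $3\times3$ milk block of $R$; records with BCS use the
full $4\times4$ inverse. This per-pattern treatment is exact, whatever the
missingness pattern.

### Prediction

All effects are estimated from the calibration data (all milk records, one
BCS per cow). The BCS prediction at a held-out herd-test date is the model
part — the sum of the BCS-trait fixed effects, the herd-test-day solution,
and the Legendre-weighted herd-year, permanent-environment and genetic
curves — plus an imputed residual

$$\hat e_{BCS} = R_{BCS,(MY,FP,PP)} R_{(MY,FP,PP)}^{-1}
  (\hat e_{MY}, \hat e_{FP}, \hat e_{PP})',$$

the multivariate-normal conditional expectation of the BCS residual given
the milk residuals of the same record (equivalently, the best linear
unbiased prediction of the unobserved residual). The continuous prediction
is then rounded to the 9-point scale — ties away from zero, clamped to
$[1, 9]$; both conventions are package decisions, as the scale's
definition forces clamping but no tie rule.

Predictions are produced at herd-test dates with milk records, where the
herd-test-day solution and the milk residuals exist. `predict_model_part()`
with `require_htd = FALSE` extends to arbitrary DIM by dropping those two
terms — both are unavailable off test dates, so such predictions carry only
the fixed-effect, herd-year, permanent and genetic curves.

## Solving and estimating

The mixed-model equations are assembled sparse (`Matrix`), with
$G^{-1} \otimes A^{-1}$ built from the pedigree by Henderson's rules with
inbreeding from the Meuwissen–Luo recursion. Two factorization paths are
used:

* **Solving.** The fixed-effect block is rank-deficient by construction
  (the mean, HTY and HTMp all span each herd's records; AS and LS both
  span the major-stage margins). Redundant equations are identified once as
  the zero pivots of the fixed-block Gram matrix under a fill-reducing
  ordering and constrained to zero — a deterministic choice of generalized
  inverse — and the remaining positive-definite system is factored by
  CHOLMOD's supernodal Cholesky. A fixed "drop the first level" rule was
  considered and rejected: per-herd aliasing makes the redundant set
  data-dependent, so no static rule removes all of it.
* **REML.** EM-REML needs selected elements of the inverse coefficient
  matrix. The package computes a simplicial LDL' factorization and the
  Takahashi inverse subset (all inverse elements on the factor's pattern)
  in compiled code, since no installed package exposes such a routine. The
  EM updates are the classical ones: each covariance matrix is replaced by
  the average over its levels of (solution outer product + the
  corresponding inverse block), with $A^{-1}$-weighting for the genetic
  component, and the residual update imputes the unobserved traits of each
  record from the conditional normal. Every update is positive
  semi-definite by construction and the restricted log-likelihood never
  decreases — both properties are asserted in the tests. The fill-reducing
  ordering is computed from a densified component pattern, because after
  one EM update every 12×12 block is dense; ordering on the (sparser)
  starting pattern costs an order of magnitude per iteration.

On the choice of algorithm: Walloon-style evaluations estimate these
components with AI-REML in blupf90. Only the converged point matters here,
so the package implements the monotone EM baseline; average-information
acceleration was left out deliberately (EM's monotonicity and automatic
positive semi-definiteness are what the tests lean on). Convergence is
declared at a relative parameter change below `tol` (default $10^{-6}$);
starting values split the observed phenotypic covariance 10% genetic, 10%
permanent, 5% herd-year, 5% herd-test-day, 70% residual, with damped
(halved) phenotypic cross-trait correlations — the usual multi-trait
starting point, which also spares the slowly-converging correlation
components many early EM iterations. A `fix` setting can hold any
component matrix at its starting value (used, e.g., to collapse the model
onto a balanced one-way design whose REML solution is known in closed
form; the package's tests do exactly that).

Daily parameters follow from the covariance functions: at DIM $d$ with
covariates $q(d)$, the daily genetic variance of a trait is
$q(d)'G_{tt}q(d)$, daily heritability is the genetic fraction of
$v_g + v_p + v_{hy} + v_{htd} + v_r$, and daily genetic correlations come
from the cross-trait blocks; `daily_parameters()` reports means and SDs
over the DIM grid.

## The synthetic generator

The original herd data are not deposited, so the package ships a generator
(`simulate_records()`) that runs the model forward under a documented
truth, emulating the study's structure: many small herds (default 30 herds
of 15–25 first-parity cows), monthly herd visits with 2–12 realized tests
per cow (mean ≈ 8), calving ages 540–1200 days, and BCS arising from
*scoring visits* — on a randomly chosen ~39% of herd visits the whole herd
is condition-scored, matching how a technician scores a herd and yielding
the observed pattern of BCS being roughly 2.5× sparser than milk records.
The observed BCS is a rounded, clamped latent Gaussian; the model is then
fitted to the rounded data, so the discretization attenuation that the
real validation carries is present in the synthetic one too.

The truth components (`default_truth()`) target the published first-parity
genetic picture: mean daily heritabilities 0.16 (MY), 0.22 (FP), 0.25
(PP), 0.11 (BCS) within ±0.02 (verified by `daily_parameters()` in the
tests), genetic correlations with the published signs and magnitudes
(MY–BCS −0.25, MY–FP −0.44, MY–PP −0.45, FP–PP 0.61), and
permanent-environment correlations as published. Quantities the study does
not print are package decisions, chosen once on biological grounds:

* BCS variance shares 0.11 genetic / 0.55 permanent environment / 0.08
  herd-year / 0.06 herd-test-day / 0.20 residual. The high permanent share
  encodes that body reserves change slowly — within-lactation BCS
  repeatability ≈ 0.7 — which is also the regime in which a single
  calibration record is as informative as the study's validation shows it
  to be.
* Residual cross-trait correlations (MY–FP −0.30, MY–PP −0.30, FP–PP
  0.40, BCS–milk −0.15/0.10/0.10): modest day-level energy-balance
  couplings; the study prints none.
* Fixed-class true values: herd-year, herd-season and age-season-stage
  classes are drawn once per class with SD 0.25 of the trait's phenotypic
  SD (herd feeding and management differences are substantial); the
  minor-stage truth follows smooth lactation curves — milk rising to a
  peak near DIM 50 then declining, fat and protein dipping at peak yield,
  BCS declining to a nadir around DIM 100 and recovering — with small
  class-level noise.
* Pedigree: founder males and females, two generations of random mating,
  record-less sires (as in real recording), exact Mendelian-sampling draws
  so the genetic coefficients have covariance $G \otimes A$ including
  inbreeding.

What the generator does **not** emulate: culling and non-random missing
visits, multiple parities, classifier effects on BCS scoring, seasonal
calving concentration, and genetic trend. Passing tests therefore show
that the machinery recovers what it claims under the model's own
assumptions at desk scale — not that the model is well-specified for any
particular real herd.

## Problem sizes used by the tests and the acceptance analyses

All sizes are package choices, set once:

* **Oracle equivalence** — 20 random instances of ≤ ~30 records, 5–8
  animals, jittered random components; dense V-based GLS/BLUP, dense
  pedigree inversion and multivariate-normal conditioning as oracles.
* **REML recovery** — 6 herds × 12–15 cows (~80 cows, ~650 records), BCS
  scored at every visit, two pedigree generations, 40 EM iterations from
  the default start, 10 seeds. At this size the mean daily BCS
  heritability is recovered within ±0.07 in every seed. The sign of the
  MY–BCS genetic correlation is recovered in 8 of 10 seeds: with ~80 cows
  the sampling spread of a genetic correlation whose true value is −0.25
  is large, and experiments at 2× the scale (where a 10-seed loop already
  exceeds a desktop run's budget several-fold) still show occasional
  wrong-sign seeds. The aggregate estimate across seeds is reliably
  negative.
* **End-to-end prediction** — 60 herds × 25–35 cows (~1500 cows), fitted
  at the true components, three seeds. The larger size is needed because
  the trait-nested fixed classes (≈250 BCS-trait class equations) overfit
  badly when the calibration holds only ~600 BCS records: below roughly
  1000 cows the class-estimate noise alone pushes the model's absolute
  prediction error above the constant-mean baseline. At ~1500 cows the
  model clearly beats the baseline (APE ≈ 0.72 vs ≈ 0.80 BCS units,
  r ≈ 0.5).
* **Pipeline closure and determinism** — the default 30-herd scale;
  identical configuration and seed reproduce byte-identical prediction
  and validation files.

## Numerical choices and degenerate inputs

* Legendre covariates are orthonormal by default
  ($\phi_k = \sqrt{(2k+1)/2}\,P_k$); a flag switches to raw $P_k$.
  Variance components are basis-dependent, so the pipeline manifest logs
  the flag.
* Zero pivots are declared at $d_j \le 10^{-9}$ relative to the original
  diagonal; constrained equations report solution 0 and are zeroed in the
  generalized inverse (also inside the EM trace terms, where the
  generalized inverse is the correct object).
* `solve_mme()` verifies the relative residual norm of the returned
  solution against $10^{-8}$ and errors otherwise.
* Rounding ties go away from zero; BCS class boundaries clamp to
  $[1, 9]$.
* Cohen's kappa: weights $1 - d/(k-1)$ (linear) and $1 - (d/(k-1))^2$
  (quadratic) with $k = 9$; large-sample (Fleiss–Cohen–Everitt) standard
  errors; a single-category table is flagged degenerate rather than
  returning a number. The published validation table gives κ = 0.439
  unweighted, 0.558 linear, 0.682 quadratic — the published scalar κ of
  0.67 sits near the quadratic value but matches none exactly, so all
  three are always reported rather than matching one silently.
* Pearson confidence intervals use the Fisher z transform; with fewer
  than two complete pairs the correlation is reported as unavailable
  while PE/APE/RMSE are still computed.
* Age-at-calving classes default to terciles of the observed
  age-at-first-calving distribution (the study names three classes but no
  boundaries); explicit cut-points can be supplied and are logged.
* An empty observed-trait pattern, BCS outside 1–9, duplicate
  animal×date records, pedigree cycles and non-positive Mendelian
  sampling variances are hard errors with the offending units named.

## Known limitations

* Fixed effects are nested within trait; whether the original evaluation
  nested them identically is not recoverable, and at small herd counts the
  BCS-trait class equations dominate the prediction error (see problem
  sizes above).
* EM-REML converges slowly in the correlation directions; the iteration
  caps used in the analyses stop it at a relative change around
  $10^{-2}$–$10^{-3}$, adequate for variance ratios but leaving cross-trait
  correlations conservative (pulled toward their start).
* Residual variance is homogeneous over DIM by design; heterogeneous
  residual classes are out of scope.
* The calibration split keeps one BCS per cow, which leaves the BCS
  permanent-environment and residual variances barely separable — the
  recovery analyses therefore estimate components from data with repeated
  BCS, and the split protocol is used for solutions and prediction.
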