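---
title: "Omics ageing clocks, their overlap, and age-acceleration associations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Omics ageing clocks, their overlap, and age-acceleration associations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocaa)
```

## The model

An *omics ageing clock* is a sparse linear predictor of chronological age
(chronAge, $Y$, in years) built from the features of one omics assay.
Given a standardised feature matrix $X$, the clock solves the elastic-net
problem

$$
\hat\beta = \arg\min_\beta \; \tfrac1{2n}\lVert Y - \beta_0 - X\beta\rVert^2
 + \lambda\left(\alpha\lVert\beta\rVert_1 +
   \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right),
$$

with the mixing parameter fixed at $\alpha = 0.5$ by default and $\lambda$
chosen by ten-fold cross-validation in the training sample at minimum mean
squared error (not the one-standard-error rule).  The cohort is split
75/25 into training and testing; the testing quarter is drawn
preferentially from individuals with complete data on every assay, so all
clocks can be evaluated on the same people.  The clock's output is the
*omics clock age* (OCA); its excess over chronAge,

$$\mathrm{OCAA} = \mathrm{OCA} - \mathrm{chronAge},$$

is the *omics clock age acceleration*, in years, interpreted as an
estimate of how much biologically older (positive) or younger (negative)
a person is than their calendar age.

Because clock construction is stochastic in the split, a *core* clock is
derived by repeating the whole procedure (fresh split, fresh
cross-validation) `iterations` times (default 500) and refitting — again
with the full procedure — on the features selected in more than 95% of
repeats.  The core refit re-runs cross-validation for $\lambda$; whether
the original study refit or froze the penalty is not decidable from its
description, and re-running is the choice consistent with "the same
construction procedure".  Mega-omics clocks column-bind all assays over
the intersection of their individuals (feature ids prefixed by assay), and
principal-component clocks fit the elastic net on the leading PCs of one
assay, with rotations estimated on training rows only.

Two leakage guards are deliberate: features are standardised with
training-set means and SDs (stored in the model and re-applied at
prediction time), and PC rotations are likewise training-only.  The
fitting function standardises internally, so coefficients are always in
years per SD of feature.

## Quality control

Each assay passes through a fixed sequence:

1. first-pass outlier masking: values with $|z| > 6$ (z-scores from the
   feature's own non-missing mean and SD) become missing;
2. covariate pre-correction: each feature is replaced by its least-squares
   residuals on the assay's covariates (sex always; batch and others as
   configured), with aliased design columns dropped and logged;
3. optional second-pass masking at $|z| > 3$ — computed on the
   *post-correction residual* distribution, since a residual-scale pass is
   the only reading under which a second threshold adds information after
   batch and sex shifts are removed;
4. standardisation of every feature to mean 0, SD 1 (constant features are
   dropped and logged).

The outlier passes are single-shot, never iterated to convergence.
Missing values are excluded pairwise from means and SDs; individuals with
missing features are dropped per assay at clock-training time, not
globally.

## Partitioning the variance in chronAge

For a set of $k$ clocks, the *unique* contribution of clock $i$ is the
squared semi-partial (part) correlation of chronAge with $X_i$
controlling for the other clocks.  It is computed by the leave-one-out
identity

$$ sr_i^2 = R^2(X_1,\dots,X_k) - R^2(X_{-i}), $$

which is numerically stable and is verified in the test suite against an
independent residual-based oracle
($sr_i^2 = \mathrm{cor}(Y, e_{i\mid -i})^2$ with $e_{i\mid -i}$ the
residual of $X_i$ on the other clocks).  The partition

$$ 1 = \underbrace{\textstyle\sum_i sr_i^2}_{\text{unique}}
 + \underbrace{R^2 - \sum_i sr_i^2}_{\text{shared by}\ \ge 2\ \text{clocks}}
 + \underbrace{1 - R^2}_{\text{unexplained}} $$

holds to $10^{-9}$ by construction; tiny negative components from
floating-point cancellation are floored at zero and logged.  Mega-omics
clocks are excluded from all between-clock comparisons by default (their
features span every assay, so overlap with them is uninformative); the
exclusion is overridable.

## The scaled excess-overlap statistic

Write $v_1, v_2$ for the univariate $R^2$ of each clock and $O$ for the
joint (bivariate) $R^2$.  Under the null that each clock *independently
samples from a latent set of complete predictors* of chronAge (ISLSP),
the variance left unexplained after both clocks is $(1-v_1)(1-v_2)$, so
the expected joint variance is

$$ E = 1 - (1 - v_1)(1 - v_2). $$

The attainable range of $O$ is $[E_{\min}, E_{\max}]$ with
$E_{\min} = \max(v_1, v_2)$ (the second clock adds nothing) and
$E_{\max} = \min(v_1 + v_2, 1)$ (fully complementary clocks).  Because
accurate clocks leave little room for $O$ to move, the deviation of
observed from expected is rescaled:

$$ \text{excess overlap} = \frac{E - O}{E - E_{\min}}. $$

A clock paired with itself scores exactly 1 at any accuracy; the ISLSP
expectation scores 0; negative values mean the clocks track
disproportionately complementary components of ageing.  Two numerical
choices: $O$ outside $[E_{\min}, E_{\max}]$ by sampling noise is clamped
(with a warning), and the degenerate case $E = E_{\min}$ (one clock
explains nothing) returns `NA` rather than a division by zero.

### The exact ISLSP construction

`simulate_latent_predictor_bank()` makes the null exact rather than
asymptotic: it builds $p$ predictors that are *exactly* orthonormal in
the realised sample (centred Gaussian matrix, QR orthonormalisation,
unit-SD rescaling) whose sum is standardised chronAge with no noise.  A
clock identified with a subset $S$ of the bank then explains exactly
$|S|/p$ of the variance, and a pair of clocks explains the coverage of
$S_1 \cup S_2$.  When $|S_1 \cap S_2|$ equals its expectation under
independent sampling ($|S_1||S_2|/p$, the hypergeometric mean), the union
coverage equals $E$ and the excess overlap is zero to machine precision.
Note the union, not the regression on the two subset *sums*, is the
null's joint variance: collapsing a subset to its sum discards
within-subset information, and the bivariate $R^2$ of the two sums (2/3
in the 50/50-with-25-overlap case) is strictly below the union coverage
(3/4).  For real clock pairs, where only the two OCA vectors exist, the
observed $O$ is the bivariate $R^2$ of those vectors, as in
`overlap_pair()`.

## Associations with risk factors and incident disease

Outcomes are screened before any OCAA test, to restrict the
multiple-testing burden: a risk factor or disease enters the association
stage only if its chronAge effect is positive, passes Benjamini-Hochberg
FDR at 10% within its outcome-type family, and (diseases) has more than 5
incident cases.  One-sided p-values are upper normal-tail probabilities of
the Wald $z$, the alternative being that age (or OCAA) increases risk.

Risk factors are standardised and fitted by least squares on OCAA with
chronAge and sex as covariates (smoking optionally, as a confounding
check).  Diseases use Cox proportional-hazards fits (Efron ties) of time
from assessment to first incidence, censored at end of follow-up, with
prevalent cases — any event before baseline — excluded entirely.  The
baseline hazard is on the time-since-assessment axis so that chronAge and
OCAA effects are comparable coefficients.

Effects are then rescaled into *years of chronAge per year of OCAA* by
dividing by the chronAge effect: trait-by-trait for risk factors, and a
single pooled per-year log hazard ratio for all diseases.  The pipeline
estimates that pooled divisor as the inverse-variance-weighted mean of the
per-disease chronAge log-HRs from its own screening stage; 0.0492 per year
(a doubling of risk every $\ln 2 / 0.0492 \approx 14$ years) is the
default when no diseases are eligible.  The divisor enters by magnitude:
for screened-eligible outcomes risk rises with age by construction, so a
negative printed sign on a pooled per-year effect can only be a labelling
artefact, and dividing by a negative number would flip every rescaled
effect.

Each estimate is also shrunk under a standard-normal prior
(posterior mean $\beta / (1 + \mathrm{se}^2)$), pulling noisy estimates
towards zero, and aggregated across outcomes per clock by
inverse-variance weighting.  Outcomes and clocks are correlated, so the
pooled SEs violate the independence assumption behind the IVW formula;
they are reported as *indicative* and never used for formal testing.
Sex-consistency follows the pooled-then-stratified pattern: associations
nominally significant in the pooled analysis are re-screened within each
sex under the same eligibility rule (the screen model drops the
now-constant sex covariate), sign agreement is counted, and discrepant
pairs get a two-sided $z$-test on standardised effects.

## The synthetic cohort generator

No individual-level data from the motivating study design are
distributable, so the generator reproduces the *moment structure* the
analysis consumes, and nothing more:

* chronAge uniform on a configured range, default 16–100 years — the
  design reports a range, not a shape, and the uniform maximises spread
  for clock training;
* one latent biological-age acceleration $\delta \sim N(0,
  \sigma_\delta^2)$ per individual, default $\sigma_\delta = 5$ years, a
  typical scale for clock age-acceleration spreads; a single component is
  the default on parsimony grounds;
* assay features $x_j = a_j z(\text{age}) + b_j z(\delta) + \text{batch}
  + \varepsilon_j$, loadings drawn once per feature from half-normals.
  The default four assays span weak to strong age loading, which makes
  trained-clock test correlations span roughly 0.2–0.95 — the
  qualitative range the analysis needs to exercise;
* risk factors linear in age and $\delta$ plus unit noise (one default
  factor declines with age, exercising the positive-effect screening
  gate);
* disease event times exponential with rate
  $\lambda_0 \exp(\beta_a \cdot \text{age} + \beta_\delta \cdot \delta)$,
  default $\beta_a = \beta_\delta = 0.0492$ per year, censored at 10
  years; prevalent cases arise from running the same hazard backwards
  over a 10-year pre-baseline window, so the prevalent-exclusion filter
  is always exercised.

All randomness flows from one master seed through a documented
stream-splitting rule (`derive_seed(seed, stage, index)`), so any stage
can be regenerated independently and identical configurations are
bit-identical.  What the generator deliberately does **not** emulate:
methylation beta-value distributions, glycan peak chemistry, NMR spectral
structure, non-linear age trajectories, informative censoring, or
correlated measurement error across assays.  Passing tests therefore
demonstrate the estimators' correctness under the assumed moment
structure, not robustness to the full messiness of real assays.

## Numerical choices and degenerate inputs

* Cross-validation folds are seeded and recorded; per-iteration seeds in
  stability selection derive from the master seed plus the iteration
  index, making the loop order-independent and parallelisable by
  contract.
* Constant features are unchanged by outlier masking (SD 0 guard) and
  dropped at standardisation; all-missing features warn and pass through.
* A single-feature assay is fitted by ordinary least squares — penalising
  one predictor chosen in advance serves no purpose.
* An all-zero coefficient clock warns but is returned (its predictions
  are the intercept; correlations are `NA`).
* Collinear clock pairs in the partition report zero unique variance with
  a warning; negative variance components above $-10^{-9}$ are floored.
* Pipeline stages always consume the on-disk TSV representation of their
  inputs, so resumed runs are byte-identical to fresh ones.

## Problem sizes in the test suite

The suite exercises parameter recovery at the sizes the estimators need:
Cox screening recovery at $n = 20{,}000$, linear screening at
$n = 1{,}000$, OCAA-disease rescaling at $n = 8{,}000$, null calibration
over 200 replicates, partition oracles over 100 random instances, and
stability selection at 20–50 iterations on assays of 30–60 features
(the 500-iteration default is for real analyses).  The end-to-end
pipeline checks run at $n = 500$–700 with three assays.

## Known limitations

The generator's linear, single-$\delta$ world cannot distinguish clocks
that track different *kinds* of biological ageing; the excess-overlap
machinery would, but the default conditions do not generate such
structure (configure several assays with uncorrelated extra components to
explore it).  Rescaled disease effects inherit the noise of the pooled
divisor.  IVW standard errors are indicative only.  The Cox fits assume
proportional hazards and exponential baseline — adequate for the moment
structure generated here, untested beyond it.
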