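---
title: "Methods: population pharmacokinetics of high-dose oral baclofen"
author: "baclopk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of high-dose oral baclofen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baclopk)
```

## The problem

Baclofen is prescribed off-label for alcohol use disorder at daily doses far
above the 80 mg/day used in spasticity — up to 300 mg/day. Two questions
drive the analysis this package implements: whether the drug's kinetics stay
linear over that tenfold dose range (a saturation of elimination would mean
accumulating exposure; a saturation of absorption, under-exposure), and
whether any clinical or biological covariate explains the between-subject
variability in exposure. Both are answered with a population (nonlinear
mixed-effects) model estimated from sparse samples: each subject contributes
only 9–10 plasma concentrations drawn around two consecutive intakes of their
own usual regimen, at steady state.

## Structural and statistical model

Concentrations follow a one-compartment model with first-order absorption
and elimination, parameterized as apparent clearance $CL/F$ (L/h), apparent
volume $V_d/F$ (L) and absorption rate constant $K_a$ (1/h). After a single
oral dose $D$ at time 0,

$$C(t) = \frac{D\,K_a}{V\,(K_a - k)}\left(e^{-kt} - e^{-K_a t}\right),
\qquad k = CL/V,$$

and a dosing history is handled by superposition, which is exact for a
linear model. Bioavailability $F$ is not identifiable from oral data alone,
so all parameters are apparent ($CL/F$, $V_d/F$); $F$ never appears
explicitly. At $K_a = k$ the expression has a removable singularity; within
a relative band of $10^{-8}$ the limiting form $(D k t / V)e^{-kt}$ is used,
keeping the function continuous without catastrophic cancellation.

Between-subject variability is log-normal,
$CL_i = TVCL \cdot e^{\eta_i}$ with $\eta_i \sim N(0, \omega^2)$ (same
pattern for $V$ and $K_a$, diagonal $\Omega$ — the study reports no
correlation terms), and residual variability is the exponential model
$y_{ij} = f_{ij}\,e^{\varepsilon_{ij}}$. Taking logs makes the residual
exactly additive Gaussian with variance independent of $\eta$, so the
"interaction" part of FOCE-I is handled exactly rather than by
linearization.

Default parameter values throughout the package are the adult estimates for
racemic baclofen: $CL/F$ 11.6 L/h, $V_d/F$ 72.8 L, $K_a$ 1.64 1/h
($t_{1/2} = \ln 2 \cdot V/CL \approx 4.4$ h), $\omega_{CL}$ 0.21,
$\omega_V$ 0.22, $\omega_{Ka}$ 0.44 (log-scale SDs, read approximately as
%CV), and $\sigma$ 0.24.

## Estimation (FOCE-I)

For subject $i$ with log-observations $z_{ij}$ and dosing history $d_i$,
the conditional (empirical Bayes) estimate $\hat\eta_i$ minimizes

$$g_i(\eta) = \frac{1}{\sigma^2}\sum_j \left(z_{ij} - \log f_{ij}(\eta)
\right)^2 + \eta'\Omega^{-1}\eta,$$

found by damped Gauss–Newton from $\eta = 0$ with an analytic Jacobian of
$\log C$ with respect to the log-scale effects. The marginal contribution is
the Laplace/FOCE approximation expanded at $\hat\eta_i$:

$$\mathrm{OFV}_i = g_i(\hat\eta_i) + n_i \log(2\pi\sigma^2) +
\log\lvert\Omega\rvert +
\log\left\lvert \frac{J'J}{\sigma^2} + \Omega^{-1} \right\rvert,$$

with $J$ the Jacobian at the mode. The additive convention includes the
$n\log 2\pi$ term of the log-scale density, so absolute OFVs differ from
other software by a dataset constant; every selection decision uses OFV
differences only, which are convention-free. Laplace is exact for models
linear in $\eta$; the test suite exploits this with a closed-form Gaussian
marginal oracle.

The outer problem maximizes the summed approximate likelihood over
$\log\theta$, covariate coefficients (log-multipliers for categorical
effects), $\log\omega^2$ and $\log\sigma^2$ with a quasi-Newton (PORT)
optimizer. The outer gradient is computed analytically: the residual part
collapses by the envelope identity at the inner mode, and the
log-determinant part is differentiated implicitly through the mode
condition $J'r/\sigma^2 = \Omega^{-1}\hat\eta$ using the closed-form
second-derivative tensor of $\log C$. The gradient is verified against
central differences of the objective in the test suite. Standard errors
come from the finite-difference Hessian of OFV/2 at the optimum; because
internal parameters are logs of the reported quantities, the standard error
of a log-parameter is directly the relative standard error, and for SD-scale
parameters ($\omega$, $\sigma$) the factor ½ maps $\log\omega^2$ to
$\log\omega$. A non-positive-definite Hessian yields NA RSEs plus the
eigen-spectrum rather than silent output.

Numerical conventions that matter:

* internal units are mg, L, h (concentrations in mg/L); files carry ng/mL
  (× 1000 at the boundary), matching the assay's 5.00–500 ng/mL range;
* box bounds $\theta \in [10^{-3}, 10^4]$, $\omega^2 \in [10^{-6}, 25]$,
  $\sigma^2 \in [10^{-8}, 25]$ on the log scale keep the search in a
  physically meaningful region;
* inner Gauss–Newton stops at a relative objective change of $10^{-13}$
  (cheap, since convergence near the mode is quadratic) so the objective is
  a pure function of its arguments to near machine precision; the outer
  relative tolerance is $10^{-9}$ for reported fits and $10^{-6}$ for
  throwaway refits inside the covariate search and the bootstrap;
* dosing histories enter the likelihood as *dose groups* — a first dose
  plus a count of exact 24 h repeats — accumulated by geometric recursion.
  This is algebraically identical to naive superposition (the test suite
  checks agreement with the naive path at $\sim 10^{-8}$) and roughly
  4× cheaper on a 4-day history;
* refits of resampled or extended models may start the inner solver from
  the parent fit's EBEs. The starting matrix is fixed per fit, so the
  objective stays pure; reported EBEs are always recomputed from
  $\eta = 0$;
* BLQ observations (below 5 ng/mL) are excluded from the likelihood and
  counted (M1 handling); at the default generating parameters they are rare
  (troughs of even the 30 mg/day regimens sit well above the limit).

## Covariate model and stepwise search

Continuous covariates act as power terms centred at the analysis-dataset
median, $CL = TVCL \cdot (x/\tilde{x})^{\theta_x}$; binary covariates as a
multiplier on the non-reference level, $CL = TVCL\cdot\theta_{sex}^{SEX}$;
the 4-level dose group as one multiplier per non-reference level (3 df),
with the reference taken as the most populated level (ties resolved to the
lowest). Categorical levels under 10% prevalence are pooled into their
nearest neighbouring level before testing; a covariate left with a single
level is dropped with a log entry.

Selection is greedy forward inclusion followed by backward elimination on
likelihood-ratio thresholds: a candidate enters when it drops the OFV by at
least the $\chi^2_{df}$ upper-5% quantile (3.84 for 1 df; 7.81 for the
3-df group covariate), best candidate first, until none passes; each
included effect is then removed in turn and kept only if its removal raises
the OFV by more than the upper-0.1% quantile (10.8 for 1 df, 16.3 for 3
df). The screened space pairs every clinical covariate (daily dose, dose
group, intakes/day, sex, weight, age, BMI, lean body mass, creatinine
clearance, serum creatinine, prothrombin time, bilirubin, AST, ALT) with
clearance; body-size covariates and sex additionally with volume; dose and
intakes/day additionally with $K_a$ — physiological plausibility bounds the
combinatorics. Under the null (no generated effects) roughly one spurious
candidate per study passes the forward 5% gate by chance; the strict
backward gate then removes it, which is why the expected final model on
null data is the covariate-free one.

## Simulation-based diagnostics

**Ensembles.** All diagnostics rest on replicate datasets simulated from a
fitted model under the *original* design — same subjects, dose histories,
sampling times and covariates — with fresh $\eta \sim N(0,\hat\Omega)$ and
log-scale residuals.

**NPDE.** Per subject, observed and simulated vectors are decorrelated with
the inverse Cholesky factor of the empirical simulation covariance; the
rank of each decorrelated observation among its simulations (mid-ranks for
ties) gives $pd \in [1/2K,\, 1 - 1/2K]$ and
$\mathrm{NPDE} = \Phi^{-1}(pd)$, approximately $N(0,1)$ under a correct
model. The clipping bound prevents infinite quantiles; a singular
simulation covariance triggers a flagged marginal fallback.

**pcVPC.** Observations and simulations are prediction-corrected by the
ratio of the bin-median population prediction to the row's own, binned on
time-after-dose with edges {0, 1, 2, 3, 4, 6, 8, 12, 24} h (the sampling
windows); bins under 5 observations merge into their neighbour. Observed
5/50/95th percentiles are compared with the across-replicate 95% band of
the same percentiles.

**Bootstrap.** Subjects are resampled with replacement, stratified by dose
group to preserve the 10/15/16/16 design, and the model is refitted on each
replicate (warm-started from the original estimates); percentile 2.5/97.5
intervals use converged replicates only, and a non-convergence rate above
20% flags the result unreliable.

## The synthetic-study generator

The generator reproduces the trial that motivates the package: 57
completers in four daily-dose groups (10/15/16/16 subjects; <60, 60–120,
>120–180, >180 mg/day), each continuing their usual regimen unchanged
through a 72 h run-in — more than 16 half-lives, so residual
non-stationarity is below 1% and steady state is represented by an explicit
dosing history rather than a steady-state formula. Daily doses are
truncated-normal draws per group (means 37/93/163/251 mg, observed
min–max bounds), rounded to 10 mg and split equally across intakes in
10 mg units with the remainder on the first intake. Intakes per day follow
the observed per-group distributions but are capped at 6, because a
repeating daily schedule cannot keep the protocol's 4 h minimum between
consecutive intakes beyond six; draws above the cap are redrawn by
truncation. Intakes are spread evenly over the 24 h cycle, identically each
day.

Sampling follows the windowed sparse design: a pre-dose sample before each
of two consecutive intakes N and n on the sampling day, post-N samples in
the 0–1, 1–2 and 2–3 h windows, one sample between 3 h and the next dose
(two when the interval leaves at least 2 h past the 3 h mark), post-n
samples at 0–1 and 1–2 h, and a next-morning trough — 9 or 10 samples per
subject, so a 57-subject study schedules 513–570 observations, bracketing
the 522 analysed in the real study. Ages, sex and group sizes follow the
published demographics (truncated normals and per-group female fractions).
Weight, height, serum creatinine and the liver panel are *not* published;
the defaults (e.g. weight $N(75, 15^2)$ kg truncated to [45, 130], +5 kg
for males; creatinine $N(0.9, 0.2^2)$ mg/dL, +0.1 for males) are documented,
configurable choices. Creatinine clearance is recomputed by
Cockcroft–Gault and creatinine redrawn while $CRCL \le 30$ mL/min (the
renal exclusion criterion). Dropout is not modelled: the generator produces
completers only, matching the analysed n = 57. All randomness derives from
one master seed through fixed per-subject substreams, so any subject's data
are reproducible independently of the others.

What the generator does *not* emulate: enantiomer-specific kinetics (the
racemate is one analyte), irregular real-world dosing times and recording
errors, missed samples (an optional per-sample missingness rate exists but
defaults to 0, since the study does not say how 522 realized observations
relate to the schedule), assay batch effects, and any covariate–parameter
relationship — the real study found none, and the generator's null is what
makes the covariate-search calibration checks meaningful. Passing tests
therefore demonstrate internal consistency of estimator, design and
diagnostics, not robustness to the messiness of real clinical data.

## Qualification sizes

The test suite exercises the pipeline at desk scale, chosen so the whole
suite runs in minutes on one core: parameter recovery and the covariate
null result use 20 replicate studies of the full 57-subject design;
NPDE calibration uses 100 replicates of a 15-subject reduction
(groups 3/4/4/4) with K = 120 simulation replicates each, plus one
study-scale check at K = 500; the pcVPC check uses K = 200; bootstrap
coverage uses 20 outer replicates with B = 100 resamples each (B = 50 is
the enforced minimum; 200 or more is recommended for reported intervals,
and K = 500 replicates — the published choice — for reported VPCs). The
acceptance script reports medians over 20 seeded replicates.

## Known limitations

* The FOCE/Laplace objective is an approximation; its small-sample bias on
  $\omega$ terms (visible as $\hat\omega_{Ka}$ medians slightly below the
  generating 0.44 under the sparse design) is inherent to the method, not
  a defect of the optimizer.
* $\Omega$ is diagonal; CL–V correlation is not estimable here and not
  attempted.
* BLQ handling is exclusion (M1). At 5 ng/mL and these regimens the BLQ
  fraction is negligible, so likelihood-based censoring methods (M3) would
  change nothing detectable.
* No inter-occasion variability, lag time, two-compartment or
  Michaelis–Menten structures: the model family is the one the data
  supported.
* Flip-flop ambiguity ($K_a < k$) is not constrained away; with the
  default parameters the two rates are well separated and the sampling
  design identifies $K_a$, if with the largest RSE and shrinkage of the
  three parameters — mirroring the study's conclusion that individual
  $K_a$ estimates are the least reliable.
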