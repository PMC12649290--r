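---
title: "Methods: population PK of cobicistat-boosted osimertinib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of cobicistat-boosted osimertinib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osipk)
```

## The problem

Osimertinib, a third-generation EGFR tyrosine-kinase inhibitor, is dosed at
80 mg once daily (QD). Its metabolism is dominated by CYP3A, so
co-administering the strong CYP3A inhibitor cobicistat ("pharmacokinetic
boosting") raises osimertinib exposure. If boosting is combined with a
reduced dosing frequency, the standard exposure can in principle be
maintained at roughly two-thirds of the tablet consumption — a meaningful
cost reduction under flat per-tablet pricing. `osipk` implements the
quantitative machinery for this question: a parent–metabolite population PK
model with a cobicistat covariate, a virtual-crossover simulator of
candidate regimens, geometric-mean-ratio (GMR) equivalence assessment, a
FOCE-I estimation engine with its diagnostic battery, and a generator of
sparse two-occasion datasets of the kind such boosting studies collect.

## Structural model

Three compartments in series, all transfers first order:

* depot (oral dose) → parent central: absorption rate constant $k_a$;
* parent central: apparent volume $V_p/F$, apparent clearance $CL_p/F$;
* a fixed fraction $f_m = 0.25$ of eliminated parent becomes the active
  metabolite AZ5104, with its own $V_m/F$ and $CL_m/F$.

$$
\begin{aligned}
\dot A_1 &= -k_a A_1 \\
\dot A_2 &= k_a A_1 - \tfrac{CL_p}{V_p} A_2 \\
\dot A_3 &= f_m \tfrac{CL_p}{V_p} A_2 - \tfrac{CL_m}{V_m} A_3
\end{aligned}
$$

with concentrations $A_2/V_p$ and $A_3/V_m$. The system is linear, so the
package uses the closed-form tri-exponential solution everywhere: dose
lists by superposition, covariate switches mid-history by propagating the
state vector analytically across segments, and the periodic steady state by
closing the geometric series of each exponential term
($\sum_m c\,e^{-k(\tau + mT)} = c\,e^{-k\tau}/(1-e^{-kT})$). A stiff ODE
integration (deSolve) serves as the independent oracle in the tests, to a
relative error of $10^{-6}$. No peripheral compartments, lag times,
transit absorption or nonlinear elimination are modeled; bioavailability
$F$ is not separately identifiable from oral data, so every volume and
clearance is apparent (per $F$).

Internal units are µg, L and h, so concentrations are µg/L; AUCs are
reported in mg/L·h to match the clinical convention.

**Degenerate rate constants.** The distinct-rate solution divides by
differences of rate constants. When two rates agree to better than one part
in $10^8$ the engine nudges them apart by one part in $10^7$ (a
perturbation branch of the $t\,e^{-kt}$ limit). The induced error is of
order $10^{-7} k t$ — far below the residual error scale — and the output
is always finite.

## Population model

Allometric scaling is applied a priori with exponents 1 ($V/F$), 0.75
($CL/F$) and −0.25 ($k_a$), referenced to 70 kg. Between-subject
variability is log-normal on the two clearances with covariance matrix
$\Omega$; concomitant cobicistat multiplies the parent $CL/F$ by
$\theta_{cobi}$. The default parameter set is the published final model:

```{r}
pk_population_parameters()
```

Two reading decisions behind these defaults: the proportional residual
error 0.178 is interpreted as a standard deviation (17.8% CV), and the BSV
entries 0.0691/0.0598 as variances — together with the covariance 0.0292
they reproduce the reported random-effect correlation of 0.45 exactly,
which neither interpretation of 0.178 affects. The cobicistat effect is
carried on the parent clearance only; the metabolite's near-unity AUC
ratio under boosting at unchanged dose frequency follows structurally from
the fixed $f_m$.

## Regimens, simulation protocol and exposure metrics

Four dose levels are built in (`pk_regimen()`): DL1 80 mg QD monotherapy
(reference), DL2 80 mg QD boosted, DL3 80 mg 2 days on / 1 day off boosted
(72 h cycle), DL4 80 mg every other day boosted. `pk_simulate_cohort()`
gives every virtual subject a drug-naive run-in of 21 days (default) and
evaluates the final 144 h on a 0.25 h grid, with the window aligned to the
first cycle start at or after the run-in (for DL4 this is hour 528; 24, 48
and 72 all divide 144, so the window always covers whole cycles). AUC is
trapezoidal on that grid; $C_{max}$/$C_{min}$ are window extrema; outputs
are individual predictions without residual error. Virtual subjects sit at
the 70 kg reference weight by default: the reference-subject AUC
$6 \times 80/19 = 25.3$ mg/L·h matches the published DL1 median (25.0),
whereas the cohort's 78.5 kg median weight would not; a `"sampled"` weight
policy (log-normal, median 78.5 kg, 15% CV) is available.

`pk_crossover()` reuses the *same* random-effect vector per subject across
all regimens — a within-subject crossover with washout modeled as
independent run-ins. Consequences worth knowing: the within-subject AUC
ratios collapse to analytic constants
(DL2/DL1 $= 1/\theta_{cobi} = 1.4205$, DL3/DL1 metabolite $= 4/6$), and the
90% CIs of the GMRs are nearly degenerate. The published table reports
visibly wider CIs (e.g. 1.43 [1.40–1.46]), which is consistent with
random effects drawn per arm rather than per subject; the shared-eta
protocol is the stricter reading of a within-patient reference and is what
this package implements.

One known bias of the finite run-in: under the boosted 48 h cycle,
subjects in the low-clearance tail have not fully accumulated after 21
days, which depresses the DL4/DL1 AUC GMR by about $6\times10^{-4}$
relative to the exact steady-state value 0.7102 (the median-subject
metrics themselves are converged to ~0.1%). The run-in length is an
argument, and the tests document the residual discrepancy rather than
hiding it.

## Equivalence and the therapeutic window

`pk_gmr()` computes paired GMRs on the log scale with a normal-quantile
90% CI (`exp(mean r ± 1.645 sd(r)/√n)`); a subject-resampling bootstrap CI
is available since the source analysis does not state its CI method.
`pk_equivalence_verdict()` applies the EMA bioequivalence range 0.8–1.25
with closed bounds. `pk_window_assessment()` splits a (typically median)
steady-state profile against the provisional therapeutic window
125–259 µg/L into time fractions below/within/above, locating crossings by
linear interpolation so the fractions sum to one exactly.
`pk_cost_fraction()` is the dose-count ratio per unit time (2/3 for DL3 vs
DL1, i.e. a ~33% saving under flat pricing).

## Estimation

`pk_ofv_foce()` implements FOCE-I as a per-subject Laplace-type
approximation: the posterior mode $\hat\eta$ of the two random effects is
found by a damped Newton search on the penalized objective (tolerance
$10^{-8}$), with the proportional residual variance evaluated at the
*conditional* prediction (the interaction term; a non-interaction option
evaluates it at the population prediction). The integral is closed with
the Gauss–Newton curvature $M = G^\top R^{-1} G + \Omega^{-1}$, $G =
\partial f/\partial \eta$ at the mode, giving

$$
-2\log L_i \approx \sum_j\!\left[\log(2\pi R_j) + \frac{(y_j-f_j)^2}{R_j}\right]
 + \hat\eta^\top \Omega^{-1} \hat\eta + \log|\Omega| + \log|M|.
$$

Subjects without observations contribute zero; inner-search failures are
flagged and penalized finitely rather than aborting the fit.
`pk_ofv_quadrature()` is the validation oracle: adaptive Gauss–Hermite
quadrature (nodes centered at $\hat\eta$, scaled by $M^{-1/2}$,
$\geq 9$ nodes per dimension), exact in the node limit but restricted to
the two-effect model. On the sparse two-occasion design the two agree to
well under 1%.

`pk_fit()` maximizes the FOCE-I likelihood with `nlminb` over
log-transformed positive parameters and the log-Cholesky factor of
$\Omega$; $k_a$ and $f_m$ are fixed by default because the four sparse
windows per occasion cannot identify absorption — mirroring the source
analysis, which fixed $k_a = 0.24$ from literature and profiled it from
0.05 to 0.45 (`pk_ka_sensitivity()`). Warm-starting each inner search at
the previous outer iteration's modes makes the nested optimization cheap.
Standard errors come from the numerical Hessian on the transformed scale,
delta-mapped to the natural scale; the condition number is the eigenvalue
ratio of the *correlation* matrix of the free estimates (chosen over the
covariance for scale invariance, which the source does not specify).
Model-building decisions use the stepwise likelihood-ratio thresholds:
include at $\Delta\text{OFV} < -3.84$, retain on backward elimination only
if removal costs more than 6.63.

## Diagnostics

* **CWRES** — first-order expansion about $\hat\eta$, whole-subject
  decorrelation by the Cholesky factor of $G\Omega G^\top + R$.
* **pcVPC** — prediction-corrected observations and simulated replicates
  binned by time after dose (default edges 0, 0.5, 2, 5, 9, 24 h matching
  the sampling windows); bins with fewer than two observations merge
  leftward with a message; bands are the simulated 90% CIs of the
  5th/50th/95th percentiles.
* **NPDE** — per-subject decorrelation by the empirical simulation
  covariance, rank-based probabilities with half-rank ties, clamped to
  $[1/(2n_{sim}), 1-1/(2n_{sim})]$ so extreme observations map to finite
  quantiles; a ridge is added to singular covariances.
* **Bootstrap** — subject-level resampling at the original cohort size;
  failed or non-converged refits are counted and excluded from the
  2.5/50/97.5 percentiles, erroring only past 50% failures.
* **Shrinkage** — $\eta$: $100(1-\mathrm{SD}(\hat\eta)/\omega)$;
  $\varepsilon$: $100(1-\mathrm{SD}(\mathrm{IWRES}))$.

## The synthetic study generator

`pk_generate_cohort()` emulates the sparse boosting-study design: 11
subjects on 80 mg QD (doses and weights overridable, e.g. one 160 mg or
one 47 kg subject), weights log-normal with median 78.5 kg and 15% CV,
30 days of monotherapy before occasion-1 sampling, cobicistat added the
following day, and occasion-2 sampling after 21 boosted days. Each
occasion samples pre-dose (exactly at the dose time, before the dose) and
uniformly within 0.5–1.5, 2.5–3.5 and 7–8 h windows, both analytes —
11 × 2 × 4 = 88 sampling instances per analyte, read here as the natural
interpretation of the trial's "88 concentrations" per compound.
Proportional residual error is applied without lower-limit censoring;
negative simulated observations are retained. The latent random effects
are returned for recovery testing, and `pk_apply_screening()` reproduces
the trial's enrolment criterion (monotherapy steady-state trough
≤ 195 µg/L), which selects high-clearance subjects — the documented
selection bias of the source cohort. Datasets round-trip through a
NONMEM-style CSV (`ID, TIME, AMT, EVID, CMT, MDV, DV, DVID, WT, COBI,
OCC`, missing values as `.`), one row per subject–time–analyte with doses
as separate rows.

What the generator does *not* emulate: assay quantification limits,
adherence lapses, dropout, occasion-to-occasion variability beyond the
covariate switch, and real covariate correlations (weight is independent
of clearance beyond allometry). Passing recovery tests therefore
demonstrate internal consistency of estimator and simulator, not
robustness to those real-data features.

## Problem sizes used by the test suite

Monte-Carlo sizes are chosen to keep the default suite fast while leaving
the assertions at their scientific tolerances: parameter recovery averages
20 replicates of 50 subjects × 8 rich samples × 2 occasions; pcVPC
self-coverage and NPDE calibration use 20 replicates of the 11-subject
design with 300 and 200 simulations; bootstrap consistency uses 20–25
resamples of a 12-subject cohort with the weakly identified parameters
held fixed. The acceptance script simulates the published scenario at full
size (n = 1000 virtual subjects, 1000 crossover etas, four regimens).

## Known limitations

* The model is the two-clearance-BSV structure of the source analysis;
  the quadrature oracle is specific to two random effects (the FOCE path
  is dimension-generic in principle but untested beyond two).
* The GMR CIs under the shared-eta crossover are nearly degenerate (see
  above); equivalence verdicts are insensitive to this, but CI widths are
  not comparable to the published ones.
* Estimation assumes the proportional-error, log-normal-BSV observation
  model throughout; no combined or additive error option.
* The screening operation selects on the model-predicted (latent) trough,
  not on a noisy measured trough as a real enrolment would.
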