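---
title: "Methods: flip-flop pharmacokinetics and titration-period analysis of transdermal fentanyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flip-flop pharmacokinetics and titration-period analysis of transdermal fentanyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfent)
library(dplyr)
```

# The scientific problem

Transdermal fentanyl must be titrated carefully after initiation: the dose
is adjusted over days until pain is controlled without excessive rescue
medication. How long that takes is governed by the time to steady state,
which for a patch is *not* set by the drug's elimination half-life.
Diffusion through the stratum corneum is so slow that absorption becomes
rate-limiting — "flip-flop" kinetics — and the apparent half-life is
$\ln 2 / k_a$. Any comorbidity that alters the skin barrier (diabetes
mellitus is the motivating case: ceramide content of the stratum corneum is
reduced) can therefore change the titration timetable even when systemic
disposition is untouched.

`tdfent` implements both halves of that argument as a tested pipeline: a
pharmacokinetic arm that separates absorption from disposition in a
two-strain rat design (diabetic Goto-Kakizaki vs normoglycemic Wistar), and
a clinical arm that relates comorbidity indicators to a dichotomized
titration period in a patient cohort. Since the underlying raw data are not
publicly deposited, the package generates statistically faithful synthetic
versions of both, and every claim the package makes is demonstrated on
those.

# Pharmacokinetic arm

## Models

Two closed forms drive everything (`iv_bolus_concentration()`,
`bateman_concentration()`):

- IV bolus, one compartment: $C(t) = \frac{D}{V_d} e^{-k_e t}$, with $D$ in
  µg/kg and $V_d$ in L/kg so concentrations come out in ng/mL (µg/L).
- First-order absorption (Bateman), used for the patch:
  $$C(t) = \frac{F D k_a}{V_d (k_a - k_e)}\left(e^{-k_e t} - e^{-k_a t}\right),$$
  with $D$ the total applied amount (µg) and $V_d$ absolute (L). In the
  flip-flop regime ($k_a < k_e$) the terminal slope equals $k_a$.

**Patch-removal semantics.** The study design removes the patch at 24 h, but
the default model is *full-depot*: the entire absorbable amount $F D$
behaves as a first-order depot for all time and removal is ignored, because
$F$ — measured per animal from the AUC ratio — already absorbs whatever was
never delivered, and because observed concentrations at 30 and 48 h decline
slowly, as a continuing depot predicts. A *truncated-input* dialect
(absorption stops at removal; mono-exponential decay at $k_e$ from the state
at removal) is available on every fitting and simulation entry point for
sensitivity analysis. No absorption lag parameter is implemented: none is
reported for this system, and the 8-point schedule could not identify one.

**Degeneracy.** When $|k_a - k_e| < 10^{-8}\max(k_a,k_e)$ the code switches
to the analytic limit $C(t) = F D k t e^{-kt}/V_d$, so the curve and the
fitter are continuous across $k_a = k_e$.

## Moment analysis

`nca_iv()` / `nca_td()` perform model-independent (non-compartmental)
analysis:

- Terminal slope $\lambda_z$: OLS of $\log C$ on $t$ over the last
  `n_terminal` samples (default 3 — the selection rule of the original
  analysis software is unpublished, so the smallest admissible window is the
  declared default and the count is configurable). A non-declining tail
  (slope $\ge 0$ up to floating noise) is returned *flagged* and downstream
  parameters become `NA`; it is never silently accepted.
- AUC/AUMC: linear-up/log-down trapezoid (standard practice; pure-linear by
  `method = "linear"` for sensitivity), with exact exponential-interpolant
  moment integrals on log-down segments; tails $C_{last}/\lambda_z$ and
  $C_{last} t_{last}/\lambda_z + C_{last}/\lambda_z^2$.
- Origin: IV profiles back-extrapolate $C(0)$ log-linearly from the first
  two samples (first sample at 1 min); transdermal profiles start at
  $C(0)=0$. Interior zero concentrations fall back to linear segments;
  trailing zeros are truncated before the terminal fit.
- Parameters: $CL_{tot} = D/AUC$, $MRT = AUMC/AUC$,
  $V_{d,ss} = CL_{tot} \cdot MRT$, $k_e = \lambda_z$; transdermal
  $C_{max}/T_{max}$ by direct scan with the *earliest* time on ties, and
  $CL_{tot}/F = (D/\text{bw})/AUC$.

On dense noise-free profiles every recovered parameter agrees with the
generating value within 1% (tested); at the sparse 8-point transdermal
schedule the AUC extrapolation error is within 10% (tested), which is the
dominant error term carried into per-animal $F$.

## Absorption-rate fit

`fit_ka()` minimizes $\sum_i w_i (C_{obs,i} - C(t_i; k_a))^2$ over $k_a$
alone, bounded to $(10^{-5}, 10^2)$ 1/hr. The subject's $F$, $k_e$ and
absolute $V_d$ are fixed — per subject, not group means — because the
design identifies disposition from the IV arm and leaves exactly one free
absorption parameter. Numerical choices:

- Initial value from inverting the Bateman argmax relation
  $T_{max} = \ln(k_a/k_e)/(k_a-k_e)$ by bisection on the flip-flop branch
  ($k_a < k_e$), falling back to $k_e/10$ when the observed peak is earlier
  than $1/k_e$ (no slow-absorption root exists there).
- An 80-point log-spaced scan of the objective brackets the minimum, then
  golden-section refinement (`optimize`, tolerance $10^{-10}$) polishes it.
  The fit is fully deterministic; on noise-free data it returns the
  generating $k_a$ to $10^{-4}$ (tested across a 50-draw random parameter
  grid), and the objective is verified locally convex around the optimum.
- Weighting: uniform by default (the original software's scheme is
  unreported), $1/C$ and $1/C^2$ options; a log-concentration scale option
  exists. On noise-free data all schemes coincide (tested).
- An AUC-ratio $F$ estimate above 1 (possible under measurement noise) is
  accepted with a warning — the fit needs only the absorbable amount
  $F\,D$ — while the model functions themselves keep the physical
  constraint $0 < F \le 1$.

`flipflop_check()` reports the regime (strict $k_a < k_e$) and the apparent
half-life $\ln 2/\min(k_a, k_e)$.

## Bioavailability decomposition

$F$ divides each animal's dose-normalised transdermal AUC by the
**group-mean** dose-normalised IV AUC (the design's stated convention; a
per-animal option exists but is off by default). $F_a$ is the patch release
fraction from residual assays, $F_{skin} = F/F_a$ the skin availability.
Values above 1 are flagged with a warning, never clamped, so downstream
summaries remain honest about assay/sampling noise. Note that group means
of per-animal ratios differ from ratios of group means; the package
computes per-animal values and summarises afterwards, and its tests treat
published group means only as approximate anchors (within 5%).

# Clinical arm

## Titration rule

`titration_period()` returns the first day $T \ge 5$ ending a 5-day window
with (a) constant dose and (b) every day's rescue count $\le 3$
("within 3 times per day" is read inclusively; the strict-`<` reading is one
config value away). The all-days-in-window convention is the default
because it makes the minimum attainable period 5 days, matching the
observed range of 5–39 days; a `final_day` convention (ceiling applied only
on the qualifying day) is available. Records with no qualifying window are
*censored*: excluded from the two-group comparison with their count
reported. The implementation is a vectorised single pass over all patients;
the test suite checks it against an exhaustive window scan on 1,000 random
records.

## Screen and adjusted odds ratios

`dichotomize()` splits at $\ge 6$ days. `univariate_screen()` fits one
maximum-likelihood logistic regression per candidate factor (continuous
covariates untransformed, so odds ratios are per unit) and selects factors
with Wald $p < 0.1$; `multivariate_aor()` fits the joint model on complete
cases and reports $AOR = e^{\beta}$ with Wald 95% intervals
($e^{\beta \pm z_{0.975} SE}$) — the convention of the clinical statistics
software this mirrors — and applies no multiple-testing correction, as the
original procedure applies none. IRLS runs at tolerance $10^{-12}$ so score
equations hold to $<10^{-6}$ (tested); on a single binary predictor the OR
equals the 2×2 cross-ratio $ad/bc$ to $10^{-8}$ (tested). Separation
(non-finite or huge standard errors, zero cells) yields a flagged row and
the factor is barred from selection; zero-variance factors are skipped with
a warning. Firth-type penalisation is deliberately not applied, to match
the reference procedure.

# Synthetic data: what it emulates, and what it does not

## Virtual rats

`simulate_rat()` reproduces the study design: IV bolus 10 µg/kg sampled at
1–300 min; transdermal 160 µg sampled at 1–48 h with removal at 24 h;
5 animals per strain at study scale. Strain presets carry the reported
parameter means (Wistar $k_a = 0.0228$, $k_e = 0.279$, $V_{d,ss} = 6.49$,
$F = 53\%$, $F_a = 69\%$, bw 305 g; GK $k_a = 0.0317$, $k_e = 0.255$,
$V_{d,ss} = 6.94$, $F = 55.5\%$, $F_a = 78\%$, bw 339 g) and
between-animal CVs taken as the reported S.D./mean per parameter.
Between-animal variability is mean-preserving log-normal on $k_a$, clearance
and $F$, drawn independently (their true correlation is unknown);
measurement error is proportional log-normal with mean 1, CV 10% by
default. Patch residuals are $X_{used} = X_{unused}(1 - F_a(1+\epsilon))$
with Gaussian assay noise at the reported $F_a$ CV, truncated to the
physical range.

One deliberate internal-consistency choice: published summary tables report
terminal-slope $k_e$, moment $V_{d,ss}$ and AUC-based $CL_{tot}$ that need
not be jointly consistent (for these strains $CL_{tot} \ne k_e V_{d,ss}$ by
some margin, and the diabetic-strain mean $T_{max}$ of 4.8 h is earlier than
the Bateman argmax of its own mean rates, ~9.3 h). The simulator treats
$k_e$ and $V_{d,ss}$ as primary and uses $CL = k_e V_{d,ss}$ as the nominal
clearance, so simulated profiles are exactly self-consistent; recovery tests
therefore compare against *generating* values, and group-mean anchors are
used only where arithmetic forces them. Simulated profiles consequently do
not reproduce the published $T_{max}$ contrast between strains, and the
per-animal mean-of-ratios bioavailabilities of the real animals are not
reproducible at all from summary statistics — both are consistency-checked,
not matched.

## Virtual cohorts

`simulate_cohort()` draws $n = 387$ patients: gender Bernoulli (61.8% male);
age, height, BMI and serum albumin log-normal matched to published
median/IQR (66 [58–73] y, 162.3 [155.4–168.2] cm, 20.3 [18.3–22.5] kg/m²,
2.9 [2.4–3.4] g/dL) with weight derived from BMI and height and albumin
missing completely at random for 34/387; initial patch strength concentrated
at 1 mg. Comorbidity indicators are independent Bernoulli draws — no
correlation structure is published, and a correlation hook is the obvious
extension. Twelve codes carry outcome log-odds equal to the log of their
published multivariate AORs (E14 "unspecified diabetes" at its reported
17.1% prevalence, coefficient $\log 0.438$); three null codes (the type-2
DM code E11 at 2.8%, plus two common codes) verify that zero-coefficient
factors stay null. **Prevalences of the eleven rare selected codes are not
published as frequencies**; they were fixed once at values consistent with
each factor's univariate CI width (≈1% for the very wide intervals, 15% for
bone/bone-marrow metastasis) and are editable in the preset. The intercept
is calibrated per cohort on the realised linear predictors so the expected
long-titration fraction is exactly 126/387.

Daily records are built *constructively*: short-titration patients are
stable from day 1 (period 5); long-titration patients get a period
$6 + \text{Geom}(0.26)$ capped at 39 — a right-skewed tail echoing the
published period histogram qualitatively (no numbers were read off the
figure) — with rescue-ceiling violations on every day more than 5 days
before the qualifying day and an optional dose step at the final window's
start. The extraction rule provably returns exactly the generated period
(tested by brute force for every generated patient), so the generator and
the extractor cannot drift apart silently.

What passing tests do **not** show about real data: real comorbidities are
correlated and confounded with disease severity; real titration behaviour
includes dose decreases, holidays, and informative censoring; covariates
here do not influence the outcome (their published univariate ORs were
null); and the published cohort's own AOR/CI are single numbers from one
real dataset, reproducible only in distribution (the recovery experiment
below), not in value.

# Problem sizes and runtime choices

The test suite runs the study-scale designs everywhere: 5 animals per
strain, 8- and 9-point schedules, $n = 387$ cohorts. Dense-grid oracles use
200–400 points to 10 half-lives. The replicate AOR-recovery experiment uses
200 cohorts of $n = 387$ — enough for the geometric-mean AOR to stabilise
within a few percent (observed ≈ 0.42–0.43 against the generating 0.438
across seeds) and for Wald-CI coverage of the true coefficient to sit near
its nominal 95%. Marginal-fidelity checks use $n = 10^4$.

# Known limitations

- One-compartment disposition only; no metabolite kinetics, no lag time,
  no covariate-PK modelling.
- The absorption fitter estimates one parameter; it will not rescue a
  mis-specified $F$ or $k_e$, by design.
- Wald inference throughout; with very rare factors at $n = 387$ Wald
  intervals are wide and mildly anticonservative, and the screen's
  selection step is not accounted for in the multivariate intervals (the
  recovery experiment sidesteps this by always including the factor of
  interest).
- Comorbidity independence in the generator is a simplification; the
  preset accepts edited prevalences but correlated flags require the
  user-supplied hook.
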