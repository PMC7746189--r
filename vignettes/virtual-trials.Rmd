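---
title: "Simulating virtual clinical trials for closed-loop glucose control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating virtual clinical trials for closed-loop glucose control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

glucosim is an in-silico testbed for artificial-pancreas dosing algorithms
in type 1 diabetes. A dosing algorithm that implements a two-method
contract — `init(setup)` once, then `step(gs, meal_cho, t)` at every dosing
interval — can be run against a cohort of simulated patients under a
protocol that mirrors a clinical study: scheduled meals with day-to-day
variability, carbohydrate counting errors, starting-glucose spread, rescue
carbohydrates, and a full clinical outcome report at the end. This
vignette documents the model, the synthetic cohort, and the numerical and
design choices a user should know before trusting (or extending) results.

## The glucoregulatory model

Each virtual patient is a thirteen-state ODE system organised in seven
subsystems.

**Subcutaneous insulin absorption.** Infused insulin `ui` (U/min) splits
into a slow channel (fraction `pi`, two compartments with rates `kis1`,
`kis2`) and a fast channel (fraction `1 - pi`, two compartments sharing
`kif`):

    dQis1/dt = ui*pi - kis1*Qis1          dQif1/dt = ui*(1-pi) - kif*Qif1
    dQis2/dt = kis1*Qis1 - kis2*Qis2      dQif2/dt = kif*(Qif1 - Qif2)

**Plasma insulin kinetics.** One compartment with clearance `ke`,
background appearance `ci`, and a multiplicative piecewise-linear diurnal
factor `Im(t)` on the absorbed flux:

    dQi/dt = (kis2*Qis2 + kif*Qif2) * Im(t) - ke*Qi + ci

Plasma insulin concentration is `Ip = Qi / (Vi*w) * 1e6` mU/L with the
distribution volume fixed at `Vi = 190` ml/kg. As written, `Im(t)`
multiplies only the absorbed flux, not `ci`; we implement exactly that
(the background term is a constant source by definition).

**Insulin action.** Three first-order filters `dx_j/dt = ka_j*(Ip - x_j)`
produce the delayed (remote) insulin effects on glucose distribution
(`x1`), disposal (`x2`) and endogenous glucose production (`x3`).

**Glucagon absorption.** A two-compartment chain with shared time constant
`tgmax` (the time-to-peak of the impulse response, a property of the
Γ-shaped kernel `t·e^(-t/tgmax)`), and plasma concentration
`Cp = Qg2 / (tgmax*w*MCRg) * 1e6 + Cb`.

**Gut glucose absorption.** Each meal feeds two channels sharing rate
`km`, the second delayed by `d` minutes, letting double-peak absorption
profiles arise; `5551` µmol of glucose per gram of carbohydrate converts
grams to per-kg glucose flux, and a diurnal factor `fm(t)` modulates the
total. Integrated over time the channels return exactly the ingested
carbohydrate (a conservation law the tests verify).

**Plasma glucose.** Two compartments (accessible `Q1`, remote `Q2`, both
µmol/kg) with a saturating non-insulin-dependent utilization
`F01*(Q1/160)/(1 + Q1/160)`, insulin-dependent transport `x1*St*1e-4*Q1`
and disposal `x2*Sd*1e-4*Q2`, endogenous glucose production, a diurnal
additive flux `Fg(t)`, and the meal flux. EGP is glucagon-driven and
insulin-suppressed:

    EGP = Cp * Sg * max(0, 1 - x3*Se*1e-4)

The sensitivities `St`, `Sd`, `Se` are stored in their conventional
`1e-4`-scaled units. The printed form of the EGP switch ("zero once the
remote effect reaches 1") is dimensionally ambiguous because `x3` lives on
the mU/L scale while `Se` carries the `1e-4` factor; clamping the whole
suppression term at zero is the only reading that guarantees `EGP >= 0`
for all inputs, so that is what we implement.

**Interstitial glucose.** `dGs/dt = ks*(G - Gs)` with `G = Q1/V`; the
sensor reads `Gs`. `V` is stored in ml/kg so that µmol/kg divided by
ml/kg is µmol/ml = mmol/L with no extra constant — the units bridge is
exact, not approximate.

`km` is treated as a per-meal constant; intra-day variability of meal
absorption is carried entirely by `fm(t)`.

## Diurnal fluxes and variability

`Im`, `fm` (multiplicative, dimensionless) and `Fg` (additive,
µmol/kg/min) are continuous piecewise-linear interpolants over eight
equally spaced knots per 24 h, periodic at 1440 min. Inter-subject
variability enters through log-normal knot multipliers (median 1, log-SD
`flux_sigma = 0.15`); intra-patient day-to-day variability is modelled by
redrawing fresh multipliers (log-SD `flux_day_cv = 0.1`) for every
simulated day of a trial. Multiplicative fluxes are therefore positive by
construction. Eight knots resolve dawn/dusk-scale structure without
over-parameterising a quantity for which no knot layout is published.

## The synthetic cohort

No fitted per-patient parameter values are published for this model, so
the cohort generator defines the package's study conditions. Template
midpoints for the glucose and insulin-action subsystems follow the
established two-compartment glucose kinetics literature (`F01 = 9.7`
µmol/kg/min, `k12 = 0.066`/min, `St = 51.2`, `Sd = 8.2`, `Se = 520` in
`1e-4` units, `ke = 0.138`/min, `ka = 0.006/0.06/0.03`/min,
`V = 160` ml/kg, `ks = 0.066`/min, i.e. a ~15-min sensor lag); the
subcutaneous insulin chain (`kis1 = 0.01`, `kis2 = 0.015`, `kif = 0.03`
/min, `pi = 0.5`) gives absorption time scales of one to two hours; meals
use `km = 0.025`/min (40-min first peak), `d = 40` min, `pm = 0.7`.

The glucagon scale deserves a note: the model's glucagon "units", the mg
doses reported clinically, and the `1e6` factor in the plasma equation do
not pin down a single physical unit system. We adopt 1 mg = 1 model unit
and choose `Cb = 0.38`, `Sg = 49`, `MCRg = 13` jointly so that (a) basal
EGP lands near 11 µmol/kg/min at basal insulin and (b) a 0.02 mg
mini-bolus transiently raises EGP by roughly 10 µmol/kg/min — a 1–2
mmol/L glucose response, matching the clinical effect size of rescue
mini-boluses. Only the products `Cb*Sg` and `Sg/MCRg` matter to the
dynamics.

Strictly positive parameters are sampled log-normally around the template
midpoint (CV 0.15, redrawn into a three-fold validity range); the channel
fractions `pi`, `pm` use a truncated normal. Demographics (age 47 ± 12 y,
BMI 25 ± 3, HbA1c 7.5 ± 0.8%, duration 28 ± 12 y) are sampled to match
the baseline table of a mixed adult T1D cohort.

Each sampled patient's basal rate is then *titrated*: we solve the
fasting steady-state balance (EGP plus mean `Fg` against utilization) for
the plasma insulin level that holds glucose at 7 mmol/L and convert it to
an infusion rate through the insulin chain's steady state. This mirrors
clinical practice — pump basals are adjusted until fasting glucose holds —
and it is how the generator meets its behavioural validation: every
fixture patient held on their own basal stays within 4–12 mmol/L fasting
for 24 h (tested). The total daily dose is defined as twice the basal
(50% basal fraction) and the insulin-to-carbohydrate ratio by the 500
rule, `ICR = 500 / TDD`.

What the generator does **not** emulate: posterior correlations between
parameters of real fitted patients (draws are independent), CGM sensor
noise and drift (the sensor state is noise-free), exercise, and any claim
of quantitative correspondence to a specific clinical population. Passing
tests demonstrate internal correctness and plausible population-level
behaviour, not clinical validity.

## The trial engine

Time starts at 0 at trial start; clock times are converted to
minutes-from-start and diurnal fluxes are evaluated at clock time modulo
1440. Within each dosing step (default 10 min) the controller's returned
doses are applied as constant infusion rates — exact for the ODE, and the
natural reading of a per-step dose — and the model is integrated across
the step with `deSolve::lsoda` (rtol `1e-8`, atol `1e-10`). Accepted
states are checked for negativity: undershoot beyond 100·atol triggers
one retry at 100-fold tighter tolerance, then clamping with a warning;
sub-tolerance noise is clamped silently. The solver may probe marginally
negative states internally; the right-hand side evaluates the physics on
the non-negative part so undershoot cannot become a spurious source.

Every patient draws all of their randomness (meal schedule, starting
glucose, per-day flux multipliers) up front from a private stream keyed
by the trial seed and a stable hash of the patient id, which gives three
engine contracts: bit-identical reruns, independence from patient
execution order, and fault isolation — a controller exception or an
invalid dose (negative, non-finite, missing) marks only that patient's
run as `controller-failed at t=...` while the rest of the cohort
completes.

Protocol semantics settled here because no finer detail is published:
meals are announced to the controller at the step containing the
mealtime, with the *announced* (possibly mis-counted) grams, while the
model digests the *true* grams; the carbohydrate counting error is
uniform on ±20%, independent per meal, rounded to 1 g and kept inside
the ±20% envelope after rounding; rescue carbohydrates (16 g, default
threshold 3.3 mmol/L, 15-min lockout) are given when sensor glucose drops
below threshold and are never announced to the controller; non-dual arms
have no glucagon pump, so glucagon returns are recorded as zero there.

Three reference controllers cover the arms: open loop (constant basal
plus `announced/ICR` boluses), single hormone (the same boluses plus
glucose-responsive basal modulation — suspend below 4.5 mmol/L, halve
below 6, +50% above 10), and dual hormone (single-hormone insulin logic
plus a 0.02 mg glucagon mini-bolus below 4.8 mmol/L with a 60-min
lockout).

## Outcome metrics

Between-sample conventions are fixed so results reproduce bit-for-bit:
per-cent-time metrics attribute each sample to one sampling interval
(hence `%<4 + %[4,10] + %>10 = 100` exactly), while threshold AUCs treat
the trace as piecewise linear and interpolate threshold crossings exactly
(a crossing segment contributes a triangle). AUC units are mmol/L·min.
Hypoglycemia incidence counts excursions below 3.3 mmol/L and requires
recovery above threshold + 0.6 mmol/L before a new event (both 3.3 and
3.1 mmol/L exposure are reported, as both appear in clinical reports);
hyperglycemia incidence mirrors this above 10 mmol/L. Insulin delivery
is reported both as U/h and U/kg/day. The nocturnal sub-report uses a
23:00–07:00 clock window (configurable). Cohort aggregation reports
median, IQR, mean and SD over completed runs.

## Problem sizes and reproducibility

The canonical fixture is 15 patients, 24 h, 10-min dosing steps, four
meals (59/70/95/20 g at 08:00/12:00/17:00/21:00 with SDs matched to that
scenario's interquartile spreads), carb error on, starting glucose
7 ± 1 mmol/L — a size at which a full three-arm comparison runs in about
a minute on a laptop core. The test suite checks the linear subsystems
against an independent matrix-exponential oracle (100 randomized patients,
relative error < 1e-6 over 24 h), carbohydrate conservation (100 draws,
< 1%), glucagon peak timing (20 draws, within one output step of
`tgmax`), exact steady-state preloading, the worked metric examples, the
engine contracts on the 15-patient fixture, and the directional arm
ordering of hypoglycemia exposure (dual ≤ single ≤ open loop).

## Known limitations

Controller faults are caught per patient, but a controller that hangs is
not timed out. The sensor is ideal (no noise, dropout or calibration
drift). Exercise is not modelled. Open-loop rescue behaviour uses the
simple threshold rule above, not any manufacturer's pump manual. The
synthetic cohort stands in for unpublished fitted patients: comparisons
against published cohort-level numbers are qualitative.
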