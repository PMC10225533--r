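---
title: "Behavioral-economic demand analysis of operant self-administration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral-economic demand analysis of operant self-administration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(opdemand)
```

## The problem

In long-access drug self-administration experiments, a rat presses an
"active" lever to earn intravenous drug infusions under a fixed-ratio
(FR) schedule: FR *n* means *n* presses per infusion. Two questions
structure the analysis this package implements, modeled on a two-strain
(spontaneously hypertensive rat, SHR, an ADHD model, versus outbred
Wistar controls) adolescent nicotine study design:

1. **Acquisition** — did the animal come to self-administer at all?
2. **Demand** — for animals that acquired, how hard will they defend
   their intake as the behavioral price rises?

The second question is answered in behavioral-economic terms. Raising
the FR requirement day by day (3, 6, 9, 15, then doubling) while the
unit dose stays fixed raises the *unit price* `C = FR / dose`
(responses per mg/kg). Plotting consumption `Q` (mg/kg per session)
against `C` gives a demand curve.

## The demand model

The package fits the exponential demand equation of Hursh and
Silberberg:

$$\log_{10} Q = \log_{10} Q_0 + k\left(e^{-\alpha Q_0 C} - 1\right)$$

* `Q0` (mg/kg) — *demand intensity*, the model-predicted consumption at
  zero price.
* `alpha` — *demand elasticity*, the rate at which log consumption
  collapses with standardized price. Small `alpha` = inelastic demand =
  high reinforcing efficacy. Because `alpha` is strongly right-skewed
  across subjects it is compared between groups on the log10 scale.
* `k` (log10 units) — the range of the demand function: consumption
  spans `Q0` down to `Q0·10^{-k}`. It is a *shared* constant (fit
  globally, or fixed at a published value such as 2.218) so that
  `alpha` is comparable across subjects and groups.

Two derived indices summarize each fitted curve. `Pmax` is the unit
price at which the curve's point elasticity
$d\log_{10}Q/d\log_{10}C$ equals −1, the transition from inelastic to
elastic demand; writing `u = alpha·Q0·C`, the condition reduces to
`u e^{-u} = 1/(k ln 10)`, solved by the principal Lambert-W branch
(implemented in-package with a Halley iteration, since the installed
stack has no Lambert W). `Omax = Pmax · Q(Pmax)` is the peak
expenditure — the maximum responses per session the animal will emit —
and is attained exactly at `Pmax`; note `Omax·alpha` is constant at
fixed `k`. `pmax_approx()` additionally reproduces the analytic
approximation `(0.084k + 0.65)/(Q0·alpha·k^{1.5})` used by the legacy
spreadsheet template that circulates in this field; it tracks the exact
root to within 5% for `k` in roughly [1.7, 4] and degrades below that,
so `pmax_exact()` is canonical.

```{r}
ref <- reference_demand_parameters()
head(ref, 3)
# derived indices from the published best-fit parameters
round(omax(ref$q0[1], ref$alpha[1], 2.218), 1)      # subject 1
round(pmax_exact(1.45, 0.000161, 2.218), 1)         # subject 16
```

### Fitting choices

The loss is squared error on **log10 consumption**, the scale on which
the model is stated and on which the zero-replacement rule (below) is
justified. The surface has local minima in `alpha`, so `fit_demand()`
is multi-start: `Q0` starts at the maximum observed consumption and
`alpha` on a log grid from 1e-5 to 1e-2, each polished by L-BFGS-B with
an analytic gradient in `(log10 Q0, log alpha)` coordinates. `alpha` is
bounded in [1e-8, 1]; a solution at the boundary (near-constant
consumption carries no information about elasticity) is flagged
`boundary = TRUE` and should be treated as low confidence; its `r2` is
`NA` when the series has zero variance. Noise-free series are recovered
to better than 1e-6 relative error, which the tests assert.

`fit_shared_k()` estimates one `k` jointly across subjects by
profiling: at fixed `k` the per-subject problems separate, so
`SSE(k) = \sum_i \min_{Q0_i,\alpha_i} SSE_i(k)` is minimized over
`k ∈ [0.5, 6]` by golden-section search. Refitting any subject at the
returned `k` reproduces its parameters by construction.

### Zero handling

A demand phase ends at the first session with 0 infusions. Zero is
undefined on the log scale, so that terminal observation is replaced by
0.01 mg/kg — one log-unit below a single infusion at the 0.03 mg/kg
unit dose (log10 0.03 ≈ −1.52, log10 0.01 = −2) — flagged
`replaced_zero`, and **included** in the individual fit: it completes
the demand function. An *interior* zero violates the stopping rule and
is rejected as a data error.

Group-level curves use a second, illustration-only device: each
subject's 0.01 is carried forward from its termination price to the
highest price any subject reached, so early terminators keep pulling
the group mean down (`group_demand_curve()`). These padded points never
enter individual fits or statistics; the contract is tested.

## Acquisition classification

Acquisition is a two-part criterion evaluated on trailing 3-session
windows from session 3 of the 14-session acquisition phase (7 FR 1 + 7
FR 2; windows may span the FR transition because the phase is analyzed
as one sequence):

1. mean active ≥ 2 × mean inactive lever presses, with some active
   responding (the 2:1 boundary is inclusive; 0 vs 0 is not
   discrimination), **and**
2. mean infusions strictly above the upper bound of the saline
   controls' 95% CI over the same window.

The CI is a t-interval on the mean of per-subject 3-session means —
the conventional construction, since the source design does not name
one — and is strain-matched by default (both strains carry saline
groups; pooling is available). "Above the CI" is read strictly:
touching the bound does not count. Windows without an evaluable saline
reference yield `not_evaluable` rather than a guess.

Subjects that never meet the full criterion but earn substantial intake
can still be counted as acquired if they meet the 2:1 criterion during
the demand phase (`demand_phase_recheck()`); intake above saline is
already evidenced there by earning infusions at escalating prices.

Per-session group proportions use the cumulative convention (once met,
met thereafter — matching the monotone published acquisition curves); a
per-window mode is available behind `cumulative = FALSE`. Final-session
proportions are compared between strains with Fisher's exact test at
the Bonferroni-corrected threshold 0.05/2 = 0.025 (one test per FR
phase).

## The synthetic cohort generator

No raw data accompany the source design, so `simulate_cohort()`
generates cohorts with its structure: group sizes Wistar/SHR ×
{30, 4, 0 µg/kg} of 20/27, 12/10, 8/12; 14 acquisition sessions; demand
phase for responders at 30 µg/kg escalating 3, 6, 9, 15, 30, … until a
zero-infusion session.

Defaults are fixed once, as the stated world of the tests:

* **Counts** are negative-binomial (size 20 at means of 12–60; the
  Poisson limit `size = Inf` is supported): daily operant counts are
  overdispersed, but 23-h session totals aggregate many bouts, so the
  overdispersion is moderate. The design reports no count variances;
  these are plausibility choices, config-exposed.
* **Responders** press the active lever at mean 60/day; non-responders
  and saline controls press both levers at mean 12 — equal means,
  because saline and sub-threshold groups show no lever discrimination
  in the emulated design. Session 1 (food-baited in the source
  protocol) is an ordinary FR 1 session with an optional additive
  boost, since no quantitative effect is reported.
* **Infusions** are the ratio completions implied by the active count
  and FR, optionally thinned by a configurable timeout-loss fraction
  (default 0; event-level timeout simulation is out of scope).
* **Demand consumption** follows the exponential model with
  multiplicative lognormal noise (`infusions = round(Q·e^ε/dose)`,
  ε mean-zero with SD implied by the CV). Default CV 0.25 reproduces
  the published per-subject r² range (~0.65–0.99); group true
  parameters default to the published strain means (Wistar Q0 1.94,
  alpha 4.59e-4; SHR 1.45, 5.45e-4; k = 2.218) with lognormal
  between-subject spread (sdlog 0.3 for Q0, 0.6 for alpha, matching the
  printed table's spread).

Two numerical edges deserve note. First, the exponential model never
actually reaches zero: its floor is `Q0·10^{-k}`, and when that floor
exceeds half an infusion (Q0 above ≈2.5 mg/kg at a 0.03 mg/kg dose and
k = 2.218) the rounded realization can only hit zero through a lucky
noise draw. Real animals stop anyway — behavior leaves the model at
extreme prices — but the generator has no extinction mechanism, so
subject-level Q0 draws are truncated at `0.7·dose·10^k` (≈3.5 mg/kg),
above the published per-subject range, and a subject that exhausts the
ladder is retried on an extended one. `simulate_demand_phase()` itself
errors with advice when its ladder is exhausted, as a single-subject
call should. Second, with rounding enabled the terminal sessions carry
1–2 infusions, and that granularity dominates recovery error for `Q0`:
at noise CV 0.1 the median relative recovery error is ≈10.7% for `Q0`
(≈5% for log-scale `alpha`), while with rounding disabled both recover
to ≈5% and ≈2.5%. The acceptance suite asserts the rounded world and
documents this miss rather than relaxing it.

What a green simulation test does **not** establish: the generator has
no pharmacokinetics, no within-session time course, no body-weight
growth, no satiation structure, and its false-acquisition rate
(~5–15% for drug-free groups, driven by the 12-window multiplicity of
the criterion) is a property of the classifier, not of rats.

## Strain comparison

Fitted indices are compared between strains with Welch's
unequal-variance t-tests (`welch_t()`, `compare_all_parameters()`):
log10 alpha, Q0, Pmax, Omax; sexes pooled for the strain contrast with
descriptive within-strain sex contrasts, and no multiplicity correction
across the four measures — mirroring the reporting conventions of the
emulated analysis. On the published parameter table the package
reproduces the headline null result:

```{r}
cmp <- compare_all_parameters(ref)
subset(cmp, contrast == "strain", select = c(measure, t, df, p))
```

## Pipeline

`run_pipeline()` chains simulate → acquire → demand → compare, writes
`sessions.csv`, `acquisition.csv`, `parameters.csv` (with recomputed
stratum mean/SEM rows), `comparisons.csv` and a flat key-value
manifest, and is deterministic given configuration and seed. Only
acquired subjects enter demand fitting; subjects with demand data but
no acquired status, or acquired subjects missing demand data, are
reported, not dropped silently. A thin command-line wrapper is
installed at `inst/scripts/opdemand.R`.

```{r}
out <- file.path(tempdir(), "demo-run")
manifest <- run_pipeline(config = simulation_config(seed = 7),
                         out_dir = out, verbose = FALSE)
manifest[c("n_subjects", "n_acquired", "n_parameters", "k")]
```

## Known limitations

* Only the exponential demand model is implemented (no linear
  elasticity, zero-bounded variants, or inverse-hyperbolic-sine
  transforms), and no essential-value or cross-price analyses.
* The published table's Pmax column is matched only to ~1%: its source
  spreadsheet used its own solver and an analytic approximation, and a
  few printed cells (the Wistar alpha/Pmax means, the overall rows)
  are not arithmetic means of the printed individual values. The
  package recomputes summaries from data and does not try to reproduce
  those cells.
* Session-level aggregates only: no event timestamps or infusion-pump
  logs.
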