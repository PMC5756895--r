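---
title: "Methods: convolution-based integral projection models of insect phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convolution-based integral projection models of insect phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoipm)
```

## The model

`phenoipm` simulates stage- and age-structured insect demography under
daily temperature forcing. The state variable of each life stage is the
density $x_i(a)$ of individuals over *physiological age* $a$ — accumulated
development, not time since birth — on day $i$. Development is stochastic
at the individual level: on a day with mean temperature $T_i$, an
individual in stage $s$ accrues a log-normal increment

$$\Delta A \sim \mathrm{LN}\!\left(\mu = \ln(r_s[T_i]\,\Delta t),\ \sigma_s^2\right),$$

whose median is exactly the classical rate-summation step
$r_s[T_i]\,\Delta t$. Because the sum of independent increments has the
density given by convolving their densities, the population-level
consequence of this stochastic process is deterministic: one day of
development maps the age distribution through

$$x_{i+1}(b) = (1 - m_i)\int_0^{\gamma_s} x_i(a)\,k_i(b-a)\,da,$$

with $k_i$ the increment density and $m_i$ a temperature-dependent daily
mortality probability. Mass reaching the maturation threshold $\gamma_s$
(canonically 1) is transferred to the next stage as a point mass at age
zero — individuals do not retain surplus development across a moult, and
they never skip a stage (a warning flags forcing so extreme that the
median daily increment exceeds $\gamma_s/2$). All individuals start as a
Dirac mass at age zero (all mass in the first grid cell).

Three model variants share this machinery:

* `simulate_ipm()` — the fine-grid integral projection model (128 age bins
  per stage by default);
* `simulate_cohort()` — the identical algorithm at 16 bins, i.e. the
  classical coarse cohort model; at 128 bins it is bit-identical to the
  IPM;
* `simulate_ibm()` — the stochastic individual-based model the IPM
  represents: fresh per-individual, per-day log-normal draws, threshold
  maturation, replicated under a master seed.

The modelling assumptions worth stating explicitly: demography is
age-independent *within* a stage (rates and mortality depend on stage,
temperature, and date only); daily increments are independent between days
and individuals (no persistent "fast" or "slow" phenotypes — a fixed
individual deviate would break the convolution representation); and the
life cycle is open (no reproduction feeding back into the egg stage).

## Temperature channels and the beetle application

Each day carries three channels, used by different processes:

| process | channel | rule |
|---|---|---|
| development | `tmean` | stage rate curve $r_s[T]$ |
| cold mortality | `tmin` | step: death iff `tmin` strictly below −18 °C |
| adult flight | `tmax` | flight iff `tmax` strictly above 18.3 °C |

The bundled mountain pine beetle life cycle
(`inst/extdata/mpb_life_cycle.yaml`) wires the cold step to egg, pupa,
teneral adult, and adult; the four larval instars cold-harden and carry no
mortality rule. Both boundary cases are deliberately strict inequalities:
a day at exactly −18 °C kills nothing and a day at exactly 18.3 °C flies
nobody, since the defining observations are worded as "below"/"exceeds".
Emerged, flying, and settled adults are scalar pools outside the staged
populations and are not exposed to the cold rule; settling removes a
fraction $1-\exp(-\lambda\,\Delta t)$ of the flying pool per day. The
settling rate default ($\lambda = \ln 2/3\ \mathrm{d}^{-1}$, a three-day
flight half-life) and the per-stage rate-curve parameters are
**illustrative**: they are chosen once to give field-realistic stage
durations (egg ≈ 10 d at 20 °C, fourth instar slowest, one-year
voltinism under montane forcing) and are not fitted to rearing data.
Users with fitted parameters supply their own YAML file.

Rate curves come in two families. `linear_degree_day` is
$\max(0, \text{slope}\,(T - T_\text{base}))$. `hump_nonlinear` is a
Logan-type curve,
$\psi\{\exp[\rho(T-T_b)] - \exp[\rho(T_m-T_b) - (T_m-T)/\delta]\}$ on
$(T_b, T_m)$ and zero outside: exponential rise from the base, collapse at
the upper threshold $T_m$. Rates at or below `clip_floor`
($10^{-8}\,\mathrm{d}^{-1}$) are treated as exactly zero development,
since $\ln(r\Delta t)$ is undefined at zero and development biologically
halts in cold; the kernel then degenerates to the identity.

## Numerical choices

**Grid.** Ages live on a uniform lattice $0, h, 2h, \dots$ with
$h = a_\text{max}/n_\text{bins}$; the cell around lattice point $jh$ spans
$[(j-\tfrac12)h, (j+\tfrac12)h)$. $a_\text{max}$ defaults to $4\gamma$;
mass convolved beyond it accumulates in an explicit overflow register —
never silently lost — and counts as matured at the next threshold split
(it exceeds $\gamma$ by construction). Centred cells rather than
left-edge cells matter: left-edge attribution drifts by $+h/2$ per
convolution, which after $n$ steps displaces the whole distribution by
$nh/2$; centred cells are $O(h^2)$ per step.

**Kernel.** Cell masses are log-normal CDF differences across cell edges
(exact cell probabilities), the beyond-grid tail is folded into the last
cell, and the kernel is renormalized to sum to exactly one. A
*mean-preserving fractional shift* is then applied: the kernel's discrete
mean is matched to the analytic mean $e^{\mu + \sigma^2/2}$ by moving the
residual sub-cell fraction of mass one cell up (or down). Without this
step, increments smaller than $h/2$ round to the zero-aging cell, so
development stalls on cool days — and stalls entirely on the 16-bin cohort
grid, whose cell width (0.25 age units) exceeds typical daily increments
several-fold. With it, expected age obeys rate summation exactly at every
resolution, and the coarse-grid limit reduces to the classical fractional
cohort-transfer (upwind) rule. The cost is a small variance inflation,
at most $h^2/4$ per step, which vanishes under grid refinement. A
$\sigma = 0$ specification produces the analogous deterministic two-point
kernel. A warning (`phenoipm_coarse_kernel`, summarized once per
simulation) flags days on which ≥ 99% of the raw kernel mass falls in one
cell: the grid is then too coarse to resolve the *variability*, though the
mean remains exact.

**Convolution.** Full linear convolution via zero-padded FFT
(`stats::convolve`, output length $2n-1$; no circular wraparound). FFT
ringing can produce tiny negative masses; values within
$10^{-12}\times\max(1, \text{total mass})$ of zero are clamped (the
tolerance scales with mass because round-off does), anything more negative
is a hard error.

**Threshold split.** Lattice cells whose *centre* reaches $\gamma$ count
as crossed, plus the overflow. When $\gamma$ is not a lattice point, the
cell containing it is assigned wholly to the crossed side — a
deterministic, conservative tie-break (documented so users can align
grids; the default grids place $\gamma$ on the lattice). This convention
carries an $O(h)$ early-crossing bias of about $x(\gamma)h/2$ per
crossing, which compounds over linked stages; analyses that compare
against stochastic replicates at tight tolerances should use fine grids
(the package's own equivalence checks use $h \approx 10^{-3}$).

**Maturation boundary.** Reaching the threshold counts as completion
(`age >= gamma` within $10^{-12}$), in both the IBM and the IPM split. The
strict-inequality alternative differs only on a measure-zero event for
$\sigma > 0$ but is ill-behaved in floating point in the deterministic
limit: ten exact increments of 0.1 sum to just under 1, so a strict rule
would complete on step 11 rather than the rate-summation day
$\gamma/(r\Delta t) = 10$.

**Within-step order.** Age (convolve) → kill ($1-m$) → split at $\gamma$ →
recruit at age zero. Recruits are not aged or killed again within their
entry step; they face mortality from the next day. The IBM applies the
same order per individual (draw → mortality by the stage occupied during
the step → advance), so the two models agree on mortality days as well.

**Recruitment bookkeeping.** The default "truncation" form takes each
step's crossed mass directly from the split. The "difference" form
implements the stage-linkage equations literally: an untruncated copy of
each stage's distribution is advanced in parallel and recruitment is the
per-step increase of its cumulative above-threshold mass. Because aging
increments are nonnegative, mass never re-crosses the threshold, and the
two forms agree to FFT round-off ($<10^{-10}$ on a 30-day three-stage
run) whenever mortality does not differ across the threshold; the
difference form is provided as a semantic cross-check, not for production
runs with stage-specific mortality.

## The synthetic forcing generator

`generate_synthetic_series()` produces daily `tmin`/`tmean`/`tmax` as a
sinusoidal seasonal cycle plus stationary AR(1) anomalies, with a constant
diurnal half-range on either side of the mean. The defaults emulate a cool
montane valley of the kind the beetle application targets: annual mean
4 °C, half-amplitude 13 °C peaking on day-of-year 200, 10 °C diurnal
range, anomaly SD 3 °C with lag-1 autocorrelation 0.6, over the 443-day
window from 15 July to 30 September of the following year (one full
beetle life cycle). Under these conditions winters occasionally dip below
−18 °C — so the cold rule is exercised — while summer maxima exceed the
18.3 °C flight threshold.

What the generator deliberately does *not* emulate: weather fronts and
skewed anomaly distributions, varying diurnal range (cloud cover), the
air-to-bark temperature transformation (available separately as
`affine_bark_transform()`, identity by default, since the mechanistic bark
energy balance is out of scope), and spatial interpolation between
stations. Tests passing under synthetic forcing therefore demonstrate the
*internal* consistency of the engine — IPM = IBM mean, resolution
convergence, conservation — not the field accuracy of any particular
parameter set.

## Validation statistics

Flight predictions are compared to trap catches via the two-sample
Kolmogorov–Smirnov test on weighted ECDFs aligned over the union of dates.
Counts are always frequency weights in the ECDF (each trapped beetle is
one observation); the sample size entering the asymptotic p-value
(effective $n = n_1 n_2/(n_1+n_2)$, Kolmogorov tail series) follows either
the `records` convention (number of rows in the series, the convention
used when quoting trap-validation sample sizes) or the `counts` convention
(total insects), selected by a flag — the literature is ambiguous on which
was intended, so both are explicit. The statistic $D$ itself is
convention-free and is verified exhaustively against a brute-force ECDF
oracle on all weighted samples of size ≤ 8. The asymptotic (not exact)
p-value is used throughout; the validation verdict is positive when
$p > 0.05$.

## Problem sizes used by the test suite

The checks bundled with the package run at sizes chosen to keep the full
suite under a minute of compute while leaving comfortable statistical
margins: kernel normalization over 1,000 random parameterizations;
Monte-Carlo comparison of the ten-fold convolved age distribution against
$10^5$ sums of ten log-normal draws (KS distance held below the 1%
critical value $1.628/\sqrt{n}$); IBM-vs-IPM mean-occupancy coverage with
500 replicates of 100 individuals on single-stage and three-stage
scenarios at $h \approx 10^{-3}$ (≥ 95% of day × stage cells within three
binomial standard errors); and the full 443-day eight-stage reference year
at 16–128 bins for the resolution sweep.

## Known limitations

* No reproduction, mating, or multi-year voltinism loop: one life cycle
  per run, initialized by an egg-introduction schedule.
* No density dependence; mortality is exogenous.
* No larval cold mortality — deliberately, since the interaction between
  cold-hardening and development remains unresolved; winter larval kill is
  therefore *under*-estimated.
* One-bin-per-day kernels assume the forcing is piecewise constant over
  $\Delta t$; sub-daily temperature excursions below thresholds are
  invisible at daily resolution.
* The fractional mean-preserving shift trades a small variance inflation
  (≤ $h^2/4$ per step) for exact mean transport; on very coarse grids the
  cohort model consequently over-disperses rather than stalls.
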