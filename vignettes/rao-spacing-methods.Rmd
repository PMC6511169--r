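---
title: "Rao's spacing test on rounded circular data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rao's spacing test on rounded circular data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raospace)
```

## The statistic and its null model

For angles $\phi_1 \le \dots \le \phi_n$ on $[0, 2\pi)$ the neighbour
arcs are $T_i = \phi_{i+1} - \phi_i$ for $i < n$ and
$T_n = 2\pi - \phi_n + \phi_1$, and Rao's statistic is

$$U = \tfrac12 \sum_{i=1}^n \left| T_i - \frac{2\pi}{n} \right|.$$

Under uniformity every arc has expectation $2\pi/n$, so $U$ measures
total departure from equal spacing without assuming any particular
alternative shape (unlike the Rayleigh test, which targets unimodal von
Mises alternatives). $U = 0$ exactly at perfect equal spacing and
reaches its maximum $2\pi(n-1)/n$ when all points coincide. $U$ is
invariant to rotation and reflection of the circle and to the input
order; ties are legal and produce zero arcs — they are precisely the
phenomenon the rounded-data variant addresses, so the package never
deduplicates.

All angles are stored internally in radians on $[0, 2\pi)$; degrees
exist only at the I/O boundary and in the critical-value comparison.
Input must lie in $[-4\pi, 6\pi)$ radians or $[-720, 1080)$ degrees;
anything outside is rejected rather than wrapped, because a silently
wrapped unit mistake (degrees read as radians) is worse than an error.
The unit is always an explicit argument — 350 is a legal value in
either unit, so detection heuristics are unsafe.

## Three test variants

**Traditional.** $U$ in degrees is compared against the Russell &
Levitin (1995) table, shipped as a plain CSV
(`inst/extdata/rao_critical_values.csv`) covering $n = 4\dots30$, then
35, 40, 45, 50, 75, 100, 150, 200, 300, …, 1000, at levels 0.001, 0.01,
0.05, 0.10. Because only grid levels are tabulated, the p-value is
reported as a bracket. For $n > 30$ between tabulated rows the critical
value is interpolated linearly in $n$, the convention of existing
implementations. The published source lists further levels; the four
embedded here are the ones in universal use, and the transcription is
cross-validated in the test suite by simulating the null distribution
of $U$ and checking the tail quantiles against the table (200,000
resamples reproduce the cells to ~0.1–0.5°). One quirk the validation
confirmed: the 0.10-level critical value rises from $n=4$ to $n=5$
before decreasing — a genuine small-sample discreteness effect, not a
transcription error.

**Continuous Monte Carlo.** The observed $U_o$ is compared against $U$
from $N_R$ uniform resamples of the same $n$; with $N_e$ the number of
null statistics $\ge U_o$ (ties count as exceedances, the conservative
choice), the p-value is the bias-corrected $(N_e+1)/(N_R+1)$, bounded
below by $1/(N_R+1)$ and never zero. Default $N_R = 10{,}000$.

**Rounded-data randomization.** Rounding to $m$ equal bins makes the
continuous critical values invalid: ties shrink spacings to zero and
inflate $U$. The fix makes the null resamples *look like the data*:
(i) the observed (grid) sample is jittered once with i.i.d. von
Mises$(0, \kappa)$ perturbations and wrapped, giving $U_o$; (ii) each
uniform resample is rounded to the same $m$-bin grid, jittered with
fresh perturbations, wrapped, and scored; (iii) the same
$(N_e+1)/(N_R+1)$ rule applies. The observed sample is perturbed
exactly once — no averaging over repeated jitters — which adds a small
random component to the reported p-value; that variance is the price of
the published algorithm's simplicity, and it is dominated by the
Monte Carlo error at the default $N_R$. Null draws are continuous
uniform *then rounded*, which is equivalent to equiprobable bins but
mirrors how real rounded data arises.

Rounding uses nearest-multiple with halves away from zero, and a value
that rounds to $2\pi$ wraps to 0; the half rule is measure-zero for
continuous draws and fixed only for reproducibility. A sample supplied
off its declared grid is rounded with a warning (or refused with
`strict = TRUE`): silent repair would hide a likely misdeclared `n_bins`.

## Parameters

* `n_resamples` ($N_R$, default 10,000): Monte Carlo resolution; the
  smallest attainable p is $1/(N_R+1)$.
* `kappa` ($\kappa$, default 1000): perturbation concentration, in the
  von Mises sense; large-$\kappa$ circular SD is $\kappa^{-1/2}$
  (≈ 0.0316 rad ≈ 1.81° at the default). The perturbation must sit well
  below the bin width, so the package warns whenever $\kappa^{-1/2}$
  exceeds 10 % of $2\pi/m$ — which the default itself triggers for
  $m \ge 36$. The default is kept because it is the value in the
  literature and the test's validity only requires observed and null
  samples to be perturbed identically (the calibration checks below run
  at exactly these settings); users who want jitter strictly below the
  granularity should raise $\kappa$ (e.g. $10^4$–$10^5$ for 10° bins).
* `seed`: every stochastic entry point accepts a seed, saves and
  restores the caller's RNG state, and is bit-reproducible. All
  samplers and the resampling loops draw from R's global RNG stream
  (the compiled loops use R's own `unif_rand`), so one seed governs
  everything.

## The samplers and what the synthetic data does not emulate

The study harness generates its own data: circular uniform draws; von
Mises$(\mu, \kappa)$ via the Best–Fisher rejection sampler (validated in
the tests against the mean-resultant-length identity
$\bar R = I_1(\kappa)/I_0(\kappa)$ and the KS test at $\kappa = 0$); and
a wrapped skew-normal — linear draws by the two-normal representation
($\delta = \alpha/\sqrt{1+\alpha^2}$,
$X = \varepsilon + \omega(\delta|Z_0| + \sqrt{1-\delta^2}Z_1)$),
validated against the closed-form skewness, then reduced modulo $2\pi$.
Wrapping is applied explicitly because with $\omega = 2$ rad a
non-negligible mass crosses the boundary; $\varepsilon$ and $\omega$
are radian-valued like every other location/scale here. These
generators emulate idealized measurement: independent draws, exact
rounding to a perfect grid, no heaping on "round" directions (N, E, S,
W), no serial correlation between successive animals or trials, and no
measurement error beyond the grid itself. Passing calibration on them
shows the tests are correct *for grouped data per se*, not that any
particular field protocol is free of those further artefacts.

## The simulation study

`rejection_rate()` draws `replicates` datasets from a configured
distribution, optionally rounds them, applies one test variant, and
reports the rejection fraction with its binomial standard error
$\sqrt{r(1-r)/\text{replicates}}$. Two conventions are implemented
literally: type I error counts $p < \alpha$ (uniform data) while power
counts $p \le \alpha$ (non-uniform data). The asymmetry matters for the
simulation tests, whose p-values are exact fractions that can equal a
round $\alpha$. The traditional variant decides by $U$ exceeding the
critical value, where the two conventions coincide almost surely.

The package's own calibration runs (the acceptance tests and
`scripts/acceptance.R`) use 2,000 replicate datasets with
$N_R = 2{,}000$ for the continuous simulation test at $n = 50$, 10,000
replicates for the traditional-test conditions, and 1,000 replicates
with $N_R = 2{,}000$ for the randomization test at $n = 100$ with 36
bins — sizes chosen so the whole study reruns from scratch in about a
minute on one CPU while keeping the binomial SE of each rate near
$0.005$ or better. The full-scale design (10,000 replicates with
$N_R = 10{,}000$) is available behind `--full-scale` in the CLI's
`study` subcommand. The sample-size grid for study curves defaults to
$\{10, 20, 30, 50, 100\}$, anchored at the sizes where the behaviour
changes qualitatively; the traditional variant is restricted to
$4 \le n \le 1000$ by its table.

## Numerical and design choices

* Exceedance uses $\ge$ so that exact ties with $U_o$ count toward
  $N_e$; with perturbed statistics ties are measure-zero, but the rule
  is kept for the unperturbed boundary cases (e.g. $U_o = 0$, where
  $p = 1$ exactly).
* The discrete null for tiny cases can be enumerated exactly
  ($m^n$ equiprobable assignments); the test suite checks the
  Monte Carlo null against this enumeration at $n = 4$, $m = 6$.
* Sorting is stable and tie order is irrelevant to $U$, so no
  tie-breaking rule exists anywhere.
* Angle wrapping in compiled code uses a floor-based reduction rather
  than `fmod` for portability across C libraries.
* `p_from_counts()` is exposed separately so the p-value rule is
  testable in isolation and reusable for other randomization statistics.

## Known limitations

* The critical-value table carries only the four standard levels;
  p-values from the traditional test are brackets, not points. For a
  point p-value use the simulation tests.
* The randomization test's p-value inherits jitter from the single
  perturbation of the observed sample; at default settings this is
  small relative to Monte Carlo error, but it means two analysts with
  different seeds can report slightly different p-values for the same
  rounded data.
* Axial data (where $\theta$ and $\theta + \pi$ are equivalent),
  weighted observations, and unequal bin widths are out of scope; the
  grid must consist of equal divisions of the circle.
* For $n$ between tabulated rows the linear-in-$n$ interpolation of
  critical values is a convention, accurate to well within the table's
  own Monte Carlo precision for the gaps involved, but still an
  approximation.
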