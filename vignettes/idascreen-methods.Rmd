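---
title: "Predicting drug-combination efficacy from monotherapy screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-combination efficacy from monotherapy screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idascreen)
```

# The problem

Experimentally screening cancer drug combinations is infeasible at scale:
the space of two-drug combinations of clinically advanced compounds runs to
hundreds of thousands, and three-drug combinations to hundreds of millions.
Monotherapy viability screens (CTRPv2, GDSC, NCI-ALMANAC and the like),
by contrast, already cover hundreds of compounds across hundreds of cell
lines. `idascreen` turns those monotherapy measurements into combination
efficacy predictions under *independent drug action* (IDA): the hypothesis
that a combination's effect on a given cell line (or patient) equals the
effect of its single most effective constituent drug. IDA deliberately
assumes away synergy; its appeal is that it needs no combination training
data and that independent evidence suggests many clinical combinations
derive their benefit this way.

The unit observable is **relative viability**: the viability of a treated
cell line at assay endpoint divided by that of an untreated control.
Internally it is always a fraction (1.0 = untreated level, 0 = complete
kill); files recorded on a 0–100 percent scale must be declared as such
(`viability_percent = TRUE`) — the scale is never guessed. Raw screen
values routinely fall below 0 or above 1; they are preserved at ingestion
because only one downstream model is allowed to clamp them (below).
Relative viability cannot distinguish cytotoxic from cytostatic effects,
a limitation inherited by everything built on it.

# Null models of combination effect

For a treatment with components $A, \dots, Z$ evaluated on cell lines
$k = 1, \dots, n$, with per-line monotherapy viabilities $E A_k, \dots$:

**IDA** — the per-line prediction is the best constituent,
$\min(EA_k, \dots, EZ_k)$ for a viability-oriented metric, and the
population efficacy is the arithmetic mean across lines:

$$\mu_{\mathrm{combo,IDA}} = \frac{\sum_{k=1}^n \min(EA_k,\dots,EZ_k)}{n}.$$

If the efficacy metric is inverted (e.g. viability *reduction*, where
larger means more kill), the minimum becomes a maximum. The orientation is
an explicit attribute of the panel object — the engine never infers it
from the data. IDA uses raw viabilities, including values outside
$[0, 1]$.

**Bliss Independence** — the comparator model treats each component
viability as an independent per-cell survival probability, so the
combination survival is the product
$\prod PA_k$. Because probabilities live in $[0, 1]$, component
viabilities are clamped into that interval *for Bliss only* (values below
0 rounded up to 0, above 1 down to 1). For in-range values the product is
never larger than the minimum, so Bliss predictions are always at least
as optimistic as IDA — one of the property tests in the suite.

Predictions are strict complete-case: a cell line contributes to a
combination mean only if it has a valid estimate for every component.
`min_lines` guards against small populations; the package defaults follow
the field conventions of 50 lines for pan-cancer analyses and 3 for
cancer-subtype analyses.

# Dose–response fitting

Clinically relevant concentrations (Csustained — the maximum plasma
concentration sustained at least 6 h after administration) are usually not
tested directly, so viabilities are interpolated from fitted
four-parameter log-logistic (LL4) curves:

$$f(x) = c + \frac{d - c}{1 + \exp\!\big(b(\ln x - \ln e)\big)},$$

with slope $b$ (sign convention: $b > 0$ means viability decreases with
dose), lower asymptote $c$, upper asymptote $d = f(0)$, and inflection
concentration $e$ (µM, the dose at half response). Fitting is bounded
Levenberg–Marquardt least squares (via `minpack.lm`) on
$(b, c, d, \ln e)$ with bounds $|b| \le 20$, $c, d \in [-0.5, 1.5]$
(raw screens overshoot $[0,1]$; truncating would bias the fits), and
$e$ within $[\min\text{dose}/100, \max\text{dose}\times 100]$.
Starting values: $d_0 = \max$ observed viability, $c_0 = \min$ observed,
$e_0$ the dose whose mean response is nearest the half-range, $b_0 = 1$.
Non-convergence triggers three jittered restarts (best residual sum wins);
if none converge the fit is flagged and replaced by linear interpolation
of per-dose means, never silently. Constant series yield a degenerate
flat fit. Series with fewer than four distinct positive doses
(three-dose ALMANAC-style designs) skip curve fitting entirely: the
panel then uses the measured value at an exactly matching dose, with the
replicate-spread standard error or, for singleton measurements, a
user-supplied default (0.05 viability units — a typical replicate
scatter in large screens).

Parameter uncertainty uses a heteroskedasticity-consistent sandwich
estimator built from the analytic Jacobian $J$ and raw residuals $r$:
$V = (J'J)^{-1} J' \mathrm{diag}(r^2) J (J'J)^{-1}$ (HC0; an HC1 variant
rescaling by $n/(n-4)$ is available via `cov_type` — the choice is
surfaced because the literature does not pin down a variant for nonlinear
least squares). $V$ is symmetrized and eigenvalue-floored at zero so it
is positive semi-definite by construction; a singular $J'J$ falls back to
the Moore–Penrose pseudo-inverse and is flagged. The delta method then
gives the standard error of any predicted viability,
$\mathrm{SE} = \sqrt{g' V g}$ with $g = \nabla f$; at dose 0 this reduces
to the SE of $d$ alone. Two numerical guards apply. SEs are floored at
$10^{-6}$ so bootstrap draws stay well-defined for zero-residual fits.
And because the delta method is a linearization, it can explode near the
inflection of an ill-determined steep fit (a slope poorly constrained
between two adjacent doses produces covariance entries orders of
magnitude beyond anything the data support); since the predicted
viability itself is bounded between the asymptotes, the reported SE is
capped at the curve's dynamic range $|d - c|$ plus the residual SD.

Predictions beyond the tested range are permitted up to 2× the maximum
tested concentration — mirroring the admission rule that clinical
concentrations must not exceed twice the tested range — but flagged
`extrapolated` above 1×; beyond 2× they are a hard error. Prospective
scoring is more conservative: each drug is evaluated at
$\min(\text{Csustained}, \text{max tested})$, so a capped flag (rather
than extrapolation) marks drugs whose clinical concentration exceeds the
screen's range. When a concentration table lists several clinical
concentrations for a drug (different dosing regimens), the highest is
stored for prospective use.

# From viability to trial power

To compare predictions against clinical trial outcomes, mean remaining
viability is treated as a proxy for patient hazard: 100% viability maps
to hazard 1, 0% to hazard 0, linearly in between (negative predicted
means floor at hazard 0). This linearity is an acknowledged
simplification — it has no mechanistic justification between the two
anchors, and it ignores everything that affects patient hazard beyond
tumor-cell kill — but it is the least manipulable way to obtain the
hazard ratio a power calculation needs: the predicted HR of a comparison
is simply the mean test-treatment viability divided by the mean
control-treatment viability, computed on one shared cell-line set.

Trial power uses the Freedman approximation for the log-rank test with
$m$ total events, allocation ratio $k$ (experimental : control) and
two-sided level $\alpha$:

$$\mathrm{power} = \Phi\!\left(\frac{\sqrt{k\,m}\,\lvert \mathrm{HR} - 1\rvert}{k\,\mathrm{HR} + 1} - z_{1-\alpha/2}\right).$$

This is the formula implemented by `powerCT.default0` in the
`powerSurvEpi` R package (Freedman 1982, *Statistics in Medicine* 1:121),
which we verified against that package's reference manual before freezing
it here; at $\mathrm{HR} = 1$ it reduces to $\alpha/2$, and the test
suite checks it against an independent erf-based normal CDF on a random
$(\mathrm{HR}, m, k)$ grid. Comparisons are classified as likely to
detect a significant improvement at the conventional 80% power cutoff,
with power exactly at the threshold counting as success (a documented
$\ge$ convention). Multi-arm trials are handled as one row per
control-vs-experimental comparison.

# Prospective ranking: the IDAcomboscore

Where future trials' event counts and control arms are unknown, ranking
uses the IDAcomboscore. With $\Delta_{\mathrm{via}}$ the mean viability
under the best reference therapy (the constituent monotherapy — or a
multi-drug backbone treated as one reference — with the lowest mean
viability) minus the mean viability under the combination, and
$\mathrm{HR}_{C/M_{best}}$ the ratio of combination to best-reference
mean viability:

$$\mathrm{IDAcomboscore} = \Delta_{\mathrm{via}} - \Delta_{\mathrm{via}} \times \mathrm{HR}_{C/M_{best}} = \Delta_{\mathrm{via}}(1 - \mathrm{HR}_{C/M_{best}}).$$

The score is positive exactly when the combination beats its best
reference, zero when it merely matches it, and rewards combinations that
both lower absolute viability and lower it relative to the best
constituent. `comboscore_matrix()` scores every unordered drug pair at
prospective concentrations (pairs below `min_lines` become explicit
missing markers), and `dose_grid_scan()` maps the mean IDA viability of
one pair over a concentration grid from 0 to Csustained, together with
the best-monotherapy plane the combination must beat.

# Uncertainty: the semi-parametric bootstrap

Standard errors for HRs, powers and IDAcomboscores come from a five-step
semi-parametric bootstrap. Per simulation: (1) every panel viability is
perturbed as $v^* = \hat v + z\,\mathrm{SE}$ with $z$ a standard normal
deviate; (2) therapy efficacies are recomputed from the perturbed panel;
(3) cell lines are resampled with replacement; (4) population means are
recomputed on the resampled multiset; (5) the statistic of interest is
recomputed. The SD of the simulated statistics is the reported SE.
Defaults follow the established simulation counts: 10,000 simulations for
trial comparisons, 1,000 for prospective scoring.

When two compared therapies share a compound, the same deviate must drive
that compound's draw in both arms (otherwise shared-compound noise would
inflate the SE of, say, a backbone-vs-backbone-plus-drug comparison).
The panel representation makes this automatic: a panel holds exactly one
column per (drug, concentration), so one drawn panel per simulation
couples every treatment referencing that column. The coupling key is the
full (cell line, drug, concentration) triple — a compound shared at
*different* concentrations is not coupled, which would require
simulating curve parameters instead of deviates; deviate coupling was
chosen because it also works for datasets where only measured viabilities
and their SDs exist (no curve fits to simulate). A degenerate but useful
consequence, used as a test: two identical treatments compared with
coupling on give HR ≡ 1 in every simulation and a bootstrap SE of exactly
zero.

Confidence intervals default to the normal approximation
(point ± $z \cdot$SE), matching the convention of deriving intervals from
the simulated SD; percentile intervals are available via
`ci_method = "percentile"`. Reported power CIs are clipped to $[0, 1]$.
The empirical null probability of a combination is the fraction of
simulated scores ≤ 0; a raw zero is reported as 0 with an attached upper
bound of $1/n_{\mathrm{sims}}$ (the simulation's resolution limit).
Across many combinations these null probabilities are adjusted with the
Benjamini–Hochberg step-up procedure (delegated to `stats::p.adjust`),
with FDR ≤ 0.05 the conventional significance call. Note that BH
re-adjustment of already-adjusted values changes them again — the
adjustment is not idempotent — so FDRs are computed once, from the raw
null probabilities. These uncertainties cover only measurement noise and
cell-line sampling: systematic errors (dilution, protocol differences),
representativeness of the cell-line collection for a patient population,
and dose-matching uncertainty are explicitly not modeled, so the
estimates are lower bounds and deliberately not promoted for hypothesis
testing.

Reproducibility: every bootstrap takes a single root seed and derives a
per-simulation substream seed by a fixed Lehmer-style map (kept below
$2^{31}$), so results are bit-reproducible and independent of evaluation
order. `subsample_stability()` quantifies how dispersion of the mean
prediction grows as fewer cell lines are used — reliability degrades
rapidly below roughly 50 lines, which motivates the pan-cancer
`min_lines = 50` default.

# The synthetic-data generator

All tests run without any external download on screens generated by
`generate_screen()`. Each (cell line, drug) pair draws a true LL4 curve —
$d$ anchored at the untreated level 1.0, $c \sim U(0, 0.6)$ (most drugs
leave a resistant fraction), $\ln e \sim N(0, 1)$ (potencies spread over
roughly two orders of magnitude around 1 µM), $b \sim U(0.5, 3)$ — and is
measured over 8 log-spaced doses (0.01–100 µM, bracketing the potency
distribution) × 3 replicates with Gaussian noise of SD 0.05 viability
units, typical of replicate scatter in large screens. The parameter
distributions are this package's own choices, made once: public screens
do not publish their parameter distributions. Noise is homoskedastic by
default with a heteroskedastic option (SD proportional to viability) to
exercise the robust-covariance path. `generate_combo_measurements()`
produces "measured" combination viabilities from the same truth under
IDA or Bliss, with an optional interaction offset (negative = synergy,
positive = antagonism) to probe how the predictors respond to model
violation: injected synergy makes IDA predictions conservative
(predicted minus measured positive on average).

What the generator does *not* emulate: plate and edge effects, batch
structure, systematic inter-site protocol differences, and any
non-sigmoid pharmacology. Passing tests on synthetic screens therefore
demonstrate correctness of the estimators and the internal consistency
of the pipeline, not predictive performance on real clinical data.

# Problem sizes and numerical conventions

The validation suite and the acceptance script run, by the package's own
choice, at these scales: 500 random small panels for the
engine-vs-enumeration checks; 400 line-drug pairs (200 lines × 2 drugs)
for dose-response recovery, where the median $|\ln \hat e - \ln e|$
under the above conditions sits near 0.09 and is compared against a 0.1
bound — 400 pairs estimate that median tightly enough that the
comparison reflects the estimator rather than Monte-Carlo noise; 10,000
bootstrap simulations for the SE contracts; 200 replicate experiments
(30 lines, 300 simulations each) for CI coverage; and 105 two-drug
combinations (15 drugs, 25 lines) for the end-to-end self-consistency
checks. Monotonicity of the power function is asserted on grids where
power has not saturated to 1.0 in double precision. Site ties in the
replicate policy break to the lexicographically smallest site id, with a
report. Unmapped identifiers pass through harmonization unchanged so
single-dataset analyses need no mapping file.

# Known limitations

- The viability-to-hazard map is linear by assumption; no alternative
  mapping is implemented because none is established.
- Predicted mean viabilities above 1 produce HRs above 1 and are passed
  through (flagged upstream by the panel, not silently truncated).
- IDA cannot predict synergy by construction; the Bliss comparator is
  the only alternative null model shipped, and no synergy estimation is
  attempted.
- Predictions for therapies outside the screened compound space
  (notably immunotherapies) are out of reach of viability screens.
- Cancer-type-specific predictions are limited by available cell-line
  counts; below ~50 lines the subsampling dispersion grows quickly.
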