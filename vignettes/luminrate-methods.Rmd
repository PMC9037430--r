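---
title: "Rate-based drug response from continuous luminescence: models and methods"
author: "luminrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-based drug response from continuous luminescence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luminrate)
```

## The problem

Fixed-endpoint viability assays reduce a drug response to a single
before/after ratio, which confounds potency with growth rate, seeding
density and assay duration, and cannot express cell killing (a response
below zero). Continuous assays avoid these biases by following the
population over days, but then the time course has to be distilled back to
one number per condition. For direct cell counting the established answer
is the drug-induced proliferation (DIP) rate: the slope of log cell number
against time once the response has stabilized. Direct counting, however,
requires fluorescent labels, segmentation, and is effectively unavailable
for suspension lines.

`luminrate` implements the luminescence analogue: a real-time,
non-lytic luminescence signal proportional to the number of metabolically
active cells is read every few hours for ~5 days, the *rate of change* of
that signal is extracted per condition, normalized to the undrugged
("basal") rate of the same cell line, and the normalized rates are fitted
against concentration with a four-parameter log-logistic model. The package
also contains the paired statistics used to validate the luminescence
channel against direct counting, and a mechanistic plate simulator that
provides ground truth for every stage.

## Rate extraction by trailing-slice regression

A well's usable signal ends where reagent consumption overtakes growth and
the trace turns over. The **end of the assay** is therefore defined as the
time of peak luminescence in the control condition (ties broken toward the
earliest time). Within a condition's analysis window, every *trailing
slice* — a contiguous run of timepoints ending at the window's last
timepoint, from `minPoints` up to the full window — is fitted by ordinary
least squares, and the slice with the highest R² wins; its slope is the
condition's rate. Short slices near a flat peak are locally quadratic and
score poorly, long slices spanning curvature score poorly, so the R²
criterion automatically finds the linear regime without any smoothing or
changepoint machinery.

Windows differ by role:

* **control**: first timepoint → control peak;
* **drugged**: the well's own peak → control peak, so that a population
  that grew and then died contributes its decline slope, not its initial
  rise.

Two numerical details are deliberate. `minPoints` defaults to 5 ("more
than four points"); descriptions of the procedure vary between "more than
four" and "at least four", and the stricter reading is the default with
`minPoints = 4` available. R² ties are broken toward the *longest* slice,
which is statistically the steadier slope estimate; noise-free fixtures
(where many slices attain R² = 1 exactly) depend on this rule.

When the drugged window holds fewer than `minPoints` samples — the well
peaks at or just before the control peak, i.e. there is no decline phase to
isolate — the peak constraint is dropped and the control's full window is
searched instead, with a `short_window_fallback` flag on the result. The
alternative (keeping only the last few points before the control peak) was
rejected because it measures the slope of the flattening peak region: a
well indistinguishable from the control would then normalize to well below
1 rather than to 1, contradicting what the normalization is for. A control
whose own best slope is negative is flagged (`negative_control_rate`) but
still used, so that the anomaly is visible downstream rather than silently
sign-flipped.

Replicates are averaged per timepoint before slicing by default (one rate
per condition); `perReplicate = TRUE` slices each well separately.

Direct-count rates use the DIP convention instead: the OLS slope of
log₂(count) over the whole series, in doublings per hour. No windowing is
applied, because log transformation already linearizes exponential growth
and decline.

A cell line qualifies for slope-based analysis only if its undrugged trace
is sufficiently linear; `linearityCheck()` gates on full-series R² > 0.90,
*strictly* — R² equal to the threshold fails.

## Dose–response model

Normalized rates $y$ against molar concentration $c$ are fitted with

$$y(c) = E_{max} + \frac{E_0 - E_{max}}{1 + (c/EC_{50})^{h}}$$

by bounded least squares on the log₁₀-concentration axis. All four
parameters are free; $E_0$ starts at 1 because the normalization anchors
the true zero-dose response there, but it is estimated, not pinned. Bounds
default to $E_{max}, E_0 \in [-5, 1.5]$, $h \in (0, 15]$, $EC_{50} \in
[10^{-12}, 10^{3}]$ M: responses pinned at −5, Hill slopes near 15 and
EC50s far outside any tested range are reported with the offending
parameter named in `boundsHit`, which is how un-identifiable fits announce
themselves. Steep-Hill sigmoids have many local minima, so fitting is
multi-started over $h \in \{0.5, 1, 3, 8\}$ crossed with EC50 seeds at the
concentration quartiles; each start runs bounded Levenberg–Marquardt with
an L-BFGS-B fallback and the lowest sum of squared errors wins. The
reported `residuals` is that sum of squares.

The fitted lower asymptote ("maximal response") encodes mechanism, with
configurable tolerance bands (`tolZero = tolOne = 0.1`, since "a rate of
about zero" is not otherwise quantified):

| $E_{max}$                  | class               |
|----------------------------|---------------------|
| within `tolOne` of 1 (or above) | no effect      |
| within `tolZero` of 0      | cytostatic          |
| below −`tolZero`           | cytotoxic           |
| otherwise (fractional, positive) | anti-proliferative |

## Cross-channel comparison

EC50s from the two channels are compared pairwise on the natural-log scale
with a Wilcoxon signed-rank test computed *exactly*: zero differences
dropped, midranks for ties, and the two-sided p-value obtained from the
full distribution over all $2^n$ sign assignments (a generating-function
convolution enumerates them; a continuity-corrected normal approximation
takes over past 25 informative pairs). The reported statistic is
$W = \min(W^+, W^-)$, the convention under which published critical-value
tables are lower-tail; `wilcoxonCriticalValue(n, alpha)` reproduces those
tables from the same enumerated null. Pairs whose EC50 sits on a fitting
bound are flagged but kept by default — exclusion is a caller's decision,
not a silent default.

Mechanism concordance is judged, by default, at the coarse three-group
level — negative (cytotoxic) vs non-negative below the no-effect band
(anti-proliferative/cytostatic) vs no effect — because that is the
screening-relevant distinction and because the cytostatic/anti-proliferative
boundary is a tolerance choice, not a biological one. A strict four-class
mode is available (`granularity = "class"`).

## The plate simulator

The simulator generates the statistical structure the analysis assumes,
plus the one nuisance that shapes real traces: reagent depletion.

* Cells grow exponentially, $N(t) = n_0 e^{kt}$, with the rate itself
  log-logistic in concentration:
  $k(c) = k_0\,[E_{max} + (1 - E_{max})/(1 + (c/EC_{50})^h)]$,
  $k_0 = \ln 2/\text{doubling time}$, so the programmed normalized
  response is exactly the 4PL curve and $k(0) = k_0$.
* Reagent is consumed at $\gamma$ per cell per hour (second-order
  consumption: rate ∝ cells × reagent), giving the closed form
  $R(t) = \exp(-\gamma n_0 (e^{kt}-1)/k)$ and signal
  $L(t) = a\,N(t)\,R(t)$ — a rise–peak–decline trace with interior peak at
  $t^{*} = \ln(k/\gamma n_0)/k$ whenever $k > \gamma n_0$. The closed form
  avoids an ODE solver and gives the tests an analytic peak oracle.
* Measurement noise is multiplicative Gaussian (plate-reader luminescence
  error scales with signal), truncated so RLU stays nonnegative.
* The count channel draws Binomial(N, `imagedFraction`) and rescales,
  emulating montage imaging of a well subregion.

Defaults are the continuous-assay regime: 300 cells per well, 24 h
doubling, readings every 4 h for 120 h (a 12 h/100 h preset matches the
sparser incubator-transfer protocol), 3 replicates, an 8-point half-log
dilution series spanning the programmed EC50, cv = 0.05. The free
parameters no protocol fixes were set once for realism: `aScale` = 100
RLU/cell (signal scale is arbitrary; every downstream quantity is
scale-invariant, and the tests assert this), and `gamma` = 7×10⁻⁶ per cell
per hour, which places the control peak near 90 h — inside the assay, as
the empirical trace shapes require — while keeping the pre-peak control
trace above the R² > 0.90 linearity gate. Simulation is fully
deterministic given `seed`.

What the simulator does **not** emulate: delayed drug action (the
programmed rate applies from $t = 0$, whereas real cytotoxic wells grow
before they die), plate-position and temperature effects, media
evaporation, or death-channel fluorescence. Passing the recovery tests
therefore shows the pipeline is correct *for the assumed kinetics*, not
that any particular laboratory trace will satisfy those kinetics.

## What recovery tests can and cannot show

The count channel's rate (log₂ slope) estimates exactly the programmed
$k(c)/k_0$, so full-pipeline parameter recovery is tested there: at the
default noise level the fitted EC50 stays within 0.15 log₁₀ units of the
programmed value (median over 100 seeds) and the sign of $E_{max}$ — the
cytotoxic/non-cytotoxic call — is recovered in at least 95 of 100 seeds on
*both* channels.

The luminescence channel's normalized slope is, under exponential
kinetics, a *biased* estimator of $k/k_0$: to first order the ratio of
late-window slopes is $(k/k_0)\,e^{(k-k_0)\bar t}$, with $\bar t$ the
effective slice time, which compresses intermediate responses downward;
and a constant-rate dying well declines steepest at the *start* of the
assay, which trailing slices anchored at the end cannot see, compressing
strongly cytotoxic responses toward zero. This is a property of the
slope-of-raw-signal method itself and is precisely why the luminescence
channel is validated against direct counting *statistically* (paired
Wilcoxon on lnEC50, mechanism concordance) rather than by parameter
identity. Effect-class signs survive the bias; absolute $E_{max}$ values
from the luminescence channel should be read as qualitative.

## Worked scale choices and degenerate inputs

Test and validation workloads are desk-scale by design: plates of one cell
line, 8 concentrations and 3 replicates over 31 timepoints; 100-seed
recovery loops; 1000-series slice-oracle scans; exact Wilcoxon enumeration
up to n = 25. Degenerate inputs have defined behavior rather than
accidents: zero-variance slices get R² = 0 (no linear signal), a zero
basal rate refuses to normalize, all-zero Wilcoxon differences refuse to
test, an all-equal abscissa refuses a static regression, and fits that
never converge return flagged parameters instead of raising.

## Session info

```{r}
sessionInfo()
```
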