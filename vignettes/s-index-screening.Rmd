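---
title: "Scoring drug screens with the S index: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug screens with the S index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sindex)
library(dplyr)
```

## The problem

Quantitative high-throughput screens (qHTS) expose panels of cell lines to
compound dilution series and summarise each concentration–response curve by
a potency (AC50, the concentration of half-maximal activity) or by the area
under the curve (AUC). Potency alone misleads when a compound is only
partially effective — a common outcome in proliferation screens — because
two curves with identical AC50 can differ enormously in how much signal
they actually remove. AUC aggregates potency and effectiveness but
confounds them: a potency shift and an efficacy shift can produce the same
area.

`sindex` scores each compound × cell-line curve with a single index that
keeps both dimensions visible:

$$ S = \log_{10}\frac{\mathrm{EFF}}{\mathrm{AC_{50}}} $$

where EFF is the *effectiveness*, the span between the fitted upper
asymptote (ZERO, the response extrapolated to zero concentration, in % of
vehicle control) and the lower asymptote (INF, extrapolated to infinite
concentration): EFF = ZERO − INF. Differences of S between a designated
reference line and each test line,

$$ \Delta S = S_{\mathrm{ref}} - S_{\mathrm{test}}, $$

are unitless (the response and concentration units cancel in the
difference): ΔS < 0 calls the test line *sensitive* to the compound
relative to the reference, ΔS > 0 *resistant*. Averaging ΔS over the test
lines gives the ΔS mean used for ranking, and the difference of group ΔS
means (tumor vs. control panels scored against one common reference) gives
ΔΔS.

When both lines share the same EFF, ΔS collapses exactly onto the relative
potency ΔpAC50 = −log₁₀(AC50_ref/AC50_test); the added value of S appears
precisely when effectiveness differs, e.g. for partial responders that a
potency-only comparison cannot see at all.

## The curve model

Curves are fit with the four-parameter logistic in log10-concentration
space:

$$ R(C) = \mathrm{INF} + \frac{\mathrm{ZERO} - \mathrm{INF}}
   {1 + 10^{\,h\,(\log_{10} C - \log_{10}\mathrm{AC_{50}})}} $$

Residuals are minimised by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) from a deterministic multi-start: the asymptotes
start at the observed extremes, the midpoint at the concentration nearest
the half-range response, and the Hill slope at ±0.5, ±1, ±2; the lowest
residual sum of squares wins and ties go to the smaller |slope|, so the fit
is reproducible.

Numerical choices that matter:

* **Bounds.** Asymptotes are constrained to [−50, 250] % control — wide
  enough for the >100 % low-dose (stimulated-growth) responses seen in real
  proliferation screens — |h| ≤ 10, and log10 AC50 to the tested range ± 3
  decades, preventing runaway extrapolation when a curve barely bends
  inside the window.
* **Canonical parameterisation.** The 4PL has an exact mirror degeneracy:
  swapping the asymptotes and negating the slope leaves the curve
  unchanged. Fits are canonicalised to h ≥ 0, so `asym_zero` is always the
  low-dose asymptote and a rising (stimulatory) curve is recognisable as
  `asym_inf > asym_zero` and flagged, not silently mirror-imaged. This also
  makes the reparameterisation invariance exact: scaling all
  concentrations by 10 shifts the recovered log-AC50 by exactly +1 and
  changes nothing else.
* **Degenerate inputs.** Fewer than five distinct concentrations, or a
  series with no response variation, yields a non-converged fit carrying a
  reason (`"too few points"`, `"no concentration-response"`) rather than an
  error or a sentinel number; downstream scoring treats these as explicit
  no-fit states.
* **R² and AUC.** R² is computed on the raw points against the
  mean-response null (it can be negative). The AUC is the trapezoidal
  integral of the *fitted* curve over the tested log10-concentration range
  (default 1001 grid points, converging to the closed-form integral);
  lower AUC means stronger inhibition.

## Scoring and flags

S is defined only when EFF > 0 and AC50 > 0. EFF = 0 flags `no_response`,
EFF < 0 flags `stimulatory`, and a missing LAC50 or asymptote flags
`missing`; in every case S is `NA` — undefined values never leak into
downstream arithmetic as −∞. Pairs where either side is undefined are
retained as `indeterminate` with a recorded reason
(`ref_no_response`, `test_no_response`, `both`, `missing`) so that
compound-level accounting stays conservative.

All logarithms are base 10: the deposited LAC50 dialect is log10 molar, and
the prioritization thresholds below read as fold changes only in base 10.

## Prioritization

Compound summaries carry the ΔS mean, the sample variance of the per-line
ΔS values, and the variance of the mean (variance / n). A compound is
prioritized when:

1. **Fit quality** — R² ≥ 0.8 in every test line and in the reference line,
   except reference records with no concentration–response, which are
   exempt (a compound the reference simply does not respond to can still be
   a meaningful differential hit). The default reads "R² of at least 0.8 in
   all test lines" per line; `r2_mode = "mean"` switches to the mean-R²
   reading for users who prefer it.
2. **Effect size** — |ΔS mean| > 0.5. On the log10 scale 10^0.5 ≈ 3.16, so
   the threshold demands roughly a 3-fold arithmetic difference.
3. **Non-inferiority** — |ΔS mean| − √(variance of the mean) ≥ 0.3
   (10^0.3 ≈ 2.0, a 2-fold margin). We operationalise the variance floor as
   a lower confidence bound on the effect: the mean minus one standard
   error of the mean must still clear the margin. The rule is configurable
   because other operationalisations of a "lower boundary of variance of
   the mean" are defensible; this one directly encodes "at least
   non-inferior to a null response".

Compounds with ΔS defined in fewer than the required number of test lines
are *excluded* (`missing_fit`) rather than failed: a single missing cell
line should not masquerade as evidence against a compound. Every predicate
is recorded in audit columns so a verdict can always be traced.

## The synthetic-screen generator

`simulate_screen()` emulates a proliferation qHTS: 11 log-spaced
concentrations from 10⁻³ to 10² µM, responses in % of DMSO control with
additive homoscedastic Gaussian noise (default σ = 5 % control — the
simplest noise model consistent with such screens), upper asymptotes near
100 (Normal(100, 5)), lower asymptotes Uniform(0, 60), Hill slopes
Uniform(0.5, 3) and midpoints drawn uniformly over the grid interior. Each
compound belongs to one effect class applied to all test lines: `null`,
`sensitive`/`resistant` (AC50 shifted down/up by 0.6–1.4 decades at equal
EFF, so the true |ΔS| straddles the 0.5 threshold with margin),
`partial` (test EFF reduced to 20–50 % at unchanged AC50 — visible to ΔS,
invisible to ΔpAC50), and `stimulatory` (test upper asymptote 105–130 %,
emulating low-dose growth stimulation). Default class proportions are
0.4/0.2/0.2/0.1/0.1. The seed fully determines the output; the true
parameters, EFF, S and ΔS travel in a separate truth table, never in the
tables the pipeline reads.

What the generator does *not* emulate — plate and edge effects, DMSO
normalisation artifacts, heteroscedastic or correlated noise, hormetic
(bell-shaped) curves, cross-line correlation of responses — bounds what
passing tests show: they demonstrate that the scoring machinery recovers a
known truth under idealised noise, not that any particular real screen
satisfies those assumptions.

A known limitation worth stating: a sensitive-class shift can push a test
line's true midpoint below the lowest tested concentration, leaving only
the tail of the curve observable. Fits of such curves are legitimately
poor or unstable, and the R² and non-inferiority filters then (correctly)
decline to prioritize the compound, which caps achievable recall slightly
below 1 even when the underlying effect is real — the same behaviour one
expects on real data for compounds more potent than the tested range.

## Problem sizes and verification

The test suite and the acceptance script work at sizes chosen to exercise
the statistics without waste: 200 noisy curves (40 compounds × 5 lines)
for parameter recovery — median |log10-AC50 error| well under 0.15 and
median asymptote error under 3 % control at σ = 5 — and a 50-compound ×
5-line screen for end-to-end class recovery. Noiseless data are recovered
to better than 10⁻⁶, and the generator and fitter serve as mutual oracles.
Identity-level properties (unit invariance of ΔS, antisymmetry, the
equal-EFF collapse onto ΔpAC50, rank-sum conservation, agreement of the
mean/variance and Pearson-r² paths with naive two-pass formulas) are
checked to 10⁻¹².

Reproducing published per-compound ΔS means for the NF1 plexiform
neurofibroma screen requires the deposited single-agent screen files,
which users must download themselves (no repository client is included by
design); the reproduction test runs automatically once the file is placed
at `tests/testthat/synapse/single_agent.csv`, scoring against the
reference line ipnNF95.11C.

## A worked example

```{r example}
scr <- simulate_screen(n_compounds = 12, n_test_lines = 4, noise_sd = 5,
  seed = 7)
fits <- fit_screen(scr$raw)
deltas <- score_screen(fits, scr$reference)
sums <- summarize_compounds(deltas)
verdicts <- prioritize_compounds(sums, n_required_lines = 4)
verdicts |>
  filter(verdict != "not_prioritized") |>
  select(compound, ds_mean, ds_variance_of_mean, n_lines, verdict)
```

```{r ranks}
ranks <- rank_endpoints(sums)
rank_concordance(ranks)
```

```{r plot, fig.width = 6, fig.height = 3.5}
plot_ds_distribution(deltas)
```
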