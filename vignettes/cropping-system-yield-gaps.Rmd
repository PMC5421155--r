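---
title: "Cropping-system yield gaps: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cropping-system yield gaps: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropgap)
library(dplyr)
```

## The problem

Classical yield-gap analysis compares the actual yield of a single crop with
its climate-determined potential. It cannot say anything about the gap that
arises from growing the *wrong arrangement* of crops: a field with one crop
per year in a climate that can support three is leaving yield on the table
no matter how well that one crop is managed. `cropgap` extends the analysis
to the cropping-system level. Because component crops differ in grain
composition and systems differ in cropping intensity, all comparisons are
made in energy per unit land and time (GJ ha⁻¹ yr⁻¹).

For a cropping system $i$ with $n$ component crops observed over $m$ years,

$$\mathrm{CSYp}_i = \frac{1}{m}\sum_{j=1}^{n} Yp_{i,j}, \qquad
  \mathrm{CSYa}_i = \frac{1}{m}\sum_{j=1}^{n} Ya_{i,j},$$

where $Yp_{i,j}$ and $Ya_{i,j}$ are potential and actual yields of crop $j$
in energy units. The *cropping-system yield potential* of a location,
$\mathrm{CSYp}^*$, is the supremum of $\mathrm{CSYp}_i$ over the set of
feasible annual crop sequences; the sequence attaining it is called CS*.
The system-level yield gap of an existing system and its decomposition are

$$\mathrm{CSYg}_i = \mathrm{CSYp}^* - \mathrm{CSYa}_i
  = \underbrace{(\mathrm{CSYp}_i - \mathrm{CSYa}_i)}_{\text{management, CSYgM}}
  + \underbrace{(\mathrm{CSYp}^* - \mathrm{CSYp}_i)}_{\text{arrangement, CSYgA}}.$$

The identity is exact by construction and `decompose_gap()` preserves it to
the last bit. Negative components are reported as-is (with a warning): a
current system can out-arrange the selected alternative, and the sign is
informative.

## Energy accounting

Grain mass at commercial moisture is converted to energy with fixed
per-crop contents: rice 1440 kJ per 100 g at 14% moisture (14.40 GJ t⁻¹)
and maize 1480 kJ per 100 g at 15.5% moisture (14.80 GJ t⁻¹). The map is
exactly linear; no dry-matter or grain-protein adjustment is applied,
because the contents are defined at commercial moisture. The registry is
config-extensible (`crop_registry(extra = ...)`) for other crops.

Reported tables round energies to integer GJ and masses to 0.1 t, with
half-away-from-zero rounding (so 239.76 → 240 and 18.15 → 18.2). Because
the shipped case-study tables print component masses at one decimal, one
per-crop energy cell (6.7 t of rice → 96.5 GJ) differs by 1 GJ from its
printed value of 97; the underlying unrounded mass (~6.74 t) explains the
difference, and the packaged fixture keeps both columns as printed.
Location energy totals in those tables equal the sums of the printed
integer per-crop energies.

## Sequence feasibility on a circular calendar

Scheduling uses a fixed 365-day circle (leap days ignored; simulation years
are labels). A crop cycle sown on day $s$ with duration $d$ occupies the
half-open arc $[s, s+d)$; its end day $e = s + d \pmod{365}$ is the first
free day. Under this convention the durations and turnaround gaps of any
feasible sequence sum to exactly 365, which the test suite re-checks post
hoc on every enumerated sequence. The turnaround rule — at least three
weeks between physiological maturity and the next sowing or transplanting,
for harvest and land preparation — is inclusive: a gap of exactly 21 days
passes. The shipped case-study schedules themselves contain two shorter
printed turnarounds (14 and 20 days), so the packaged fixture configuration
relaxes `min_turnaround` to 14 to admit the published systems; the package
default remains 21.

`enumerate_sequences()` considers every subset of one to three cycle
options. Internally it exploits a graph property: because adding a cycle
only ever subdivides an existing gap, a set of cycles is feasible if and
only if every *pair* is non-overlapping with both directed gaps at or above
the threshold. Feasible sequences are therefore exactly the cliques of the
pairwise-compatibility graph, found without testing most of the
$\binom{192}{3}$ subsets explicitly. A one-crop sequence still faces the
wrap-around gap back to its own next-year sowing. The correctness of this
shortcut is established in the tests against an independent brute-force
oracle that expands cycles to day-occupancy sets and scans the circle.

Scoring follows the energy-sum definition: the annual system yield is the
sum of component energy yields in that year; the score is its mean over
years, and stability is the inter-annual CV (sample SD over mean, in
percent) of the annual energy series. The CV filter (default: discard
sequences with CV above 10%, a high value for irrigated production) applies
to the sequence-level series, not to individual crops, so anticorrelated
components can rescue a sequence. `select_best()` breaks exact ties
deterministically: highest energy yield, then lowest CV, then fewest crops,
then lexicographic crop/variety/start order — the selection rule itself
only specifies the argmax.

Same-crop repeats (maize–maize) are allowed; simultaneous crops
(intercropping) and sequences of more than three crops per year are out of
scope. A cycle may span the year boundary; its yield is attributed to the
12-month system year in which it was sown.

## The surrogate crop model

Process-based crop models (rice and maize simulators run under potential
conditions) produce the real input to this analysis: potential yield,
seasonal evapotranspiration and intercepted PAR per (variety, sowing date,
year). `cropgap` does not re-implement them. Externally simulated output in
the documented CSV layout is first-class input via `read_yield_surface()`.
For self-contained testing and experimentation the package generates
surfaces with a stochastic surrogate whose structure mirrors what such
simulations look like in a sub-tropical irrigated rice–maize environment:

* **Seasonal response.** Mean potential yield is a circular Gaussian in
  sowing/transplanting day, peaking near 1 October (DOY 274) for maize and
  15 November (DOY 319) for rice, with widths of 110 and 100 days. The
  published response curves are empirical and no functional form is given;
  a smooth unimodal surrogate suffices to exercise the framework and is
  documented as exactly that.
* **Maturity classes.** Four classes per crop with fixed durations (maize
  85–128 d, rice 70–130 d, anchored to the printed cycle lengths of the
  case-study schedules) and peak yields non-decreasing in duration
  (longer-cycle varieties have higher potential). Per-location peaks are
  set so the noise-free maxima fall in the observed ranges: maize 15–18,
  rice 13–14.5 t ha⁻¹. No thermal-time model is used, so the surrogate
  cannot reproduce the season-dependent cycle shortening that real
  simulators show (a monsoon-sown "late" maize maturing in 83 days).
* **Inter-annual variability.** Multiplicative log-normal noise with unit
  mean, parameterised by a target CV (5% maize, 6% rice), independent
  across cells. Near the optimum this lands in the observed 3–10% range.
* **Cold injury.** Rice transplanted in a late-October window (DOY
  283–311) would pass panicle initiation to flowering through the coldest
  weeks; the surrogate multiplies its mean by 0.65 and inflates its CV 2.5×
  there. This reproduces the qualitative late-transplanting yield drop and
  CV rise while leaving the mid-November optimum intact.
* **ET and PAR.** Affine functions of yield with per-crop baselines (rice:
  240 + 35·Yp mm, 230 + 67·Yp MJ m⁻²; maize: 30 + 40·Yp mm,
  350 + 93·Yp MJ m⁻²), roughly matched to the single-crop rows of the
  published resource table. These are accounting plumbing — only their
  aggregation is meaningful, not their values; the surrogate has no water
  balance or radiation model.

Identical seeds give bit-identical surfaces. The default date grid (24
dates at 15-day intervals starting DOY 4) is chosen so both crops' optimal
dates lie on the grid; the case-study source does not state where its grid
starts, and arbitrary grids are accepted.

One structural limitation is worth stating plainly: with a single unimodal
response per crop peaking in autumn, both crops always prefer the later of
two open calendar slots, so enumeration over surrogate surfaces selects the
same qualitative sequence everywhere (two maize cycles plus a spring rice
crop). The one case-study location where the observed optimum instead
places rice in the monsoon slot reflects bimodality and duration
flexibility that the surrogate deliberately lacks. Reproducing the
published per-location selections therefore runs the same enumeration and
selection machinery over the packaged *anchor* cycles (the published
schedules expanded to a small constant surface), which `make_fixture()`
writes next to the surrogate surfaces.

## Nitrogen, water and radiation requirements

Under potential conditions a nitrogen budget is not simulated, so annual
crop N uptake is recovered by inverting a published square-root yield
response, $y = a + b\sqrt{N}$ with $(a, b) = (-1573, 643)$ for rice and
$(-3710, 995)$ for maize (yield in kg ha⁻¹ at commercial moisture). The
inverse $N = ((y - a)/b)^2$ is exact; the tests require round-trip
consistency to $10^{-9}$ relative. Below the curve root the response is
negative and `yield_from_n()` censors it at zero with a flag. The
relationships are calibrated on well-managed crops and are exposed for any
yield with that caveat; uptake is a biological requirement, not a
fertiliser recommendation. Annual ET is summed over component cycles and
expressed against rainfall (it may exceed 100% where irrigation draws on
groundwater); intercepted PAR is expressed against annual incident PAR.

Two reporting quirks of the shipped case-study tables are preserved rather
than corrected. First, the location-average *actual* yields printed in the
source do not equal the area-weighted means of the printed per-system
values (the potential-yield averages do reconcile exactly); the
area-weighting rule is implemented as stated, and the gap-decomposition
fixture takes the printed location aggregates as inputs. Second, the
published N-uptake rows for two locations appear interchanged: recomputing
from the printed component yields yields the same *pair* of totals
(746 and 800 kg N ha⁻¹ yr⁻¹) with the assignment swapped. The package
computes, the tests assert the pair, and nothing is silently corrected.
Multi-crop current systems whose per-crop potential-yield split is not
published cannot have their N totals recomputed at all and are not
asserted.

## Numerical choices

* Mass-to-energy conversion and gap decomposition are exact linear
  arithmetic; comparisons in tests use exact equality where the algebra is
  exact.
* CV uses the sample (n−1) standard deviation; a single-year series has
  undefined CV and is flagged rather than zeroed.
* Report rounding is half-away-from-zero with an 8-digit guard against
  binary representation artefacts (18.15 must round to 18.2).
* Area shares are renormalised to sum to one (with a warning when they do
  not sum to 100%); weighting location gaps from weighted aggregates is
  algebraically identical to weighting per-system gaps, both being linear.
* Mixed-crop mass totals (tonnes of rice plus tonnes of maize) are
  reported as in the source tables for comparability, with the caveat that
  they are not energy-equivalent; the energy basis is the coherent one.

## Problem sizes

The shipped defaults are sized for interactive use: per location, 2 crops ×
4 maturity classes × 24 dates = 192 cycle options, about 1.2 million
candidate subsets of which roughly ten thousand are feasible, enumerated
and scored in well under a second. The test suite simulates 5–14 years per
surface and verifies enumeration against a brute-force oracle on up to six
options, where exhaustive day-occupancy checking is still instant.

## Limitations

Beyond the surrogate's unimodality: economic and risk evaluation, market
screening beyond restricting the crop list, rotation carry-over effects
(residual N, water, soil biology — excluded by the definition of potential
yield), intercropping, national upscaling beyond single-location area
weighting, and fertiliser-rate recommendation are all out of scope. Passing
tests demonstrate that the framework arithmetic and the selection machinery
are correct on surfaces with the assumed structure; they say nothing about
the fidelity of any particular crop model's output, which remains the
user's responsibility to supply.
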