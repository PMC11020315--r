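---
title: "Quantifying tooth replacement: waves, rates, and their evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tooth replacement: waves, rates, and their evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zahnreihen)
library(dplyr)
```

Polyphyodont reptiles replace their teeth continuously, in waves that
sweep along the jaw. This vignette explains the three models the package
implements — the replacement-index/Z-spacing quantification of those
waves, incremental-line odontochronology, and Mk-model ancestral-state
reconstruction of replacement patterns — together with the assumptions,
tunable parameters, and numerical choices behind each.

## The replacement index and Zahnreihe segmentation

Tooth sizes vary hugely along a jaw, so raw lengths cannot be compared
across positions. The replacement index normalises them within each tooth
family (alveolus): a replacement tooth scores its total length divided by
the length of its corresponding functional tooth, and the functional
tooth scores 1 plus the index of its most mature measurable successor
(exactly 1 with no successor). The index is dimensionless, lies in
(0, 1) for a growing germ, and is flagged (not dropped) when it exceeds
1, which can genuinely happen when a successor outgrows a worn functional
tooth — or, in simulations, when independent measurement noise is applied
to both lengths. Families whose functional tooth cannot be measured are
excluded from index computation but still count in dentition tallies;
this mirrors how fossil germs are countable long before they are
measurable.

A *Zahnreihe* is one replacement wave: an ordered series of teeth whose
maturity decreases caudally. On the index-versus-position plot it is a
degressive run. We operationalise "degressive sequence" as a **maximal
strictly decreasing run in plot order**, with two deliberate tie-breaks:

* an index that fails to decrease strictly (including an exact tie)
  starts a new Zahnreihe — the only order-deterministic reading;
* a point at the same position as its predecessor starts a new
  Zahnreihe, because two generations in one alveolus belong to
  successive waves by definition.

One subtlety matters. The plot contains two points per occupied alveolus
(functional at `1 + RI`, replacement at `RI`), and any functional index
(≥ 1) exceeds any replacement index (< 1 in practice). Run decomposition
applied to that interleaved series therefore always fragments into
per-position pairs and can never trace a wave across positions. But the
functional tooth's index already encodes the whole family's replacement
state (it is 1 + the most mature successor's index), so the wave signal
lives entirely in the **per-family maturity series** — one point per
position. `z_spacing()` and `summarize_jaw()` segment that series;
`build_plot_series()` still returns every tooth for Zahnreihen graphs.
`segment_zahnreihen()` itself is agnostic: it applies the run rule to
whatever ordered series it receives.

## Z-spacing and wave direction

Each Zahnreihe is a polyline in (position, index) space. For every member
tooth of every Zahnreihe except the last, the spacing measurement is the
horizontal (position-axis) distance to the next Zahnreihe's polyline
evaluated at the same index level by linear interpolation. Horizontal
distance is the only definition that yields the dimensionless
tooth-position units in which Z-spacing is conventionally reported. Teeth
whose index lies outside the next polyline's index range are skipped
rather than extrapolated: extrapolation would invent geometry the plot
does not contain. The dentition row's Z-spacing is the arithmetic mean of
all measurements, reported half-away-from-zero at 2 decimals (grand means
also at 3, since published element averages appear at mixed precision).

Direction classification is a pure threshold rule: Z-spacing above 2.0
means the wave travels rostral→caudal, below 2.0 the reverse, exactly 2.0
simple alternation between odd- and even-numbered alveoli. The
"alternating" band has width `tol` (default 0, i.e. exactly 2.0,
configurable) — with real measurement error a user may prefer a small
positive band. Left and right sides are always analysed independently:
premaxillary dentitions are known to fall out of phase between sides, and
merging them would average away exactly that signal.

## Odontochronology

Von Ebner incremental lines are daily light/dark couplets in dentine.
Their count is the tooth formation time in days; their mean width is the
daily dentine apposition rate (DDAR, µm/day). The package consumes
already-measured width series — increment identification from microscope
images is a separate imaging workflow, out of scope here. DDAR is the
unweighted mean over all supplied couplets (no published weighting exists
to follow), so the identity `formation_days × DDAR = total dentine
thickness` holds exactly and is used as an internal consistency check.

Two inference rules turn formation times into replacement rates:

* **Newly erupted, no successor**: the next generation has at most just
  begun, so the replacement rate equals the formation time as an upper
  bound. The figure is reported with an explicit
  `upper_bound_newly_erupted` qualifier everywhere, because the headline
  number ("46 days") is a supremum, not a point estimate.
* **Two sectioned generations of one family**: the exact rate is the
  difference of their increment counts (both teeth started one
  replacement cycle apart).

Worn teeth without family data support no inference; the package says so
rather than guessing.

## Time calibration by the 'equal' method

Fossil tips are dated by first-appearance dates (FADs, Ma; last
appearances are carried for optional midpoint dating but not used by
default, since no published tip-dating choice exists to follow). Each
internal node starts at the oldest FAD among its descendants, and the
root is pushed back by `root_extension` Myr. This "minimum-age" dating
leaves a zero-length chain above each subtree's oldest tip; the 'equal'
rule removes them by letting every chain of zero-length branches share,
in equal parts, the duration of the nearest ancestral branch of positive
length. Node ages only rise during redistribution, so sibling branches
never go negative; root-to-tip path lengths (root age minus tip FAD) are
conserved exactly. With `root_extension > 0` every branch ends strictly
positive. Polytomies are treated as hard; chains through a polytomy are
resolved in preorder sequence.

## Mk models, model averaging, and stochastic maps

The replacement-pattern character (default state set `one_generation`,
`two_generations`, `three_plus`; the coding is user-supplied) evolves
under a continuous-time Markov model with generator `Q`. Likelihoods are
computed by Felsenstein pruning with per-branch transition matrices
`exp(Q t)` from one spectral decomposition of `Q` (validated by
reconstruction; a scaling-and-squaring fallback handles numerically
defective cases), with per-node rescaling against underflow. The root
prior defaults to flat over states — no published choice exists to follow
— and can be set to the stationary distribution or any probability
vector.

Three rate structures are fitted by maximum likelihood: ER (one rate),
SYM (one per unordered pair), ARD (one per ordered pair). Optimisation is
multistart (default 5 deterministic starts spanning 2.5 orders of
magnitude around one change per total tree length) on log-rates;
single-parameter models use golden-section search, multi-parameter models
Nelder–Mead exploration with one quasi-Newton polish. Rates are bounded
at 100 expected changes per average branch: beyond that the likelihood
sits on its saturation plateau, the rate is unidentifiable, and unbounded
estimates only destabilise downstream simulation. Akaike weights
`w_m ∝ exp(-ΔAIC_m / 2)` quantify model support, and stochastic maps are
drawn under each model's ML generator in proportion to its weight
(largest-remainder rounding makes the total exact; default 1000 maps).

Each map samples node states from their exact joint conditional
distribution (pruning partials combined pre-order with branch transition
probabilities), then fills in branch histories conditional on endpoints:
rejection sampling (cap 1000 attempts) where forward simulation is cheap,
switching to an exact uniformization sampler when a branch expects more
than 20 jumps or rejection exhausts its cap. Per-node state frequencies
across all maps summarise the posterior; the root row is the
ancestral-state estimate.

## What the simulators emulate — and what they do not

`simulate_dentition()` generates one dentition row whose replacement
indices follow a degressive sawtooth `RI(x) = 1 − frac((x − phase) /
period)` mapped onto (0, 1], so the true Z-spacing is `period` by
construction. (The sawtooth must decrease with position: waves mature
rostrally.) Functional lengths follow a unimodal profile peaking at
position 8, mimicking maxillary rows whose crowns are largest mid-row;
lengths get mean-preserving multiplicative lognormal noise
(`noise_cv`, default 0) — lognormal because lengths and widths are
strictly positive. `simulate_increments()` draws lognormal daily widths
around a target mean; `simulate_mk_tips()` evolves a character root→tips
with exponential waiting times, retaining true internal states. Every
generator embeds its parameters in a `provenance` attribute, and recovery
tests read truth only from there.

What passing recovery tests show is that the estimators invert the
generative models faithfully. Real dentitions add what the generators
omit: resorption remnants, missing germs, asynchronous left/right phases,
eruption-order irregularities at the row ends, and measurement error that
is not multiplicative lognormal. Results on fossils therefore inherit the
usual caveats of the underlying methods, not a guarantee from these
tests.

## Numerical choices and problem sizes

Defaults follow the conventions of the analyses the package reproduces:
1000 stochastic maps split across three rate models; direction tolerance
0; rounding half-away-from-zero (2 dp per side, 2 and 3 dp for grand
means). Validation experiments in the test suite use sizes chosen for
statistical power at reasonable runtime, as their own design choices:
Z-spacing recovery uses 16-position rows over 200 seeded replicates per
period (wave periods 2.0–3.0, 3% length noise); the ER rate-recovery
experiment uses 50-tip trees with total length 1500 Myr at a true rate of
0.01 changes/Myr, so the ~30 expected changes make a factor-of-two
recovery band achievable (the standard error of a log-rate scales as one
over the square root of the number of changes — on a tree with a handful
of expected changes the rate is simply not identifiable to that
precision, regardless of estimator); ancestral-state recovery simulates
low-rate (0.002/Myr) three-state characters on the bundled 18-taxon
synthetic ornithischian tree and checks the model-averaged root mode over
20 seeded runs of 200 maps each.

## Known limitations

* Zahnreihe segmentation is deterministic and local; hand-drawn wave
  assignments that tolerate small non-monotonicities will occasionally
  differ near run boundaries, especially under noise.
* Z-spacing is undefined with fewer than two Zahnreihen; such rows
  report an empty cell rather than failing.
* The 'equal' method inherits the usual caveat of minimum-age
  calibration: absolute node ages depend on `root_extension`, for which
  no principled default exists (the package requires it explicitly).
* ML Mk fitting on small trees has flat likelihood surfaces; Akaike
  weights, not single best models, should carry the interpretation, and
  the bundled synthetic character data are stand-ins, not a published
  matrix.
* No left/right wave pairing is attempted: asynchrony is reported per
  side, never merged or reconciled.
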