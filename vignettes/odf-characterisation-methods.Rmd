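---
title: "Methods: synthetic scenarios and analysis pipelines for ODF characterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic scenarios and analysis pipelines for ODF characterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odftoolbox)
```

## Why a scripted generator

The three bench methods this package analyses — a stopwatch-timed Petri
dish test, plan-view video in an oral cavity model (OCM), and
coefficient-of-friction traces from a reciprocating BioTribometer
(BTM) — produce raw data (videos, 100 Hz force traces) that are not
publicly deposited. The package therefore ships a ground-truth-scripted
generator: every film × method cell is a `film_scenario` whose event
schedule, endpoint, and friction signature are packaged parameters
(`inst/extdata/scenario-params.json`), and every analysis stage is
validated by *blind parameter recovery* — the pipeline sees only
rendered frames or synthesised traces, never the script.

The four films are the study's: C1 and C2 (sodium
carboxymethylcellulose, 395 and 725 kDa, 1 % w/v) and P1 and P2
(polyvinyl alcohol, 39 and 197 kDa, 5 % w/v), printed at 30 × 20 mm.
Packaged endpoints per cell are the study's means (e.g. P1: 7.4 s
Petri, 24.0 s OCM, 31.0 s BTM; censored cells such as C2-Petri carry
the `>180 s` marker), and the per-film OCM behaviours follow the
reported narratives:

- **P1**: a fragment holding 20 % of the area detaches at the endpoint
  and is carried off at 3 mm/s; the remnant then shrinks progressively
  (0.012 of scale per second).
- **P2**: transient corner tears at 70, 80 and 95 s that re-coalesce
  within ~8 s, and a larger partial vertical tear over 105–160 s; the
  film never splits into two persistent objects, so the cell is
  censored.
- **C1/C2**: hydration swelling only (factor 1.12/1.18 over 120 s),
  modelling palate adhesion with no split — censored.
- **BTM signatures**: CMC films decline to a terminal plateau over a
  3 s ramp ending at the observed endpoint; PVA films fluctuate
  sinusoidally (amplitude 0.06/0.09, period 5 s) before plateauing.

## Video rendering and its deliberate limits

Frames are 640 × 480 px at 0.1 mm/px (the 30 × 20 mm film is a
300 × 200 px rounded-corner rectangle), rendered saturated magenta on a
pale silicone tone with shared Gaussian appearance noise (sd 0.02) per
frame, at 30 fps by default. Method artifacts are injected so the
segmentation has something real to be robust against: the OCM dims
frames by 15 % during the first 0.4 s of each 2 s compression cycle;
the BTM sweeps an additive specular band (amplitude 0.15, ±25 px)
sinusoidally at the 1 Hz reciprocation frequency.

The generator is *not* photorealistic: no refraction or fluid film, no
motion blur, no partial transparency as the film thins, no
out-of-plane deformation (the reported palate adhesion is modelled only
as swelling with no split). Passing tests therefore demonstrate that
the pipeline recovers scripted geometry under controlled nuisance
factors — not that it would segment arbitrary laboratory footage
unchanged; on real footage the chromaticity threshold and the fragment
size floor are the first knobs to revisit.

Rasterisation is analytic: a pixel is film iff its clamped distance to
the scaled core rectangle is within the scaled corner radius, so
shrink schedules produce pixel-monotone masks by construction (the
monotonicity tests rely on this, not on chance). Determinism is exact:
per-frame noise seeds derive from `(seed, frame index)`, so identical
`(scenario, seed)` pairs are bit-identical.

## Segmentation and measurement conventions

The film is dyed, so the primary segmentation thresholds the red–green
excess (default 0.25), which cancels brightness changes and survives
additive white highlights until clipping; morphological opening (3 px
box) then hole filling clean the mask. Otsu auto-thresholding and a
gradient-edge mode are config-switchable fallbacks.

Conventions that matter and are easy to get inconsistently:

- **Fragments** are 8-connected components with at least
  `min_fragment_px` pixels (default 0.5 % of the initial film area —
  small enough to catch the 20 % P1 fragment instantly, large enough to
  ignore the sub-300 px corner nibbles scripted for P2).
- **Perimeter** is the closed polygon through boundary-pixel centres
  (Moore contour; unit steps for 4-neighbour moves, √2 for diagonals):
  a filled 10 × 10 px square has perimeter 36.0. Tests check this
  against two independent tracers.
- **Normalisation**: area fraction is exactly 1 at the first analysed
  frame; area and perimeter are median-filtered in time (window 7
  frames) but the fragment count is left raw, because the endpoint rule
  applies its own temporal logic.

## Endpoint definitions

*Video*: earliest time the retained fragment count is ≥ 2 for 5
consecutive frames (~0.17 s at 30 fps). The persistence rule exists for
the P2 behaviour — transient tears re-coalesce and must not register.
If no persistent split occurs before the 180 s Pharmacopoeial cap the
result is right-censored; censored endpoints never enter means or
ANOVAs, and cells where all replicates are censored render as
`>180.0`.

*Friction*: per-stroke μ (strokes are 1 s reciprocation cycles,
delimited by stage-position minima when the position channel exists;
the central 60 % of the positional range is kept because μ is
ill-defined at the turnarounds, and strokes whose samples are all
excluded stay in the series flagged invalid). The endpoint detector
fits piecewise-constant models with 0, 1 and 2 change points by exact
least squares (cumulative-sum costs, minimum segment 2 strokes) and
selects by BIC with 2k + 1 parameters; the reported time is the start
of the stroke opening the terminal segment, minus half a stroke. A
0-change-point selection means no plateau onset: censored. On a 3 s
decline ramp this estimator is unbiased to within about one stroke,
which is well inside the ±2 s replicate spread the study reports for
these endpoints.

*Petri*: the simulated observer adds a zero-mean truncated-normal
latency (truncation at ±3 sd; sd defaults to the study's printed
replicate sd for that film) to the scripted endpoint, censoring at
180 s.

## Rheology fitting choices

Flow curves use exactly 30 logarithmically ascending shear rates on
0.01–100 s⁻¹ with multiplicative log-normal noise. The power-law fit is
a least-squares line in log η vs log γ̇; shear thinning means
n < 1 − 0.02, the 0.02 tolerance separating behaviour from noise at the
emulated noise levels. The Cross fit minimises *log-viscosity*
residuals: the curves span about three decades, and absolute residuals
would let the low-shear plateau dominate, leaving η∞ almost
unconstrained (in seeded experiments the worst-case η∞ recovery error
drops from ~63 % to ~13 % at 5 % noise when switching to log
residuals). Even so, η∞ rests on the few near-plateau points the
protocol provides, so the packaged recovery test runs at 3 % noise
where all parameters are identifiable; near-Newtonian inputs are
returned flagged `degenerate` rather than failed. Interpolation
(`viscosity_at`) is linear in log–log space, exact on power-law data,
and refuses to extrapolate.

No numeric flow-curve values are published for these solutions; the
parameters used in `analysis/04_rheology.R` are stand-ins chosen to
encode the reported qualitative facts (viscosity rises with molecular
weight, CMC thins throughout, PVA plateaus early, and P1/P2/C1 share a
similar η at 50 s⁻¹). They are never treated as measured truth.

## Friction levels and replicate variability

Mean CoF values are likewise unpublished; the packaged signature levels
encode the reported ordering (C2 lowest, P1 highest, C1 well below the
PVA films) with P1 and P2 deliberately near-equal, since the study
found their difference not significant while C1–C2 was significant at
p < 0.0001. `run_toolbox` adds a per-replicate specimen jitter
(sd 0.015 on the signature levels) so replicate-level statistics have
realistic variance rather than only trace noise; with three replicates
this reproduces a strongly significant C1–C2 contrast and a
non-significant P1–P2 contrast.

## Problem sizes and numerical details

The packaged defaults are the study conditions: 4 films × 3 methods ×
3 replicates, 30 fps video, 180 s cap, 100 Hz traces. The narrative
scripts and the test suite run reduced sizes chosen once — 2–10 fps
and, for full-grid runs, a 30 s cap (every non-censored endpoint lies
below 30 s, so the censoring pattern is unchanged; endpoints scripted
beyond a reduced cap, such as P1-BTM at 31 s, censor correctly against
it). The acceptance script renders P1-OCM at the full 30 fps and the
full-length 180 s C2-OCM censoring check at 10 fps.

Other numerical choices: sub-seeds derive from a fixed integer
recurrence kept below 2³¹; BIC ties resolve to the smaller model; the
change-point search constrains segments to ≥ 2 strokes; positional
stroke cutoffs carry a 10⁻⁶-of-range epsilon so CSV round-trips cannot
flip boundary samples; empty masks measure as zeros rather than
erroring; `fit_cross` reports its convergence message, and failures
carry the residual at the start values.

## Known limitations

- The OCM/BTM operator "observed disintegration" times and the
  friction-signature plateau onset are assumed to coincide; that
  assumption is only exercised on synthetic data.
- Palate adhesion is observed side-on in the laboratory but modelled
  here only as plan-view swelling; thickness loss ("washing away") is
  not modelled because the study recorded no thickness.
- Video input is PNG frame directories (plus the in-memory generator);
  container formats need external extraction.
- The Cross η∞ is weakly identified above ~3 % noise with this
  30-point protocol — a real campaign wanting η∞ should extend the
  high-shear range rather than trust the fit.
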