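---
title: "Models and methods behind rotodbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rotodbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotodbs)
```

`rotodbs` analyzes deep brain stimulation (DBS) parameter sweeps through
the transient contralateral rotation they induce in the unilateral 6-OHDA
rat. This vignette documents the models implemented, the parameters that
matter, the numerical conventions, and what the synthetic cohort does and
does not establish.

## Waveform charge calculus

A stimulation condition is a charge-balanced biphasic pulse train:
shape, peak amplitude $I$ (µA), per-phase pulse width $PW$ (µs),
zero-current interphase interval, and repetition frequency $f$ (Hz).
Charge per phase is the integral of $|i(t)|$ over one phase,

$$Q = c_{\text{shape}} \cdot I \cdot PW, \qquad
  c = 1 \;(\text{Rect}),\; \tfrac{2}{\pi} \;(\text{Sine}),\;
  \tfrac12 \;(\text{Tri}),\; \tfrac12 \;(\text{Lin.Dec}),$$

with three conventions the source material leaves implicit and we fix
explicitly:

* the **Sine** phase is a half-sine $\sin(\pi t/PW)$, the **Tri** phase a
  symmetric isosceles triangle, and **Lin.Dec** a ramp starting at the
  peak and decaying linearly to zero — the conventional readings of these
  shape names;
* the second phase is the time-mirrored negative of the first (equal
  width, equal charge), cathodic-first by default, so every pulse is
  charge balanced by construction;
* charge *rate* counts both phases: $2 Q f$ µC/s.

`equivalent_amplitude()` inverts $Q$ in $I$ exactly (property-tested to
$10^{-12}$ relative), which is how the waveform paradigm keeps charge
consistent across shapes: at equal $PW$, Sine needs $\pi/2\times$ and
Tri/Lin.Dec $2\times$ the rectangular amplitude.

Frequency charge multipliers are reported as $f/f_0$ **truncated** (not
rounded) to one decimal: $100/15 = 6.67 \to 6.6$. This matches the
published reporting convention (6.6, 8.6, 16.6, 23.3), so truncation is
the default of `charge_multiplier()`.

`teed()` computes the total-electrical-energy-delivered estimate exactly
as printed in the DBS literature, $I^2 f \, PW / Z$. Applied to a
current amplitude this is dimensionally odd (a power would multiply by
$Z$); we deliberately implement the printed form and document the caveat
rather than "fix" it, so values are comparable with published numbers.

Sampled waveforms use midpoint sampling of each $dt$ bin; the sampled
per-phase charge converges to the closed form as $dt \to 0$ and the net
charge of any sampled pulse is bounded by one bin's worth of current
(both under test).

## Session protocols

All three paradigms use 30-s DBS-on episodes separated by 45-s off
periods, time origin at the first onset, and no trailing off period
(sessions end at the last ON offset — the source material does not state
otherwise):

* **amplitude**: multipliers $(1, 1.25, 1.5, 1.75, 2)\times I_0$,
  Rect, 130 Hz, 65 µs, 100 µs gap;
* **frequency**: 15, 50, 100, 130, 180, 250, 350 Hz at the amplitude
  titrated at 15 Hz, Rect, 65 µs / 100 µs;
* **waveform**: five charge blocks $(1 \ldots 2)\times Q_0$, each a
  Rect–Sine–Tri–Lin.Dec sequence at 130 Hz, 100 µs / 100 µs, amplitudes
  charge-matched within the block, with a 20-min recovery break between
  blocks. All five charge levels are built even though published figures
  show only three; reporting subsets instead.

Samples are assigned to episode windows by the half-open convention
$[t_{\text{start}}, t_{\text{end}})$, so the sample at an ON offset
belongs to the following off period. Condition order is fixed ascending
(as run in the reference experiments); `randomize_order = TRUE` is
available but off by default.

## The synthetic cohort

No raw trajectories from the reference experiments are public, so the
pipeline is exercised by a *phenomenological* generator whose defaults
are the stated experimental world, chosen once and frozen:

| parameter | default | rationale |
|---|---|---|
| cohort size | 9 | reference cohort size |
| exclusion probability | 1/3 | 3 of 9 animals excluded as over-sensitive |
| threshold $I_0$ | lognormal(log 60 µA, 0.3) | tens-of-µA bipolar STN microwire thresholds; positive, right-skewed |
| rotations at $I_0$ | 0.25 / 30 s | "not more than a quarter rotation" at threshold |
| rotations at $2 I_0$ | $N(6, 1)$, truncated $> 1$ | "close to six full rotations" at twice threshold |
| frequency gain | knots $\{15{:}0.0625,\ 50{-}180{:}1,\ 250{-}350{:}1.75\}$ | quarter rotation at 15 Hz vs ~4 at 50 Hz fixes $0.25/4$; therapeutic plateau 50–180 Hz; saturating step at 250–350 Hz (~7 rotations) |
| shape efficacy $\kappa$ | $N(0.75, 0.05)$ in $(0.5, 0.95)$, shared by Sine/Tri/Lin.Dec; $\kappa(\text{Rect}) = 1$ | makes non-Rect at $2 Q_0$ behave like Rect at $\kappa \cdot 2 = 1.5 \times Q_0$, the headline waveform observation, exact in the noise-free model |
| rate noise | 10 deg/s per 0.1-s step | keeps single-episode rotation counts reproducible to ~±0.1 rotation, the plausible scale of video-scored rotometry |
| off-period drift | 2 deg/s | small spontaneous reorientation between episodes |
| onset/offset ramp $\tau$ | 1 s | encodes the *transient* kinetics of induced rotation; first-order filter |
| arena | bowl, radius 20 cm | corner-free environment of the reference setup |
| locomotion | speed $= 1 + 0.15 \, |\omega|$ cm/s | chosen so threshold episodes travel tens of cm and $2 I_0$ episodes a few hundred cm, the published range (62.8–366.7 cm) |

The response model is linear in the **effective charge multiplier**
$m_{\text{eff}} = \kappa(\text{shape}) \cdot Q(\text{train}) /
Q(\text{threshold})$:

$$R = \big[r_{I_0} + (r_{2I_0} - r_{I_0})(m_{\text{eff}} - 1)\big]_+
      \cdot g(f), \qquad g(130\,\text{Hz}) = 1,$$

rotations per 30 s, clipped at zero (sub-threshold charge produces no
rotation — which is why no alternative waveform rotates at $1 \times
Q_0$: $m_{\text{eff}} = 0.75$ lands below threshold). Anchoring
$g(130) = 1$ means amplitude-paradigm anchors need no rescaling; the
frequency paradigm titrates its own threshold at 15 Hz, which lands
above the 130-Hz threshold by construction, reproducing the ~¼ rotation
at 15 Hz and ~4 at 50 Hz without extra tuning.

All randomness flows from one root seed through a deterministic
counter-based splitting scheme (stream × index), so any animal or
session is reproducible in isolation; identical configs give
bit-identical bundles (under test).

**What a green synthetic test establishes** — that the pipeline
*recovers the structure it was given*: affine dose–response in the
noise-free limit ($\rho = 1$), median $\rho \ge 0.9$ across 200 noisy
6-animal cohorts, the frequency plateau and its Euclidean-distance block
structure, and the $\kappa = 0.75$ waveform equivalence. It does *not*
establish anything about real rats: the generator has no dyskinesia
dynamics, no habituation or order effects across the fixed ascending
sequence, shared frequency knots across animals (per-animal frequency
heterogeneity is unreported), and white rather than autocorrelated
behavioral noise.

## Titration and exclusion

$I_0$ is the smallest amplitude on an ascending grid whose noise-free
30-s probe yields a maximum cumulative rotation in $[30°, 180°)$. The
180° ceiling is the stated threshold criterion; the **30° floor is our
addition** — "smallest amplitude that induced a rotation" needs a
detectability bound, and 30° (a twelfth of a turn) is the smallest
excursion a video scorer would plausibly call an induced rotation. It is
configurable (`detect_min_deg`). Dyskinesia-prone animals, and animals
already past 180° at the first grid point, are excluded — the synthetic
counterpart of removing over-sensitive animals. With steep
dose–responses the $[30°, 180°)$ window can be narrower than the default
5-µA grid; the titration then fails loudly rather than guessing, and
`run_paradigm()` uses a 1-µA grid.

## Rotometry, similarity, statistics

Features re-zero the angle at the first sample of each window; the AUC
is the trapezoidal integral of the rotation count over the window, in
rotation·seconds (the published unitless 5–141 range does not pin a
unit; ours is documented and internally consistent). Both the window
maximum and the window-end (net) rotation are computed; the maximum is
the headline feature, matching the "maximum rotation" figure captions.

Similarity uses one cohort-*mean* trace per condition (published tables
print one value per pair, not per animal), resampled to 30 uniform
points per 30-s window (1 Hz; no sampling rate is stated, so the grid is
a documented, configurable default) and re-zeroed at onset. Distances in
degrees are exactly 360× those in rotations; both units are offered
because published waveform-experiment distances are ~100× the amplitude
ones, consistent with a different unit convention that the source never
reconciles — we expose the parameter rather than guess.

Correlations are computed on per-level cohort means against the physical
level (multiplier or Hz), so $n$ = number of levels. This is the only
reading consistent with the published significance values:
$\rho = 0.945$ with $p = 0.015$ requires df = 3 (5 levels), and
$\rho = 0.894$ with $p = 0.007$ requires df = 5 (7 levels) — both
reproduced by `p_from_r()`, which uses the exact closed form of the
Student-$t$ tail at df = 3,
$S(t) = \tfrac12 - \tfrac1\pi\big[\tfrac{t}{\sqrt3 (1 + t^2/3)} +
\arctan(t/\sqrt3)\big]$, agreeing with the numerical tail to $10^{-10}$
over $t \in [0, 50]$ (under test). Waveform comparisons default to a
paired $t$-test (the same animals underwent every waveform); Welch is
offered since the variant is not named in the source. Two-tailed $p$
throughout; no multiple-testing correction (none was applied in the
source) — reported as raw $p$.

Degenerate inputs are explicit errors (constant correlation input,
non-positive charges, windows with fewer than two samples) except the
zero-variance paired difference, which is reported as $t = 0, p = 1$
(all-zero) or $p = 0$ with a `degenerate` flag, so downstream tables
never silently contain NaN.

## Known limitations

* The behavior model is phenomenological; no basal-ganglia circuit model,
  no biophysics of charge injection at the electrode interface.
* Trajectories are generated post-annotation (angle series), not from
  video; BORIS-style export parsing is out of scope beyond a documented
  column mapping (`time_s`, `angle_deg`, `x_cm`, `y_cm`).
* Pulse width, polarity, asymmetric phases and interphase-interval sweeps
  are representable in `pulse_train()` but have no dedicated paradigm
  builders, mirroring the scope of the reference experiments.
* The radial fold-back at the bowl wall is a simple reflection, not a
  thigmotaxis model; path-length features near the wall inherit that
  simplification.
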