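---
title: "Simulating and classifying reference frames in a desired-trajectory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and classifying reference frames in a desired-trajectory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachframes)
```

## The model

`reachframes` simulates a feedforward basis-function network whose job is to
compute a *desired reach trajectory in visual coordinates*. All positions are
1D eccentricities in degrees: eye position $E$, initial hand position $H$ and
target position $T$, with the derived quantities $TE = T - E$ (target in eye
coordinates), $HE = H - E$ (hand in eye coordinates) and the displacement
vector $TH = TE - HE = T - H$.

The computation happens in two stages. A first vector subtraction forms the
displacement $TH$; a temporal operation then scales it by a decreasing
interpolation function $\psi(t)$ and a second subtraction produces the
desired eye-centered hand position

$$he(t) = TE - \psi(t)\,TH.$$

Normalized task time has three unit-length epochs: pre-target
($-2 \le t < -1$), delay ($-1 \le t \le 0$, with $\psi = 1$ by
back-extrapolation) and movement ($0 < t \le 1$, with the piecewise-linear
default $\psi(t) = 1 - t$). During the delay $he$ equals $HE$; at movement
offset it equals $TE$. A smooth sigmoid could replace the linear ramp
without qualitatively changing any result; the package keeps the
piecewise-linear form because every analysis below depends only on the
values of $\psi$, not its smoothness, and the linear ramp makes epoch
boundaries exact.

The three internal nodes of the network carry Gaussian-tuned,
gain-modulated unit responses (`unit_response()`):

* **eye node** $r_1 = A\,e^{-(TE-u)^2/2\sigma^2} f(\pm(HE - v)/\sigma)$ —
  an eye-centered target representation, gain-modulated by hand position;
* **dynamic hand node** $r_2 = A\,e^{-(\psi(t)TH-u)^2/2\sigma^2}$ — tuned to
  the scaled displacement vector;
* **eye-and-hand node**
  $r_3 = A\,e^{-(TE-u)^2/2\sigma^2} f(\pm(\psi(t)TH - v)/\sigma)$.

Here $f(x) = \max(x, 0)$ is the semi-linear gain, $u$ and $v$ are tuning and
modulation onsets, and the $\pm$ slope alternates between adjacent units.
Before target onset the target-related factors are set to unity, so the eye
node reduces to its gain factor and the other two to the constant amplitude
$A$. Populations tile onset space with $N$ values per dimension spanning
$[-3\sigma, 3\sigma]$: $N$ units for the single-onset hand node and $N^2$
for each dual-onset node.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| $A$ | 30 | rate | response amplitude |
| $\sigma$ | 15 | deg | tuning and gain length-scale |
| $N$ | 30 | — | onsets per dimension |
| noise SD | 5 | rate | additive Gaussian response noise |
| SVE threshold | 10 | rate | screening acceptance |
| $\alpha$ | 0.01 | — | F-test level |

Noise is added independently per unit, condition and time point and is
deliberately not clipped at zero: clipping would skew the residuals the
regressions assume to be additive. All noise comes from one seeded stream
per experiment, consumed in a fixed order, so every run is reproducible
end to end.

## The analysis chain

**Screening.** Units are first screened on a center-out task ($E = H = 0$,
9 targets from $-2\sigma$ to $2\sigma$ spaced $\sigma/2$) by fitting the
four-parameter Gaussian $r = a\,e^{-(T-\mu)^2/2s^2} + c$ under the bounds
$a \in [0,100]$, $\mu \in [-45,45]$, $s \in [10,30]$, $c \in [0,10]$. A unit
is kept when its spike variance explained, $\mathrm{SVE} = r^2 a$, reaches
10 and its fitted peak lies at least $s/2$ inside the task range. Screening
uses the same (noisy) simulated dataset as the downstream fits, matching an
experimental workflow.

**Reference-frame regression.** Accepted units' 45 delay-task responses
(9 targets $\times$ 5 eye/hand pairs) are fitted to the six-parameter model

$$r = a\,e^{-(TX-\mu)^2/2s^2}(1 + g\,HE) + c,
\qquad TX = w\,TE + (1-w)\,TH,$$

with $g \in [-0.15, 0.15]$ and $w \in [-1.5, 2.5]$; $w = 0$ is a pure
hand-centered and $w = 1$ a pure eye-centered encoding. Fixing $w$ at 0 or
1 gives the two pure-frame submodels. Each submodel is compared to the full
model with $F = (RSS_{sub} - RSS_{full})/(RSS_{full}/(n-6))$ on $(1, n-6)$
degrees of freedom; rejecting both gives *intermediate*, rejecting only the
hand (eye) submodel gives *eye* (*hand*), rejecting neither gives
*indeterminate*. The stepwise table is isolated in `classify_unit()` so it
can be swapped; it is the natural reconstruction of the four class labels
from two nested tests, which is all the published methods pin down.

**Dynamics.** `evolve_classification()` repeats the whole chain at
successive movement times (default $t \in \{0, .25, .5, .75, 1\}$; the
movement epoch is re-sampled because the underlying studies probed "various
points" without fixing them), with fresh noise at each $t$, and re-evaluates
class membership each time. The re-evaluation is essential: the residual
hand class drifts *because* its best-fitting members keep being reclassified
away — suppressing it would suppress the phenomenon. Units are also
re-screened at each $t$; the dynamic hand node loses its target modulation
as $\psi \to 0$ and its units progressively fail the screen, which is what
shrinks the hand class.

**Gradient analysis.** For each parameter pair ($T$–$H$, $T$–$E$, $H$–$E$;
third parameter fixed at $0°$) a $5\times5$ response matrix over
$\{-20,\dots,20\}°$ is differentiated by central differences (one-sided at
the edges, $10°$ step in the denominators). Because a relative variable is
indistinguishable from its inverse, each element gradient's angle is
*doubled* (magnitude kept) before summation — gradients along equivalent
axes then reinforce instead of cancelling. Unit resultants are summed per
node; hybrid populations combine the per-node *mean* resultants with
composition weights (default eye : hand : eye-and-hand = 0.25 : 0.50 :
0.25). Means rather than sums are used because the weights describe the
*composition* of a recorded population, and the node populations here have
very different sizes (about 200 : 15 : 225 after screening) — weighting raw
sums would let the large nodes swamp the intended 50% hand share. Reported
directions are the halved resultant angles, read against the parameter
axes ($T$ axis at $0°$, the $T-H$ diagonal at $-45°$); both raw and halved
angles are emitted. Gradients are computed on noiseless responses by
default, with a noisy mode for robustness checks.

## Design choices that were genuinely open

**Onset sampling.** "Uniform sampling" of onsets is implemented as an
evenly spaced grid from $-3\sigma$ to $3\sigma$ (endpoints included).
A deterministic grid keeps screened-unit counts stable across runs, which
the reported percentages depend on; a seeded uniform-random mode exists for
robustness checks.

**The five eye/hand pairs.** The delay task's eye/hand configurations are a
free design choice constrained only to the $\sigma/2$ position grid. The
default, $\{(0,0), (\pm\sigma/2, \mp\sigma/2), (\pm\sigma, \mp\sigma)\}$,
displaces eye and hand symmetrically to opposite sides, which (i) keeps
$TE$, $HE$ and $TH$ dissociable in the regression and (ii) spans
hand-in-eye positions out to $\pm2\sigma$, driving the semi-linear gain of
modulated units through its clipping region. The clipping matters: a unit
whose gain is partially suppressed across postures is exactly the kind of
unit the regression misclassifies as intermediate or indeterminate, and
with a narrower posture set (e.g. displacing only the eye by $\pm\sigma$)
virtually every eye-node unit classifies as eye-centered (≈97%) — the
heterogeneous classification structure of real populations only emerges
when the gain nonlinearity is exercised. The pair set is a config entry
(`eh_pairs`) so alternatives can be swapped in.

A consequence worth stating plainly: with clipping exercised, the *global*
noiseless optimum of the six-parameter fit sits slightly away from $w = 1$
for partially suppressed eye-node units (shifting $w$ moves the Gaussian
off-peak for exactly the clipped posture group, imitating the suppression).
Per-unit exact recovery of $w = 1$ and realistic misclassification rates
are therefore mutually exclusive regimes of the same generator; the package
defaults favor the realistic regime.

**Optimization.** All fits are box-constrained least squares. Starts come
from profiling the amplitude and baseline in closed form over a
deterministic grid of the nonlinear parameters (peak locations at the
targets, widths $\{10,15,20,25,30\}$, $w$ starts
$\{-1, 0, 0.25, 0.5, 0.75, 1, 2\}$); the best starts are polished by
bounded Levenberg–Marquardt. Ties break toward the smallest width and
smallest $|\mu|$ in the screen and toward $w$ closest to $0.5$ in the
reference-frame fit. The submodel solutions are included among the full
model's starts, which enforces the nesting inequality
$RSS_{full} \le RSS_{sub}$ numerically; a violation beyond tolerance raises
an error rather than producing a negative F statistic. Perfect fits are
handled explicitly: $RSS_{full} \approx 0$ yields $p = 0$ against a
misfitting submodel and $p = 1$ when both fits are perfect; constant
screening responses yield the degenerate zero-SVE fit rather than an
error. `grid_search_reference_frame()` is an independent brute-force
fitter (exhaustive lattice over $w, \mu, s, g$ with $(a, c)$ profiled in
closed form) used to validate the polished fits.

## What the generator does and does not emulate

The simulator reproduces the *population-level statistical structure* that
reference-frame analyses measure: heterogeneous weights, gain fields,
classification overlap, movement-epoch drift, and gradient rotations. It
does not emulate spiking variability (noise is additive Gaussian, not
Poisson), trial structure (one draw per condition), target-onset
transients, reaction-time variability, 2D/3D workspaces, or foveal
magnification of onset densities. Passing tests therefore show that the
analysis chain recovers the designed structure under idealized noise — not
that real recordings would behave identically.

## Problem sizes

The packaged analyses use the full populations ($30 + 2\times900$ units),
45 delay conditions and 10 simulation seeds for the noisy classification
percentages; the movement analysis re-runs the chain at 5 time points; the
gradient analysis covers 31 time steps and 3 parameter pairs. Unit tests
exercise the same code paths on reduced populations ($N = 6$–$10$).

## Known limitations

* The stepwise decision table is a reconstruction (see above); published
  stepwise procedures differ in detail.
* The pre-target responses of the alternative architectures are undefined
  (no published closed forms); requesting them is an error, and the
  static-displacement variant's gradient series therefore starts at the
  delay epoch.
* With onsets on a deterministic grid, screened-unit counts are step
  functions of the screening bounds; small changes to the SVE threshold or
  width bounds can move them by a few units.
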