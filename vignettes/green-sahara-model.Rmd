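---
title: "Modelling the rise and fall of green Sahara states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the rise and fall of green Sahara states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(greensahara)
```

## The model

North African vegetation and monsoon rainfall form a coupled system with a
positive feedback: more vegetation lowers albedo and recycles moisture,
which sustains more rainfall. `greensahara` implements an idealised,
non-dimensional version of this system. Vegetation cover $v$ ranges from
desert ($-1$, "yellow") to shrubland ($+1$, "green") and relaxes towards a
saturating function of rainfall,

$$\frac{dv}{dt} = \frac{1}{\tau_v}\left[\tanh(R) - v\right], \qquad
R = a + bP + cF + dv + N,$$

where $P$ is the climatic precession parameter
($\varepsilon \sin \varpi$; negative extremes mean strong Northern
Hemisphere summer insolation and a wetter Sahara, hence $b < 0$), $F$ is
the CO$_2$ radiative forcing relative to the preindustrial atmosphere,
$F = 5.35\,\ln(\mathrm{CO_2}/278)$ W m$^{-2}$ (so $c > 0$), $d$ scales the
vegetation–rainfall feedback, and $N$ is red noise representing
interannual soil-moisture variability,

$$\frac{dN}{dt} = \frac{\sigma\,\varsigma(t) - N}{\tau_N},$$

with $\varsigma$ unit-normal. Integration uses the explicit scheme

$$v_{k+1} = v_k + \frac{\Delta t}{\tau_v}\left[\tanh(R_k) - v_k\right],
\qquad
N_{k+1} = N_k - \frac{N_k \Delta t}{\tau_N} +
\frac{\sqrt{\Delta t}\,\sigma W_k}{\tau_N},$$

with $\Delta t = 1$ yr. The explicit one-year scheme is part of the method,
not a numerical convenience to be swapped out; the guard
$\Delta t \le \min(\tau_v, \tau_N)$ is enforced because sampled
soil-moisture timescales reach 1 yr.

Because $|\tanh| < 1$, the noiseless drift can never push $v$ out of
$[-1, 1]$. The stochastic system is *bimodal without being bistable* in
most regimes: for background rainfall $r = a + bP + cF$ away from zero the
noise is effectively biased towards one state, and transitions between the
green and yellow states are forced by the slow drivers rather than by pure
noise-induced escape.

## Equilibrium potential and threshold times

In the absence of noise the model is the gradient flow of

$$U(v) = \frac{v^2}{2} - \frac{\ln \cosh(r + dv)}{d},$$

whose critical points are the fixed points $v = \tanh(r + dv)$. The global
minimum of $U$ lies on the same side of $v = 0$ as $r$ (for $r \neq 0$),
so the time at which the minimum-potential state switches side — the
*threshold time* $t^*$ — is exactly a zero crossing of the background
rainfall:

$$\mathrm{sgn}(r_{t^*}) \neq \mathrm{sgn}(r_{t^* - \Delta t}).$$

`threshold_times()` implements the sign rule; the test suite verifies its
equivalence with a brute-force minimisation of $U$ on a $10^{-3}$
vegetation grid at every timestep for hundreds of random parameter draws.
`sgn(0)` is treated as positive; exact zeros of $r$ are vanishingly rare on
floating-point forcing, and the convention only matters for resolving ties.

The *simulated sensitivity* $SS(t)$ counts, per century, the screened
ensemble members whose threshold time falls in that century. A peak in
$SS$ marks a time when many not-implausible parameter settings would have
tipped — when the region was most susceptible to a forced state change.
Bins are left-closed and labelled by their older edge (a bin starting at
6100 yr BP covers $6100 \ge t > 6000$); the 3-point running average
truncates to the available neighbours at the series edges. Both
conventions are arbitrary but documented, so the outputs are exactly
reproducible.

## Ensemble screening

The seven parameters $(a, b, c, d, \tau_v, \tau_N, \sigma)$ cannot be
constrained individually. Instead a large ensemble is drawn uniformly from
broad ranges and screened against one robust observation: the number of
green episodes (Mediterranean sapropels) over the last two glacial cycles,
230–20 ka BP. Members whose simulation shows exactly the required count
(six by default) are retained as "not implausible"; the timing of the
episodes is deliberately not matched, because the dating of pre-Holocene
humid periods carries millennial errors while their number is secure.
Screened members are then integrated through the Holocene with the same
noise stream, and their Holocene collapse threshold time feeds $SS(t)$.

Default sampling ranges are engineering choices, overridable via
`param_ranges()`: $a \in [-2, 0.5]$ (background rainfall generally
negative, so green is episodic), $b \in [-40, 0]$, $c \in [0, 1]$
(W m$^{-2}$)$^{-1}$, $d \in [0.5, 1.5]$ (a wider bracket than the
0.8–1.2 used in earlier single-run studies), $\tau_v \in [5, 100]$ yr,
$\tau_N \in [1, 20]$ yr, $\sigma \in [0.1, 2]$.

A green *episode* is defined operationally: boxcar-smooth $v$ over
1,000 yr, mark smoothed $v > 0$, merge green intervals separated by gaps
under 2,000 yr, and drop episodes shorter than 2,000 yr. The smoothing
window targets millennial (sapropel-like) features; the merge and duration
thresholds suppress noise flicker around episode edges. All three knobs
are exposed in `detect_green_events()`.

When a member's background rainfall wiggles across zero several times in
the Holocene, its collapse time is the first collapse-direction crossing
after its last onset crossing (`holocene_collapse()`, rule
`"after_last_onset"`); the alternative `"first"` rule is provided. Members
that turn green and never cross back before present are flagged
`never_leaves_green`; they contribute no collapse time, which is why
excluding them provably leaves $SS$ unchanged — an invariant the tests
assert.

## Synthetic study conditions

No forcing data ship with the package; `make_forcing()` generates an
analytic stand-in whose structure matches what the real drivers
contribute:

* precession: two sinusoids with the 23.7- and 22.4-kyr quasi-periods,
  amplitudes 0.035 and 0.02, under a 100-kyr amplitude modulation of depth
  0.5 standing in for eccentricity. The default phases place a joint
  precession minimum (wet phase) at 12 ka BP, mimicking the early-Holocene
  insolation maximum;
* CO$_2$: an asymmetric 100-kyr sawtooth between 190 and 280 ppm (slow
  glacial decline, fast deglacial rise completing at 10 ka BP), converted
  through the logarithmic forcing law.

This reproduces the essential phenomenology — discrete precession-paced
humid windows, suppressed during glacials and enabled at deglaciations —
but not the irregular multi-line spectrum of a real orbital solution, nor
dating structure of real ice-core CO$_2$. Real series are supplied as CSV
through `load_forcing()` (linear interpolation to the annual grid, no
extrapolation, explicit time units only — a ka-versus-years guess would be
a silent thousand-fold error). Passing tests on the synthetic fixture
validate the machinery and the method's internal consistency; quantitative
statements about the real system additionally require the real forcing
series and sampling ranges chosen for it.

`make_truth_study()` closes the loop: it tunes the truth member's offset
$a$ (coarse scan, then bisection on the episode count, which grows with
$a$ on the relevant branch) until the 230–20 ka window holds exactly six
green episodes, then emits the truth trajectory, a noisy Ba/Al-like proxy
trace, replicate 500-yr binned wet/moderate/dry state tables with known
collapse dates, and the truth member's threshold events recomputed by an
independent 10-yr-resolution scan of the background-rainfall sign.

## Proxy collapse dating

Observed records enter as already-classified hydroclimate states (wet,
moderate, dry) on a 500-yr grid. The humid-period termination of a record
is dated as the first bin, scanning forward from the record's earliest wet
bin, whose state is no longer humid. "Humid" means `wet` only by default —
`moderate` reads as semi-arid — but this is a `humid_states` argument.
Records south of a configurable latitude cut (13.42° N matches the
southern limit of the associated population reconstructions) can be
excluded from the histogram.

## Numerical choices and degenerate inputs

* Initial conditions: $v_0$ defaults to the noiseless equilibrium under
  the oldest forcing value (root-finding on $v = \tanh(r + dv)$), $N_0 =
  0$, followed by a 1,000-yr spin-up at held forcing that is discarded.
  This removes transients of order $\tau_v$; the choice is configurable.
* Reproducibility: member $i$ uses seed `base_seed + i`; the Holocene
  extension re-runs the member from 230 ka with the same seed, so the
  Pleistocene part of its noise stream is bit-identical and simply
  continues. Compiled (Rcpp) and pure-R integrators consume the same draw
  stream and agree to machine precision.
* $\ln \cosh$ is evaluated as $|x| + \log(1 + e^{-2|x|}) - \ln 2$ to avoid
  overflow; `potential()` rejects $d = 0$, where the expression is
  undefined.
* `min_potential_state()` locates all fixed points in $[-1.5, 1.5]$ by a
  601-point sign scan plus `uniroot` refinement and returns the one with
  minimal $U$; at an exact tie (bistable $r = 0$) the non-negative state
  is returned, matching the $\mathrm{sgn}(0) = +$ convention.
* Degenerate sampling ranges (width $\to 0$) are allowed; zero noise
  ($\sigma = 0$) gives $N \equiv 0$ exactly.

## Problem sizes

The package's reference experiment — used by the test suite and
`scripts/acceptance.R` — screens 2,000 sampled members plus the truth
member over 230–0 ka at annual resolution, extends the survivors through
the Holocene, and replicates a 500-member version three times. This runs
in a few minutes on one CPU; the ensemble size trades Monte-Carlo
smoothness of $SS(t)$ against runtime and is a package choice, scaled down
from the 100,000-member experiment the method is designed for. With only a
few dozen survivors per replicate the location of the $SS$ peak wobbles by
on the order of a millennium between replicates; at the full ensemble size
the temporal structure is far more stable.

## Known limitations

* The screening criterion is a hard equality on the episode count; there
  is no likelihood weighting or posterior (no history matching beyond
  counting).
* The potential analysis uses the noiseless landscape; no Kramers-type
  escape-rate correction is applied, so threshold times mark forcing-driven
  susceptibility, not expected stochastic transition times.
* The proxy-state generator classifies smoothed vegetation with fixed
  thresholds ($\pm 0.3$); real proxy classification is a subjective,
  record-specific judgement consumed here as given.
* The synthetic precession is a two-tone caricature; conclusions about
  real chronologies require user-supplied orbital and ice-core series.
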