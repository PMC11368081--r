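---
title: "How ankle position corrupts flight-time jump height, and how to correct it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How ankle position corrupts flight-time jump height, and how to correct it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpsim)
library(dplyr)
```

## The problem

The flight-time (FT) method turns an airborne duration into a jump
height, $\hat h = g\,FT^2/8$. The derivation assumes the centre of mass
(CoM) leaves and returns at the same height. Jumpers, however, take off
plantarflexed (on their toes) and tend to land with a flatter, more
dorsiflexed foot. The CoM then lands *lower* than it took off, the body
stays airborne longer than the symmetric model assumes, and the method
overestimates the jump. Changes of 10–20° at the ankle are common and
hard to see in real time, which makes this a systematic, practically
invisible error.

`jumpsim` simulates that error over a dense factorial design and
implements an anthropometric correction that recovers the true height
from the measured flight time plus two ankle angles and a single body
measurement.

## The body model

A planar four-segment chain — foot, shank, thigh and a combined
head-arms-trunk (HAT) segment — is scaled to stature $H$ and stands on a
single leg whose segment masses are doubled, so the mass fractions sum
to one over four segments: foot 0.029, shank 0.093, thigh 0.200, HAT
0.678 (Winter's per-limb values doubled, HAT as the remainder). The
chain's origin is the tiptoe. The foot geometry is fixed by three
stature fractions: foot length $0.152\,H$, standing ankle (lateral
malleolus) height $0.039\,H$, and a tiptoe-to-ankle horizontal distance
of 78.7% of foot length. The straight tiptoe-to-ankle distance is
therefore

$$l_{at} = \sqrt{(0.039H)^2 + (0.152 \times 0.787\,H)^2} \approx 0.12582\,H,$$

which rounds to the familiar $0.126\,H$; the package always uses the
exact expression, treating 0.126 as a display rounding. The line makes a
natural angle $\beta = \arctan(0.039 / (0.152 \times 0.787)) \approx
18.06°$ with the floor, identical for all statures.

Plantarflexing the ankle by $\alpha$ (degrees above flat-foot; knee and
hip stay extended) rotates the tiptoe-ankle line about the tiptoe, so
the ankle rises by $l_{at}(\sin(\alpha+\beta) - \sin\beta)$. Everything
above the foot translates rigidly with the ankle; the foot CoM, placed
at the midpoint of the tiptoe-ankle line, rises half as far. The
CoM *difference* between two postures is therefore

$$h_{diff} = h_{land} - h_{to} = \underbrace{(1 - m_{foot}/2)}_{0.9855}
\, l_{at}\,\big(\sin(\alpha_{land}+\beta) - \sin(\alpha_{to}+\beta)\big),$$

negative for a flatter landing. A useful structural fact, which the test
suite verifies by perturbation: the shank, thigh and HAT length and CoM
fractions cancel exactly from $h_{diff}$, because those segments only
translate. They matter solely for the absolute standing CoM height,
which nothing downstream consumes. The foot CoM location is the one
genuinely free parameter; the midpoint is the natural symmetric choice
and the headline results are insensitive to it at the sub-millimetre
level (it moves $h_{diff}$ by at most $m_{foot}/2 \approx 1.5\%$ of the
ankle raise).

## Flight, error and correction

With $V_{to} = \sqrt{2gh}$ and a signed $h_{diff}$, the measured flight
time solves the landing-height crossing of a point projectile:

$$FT = \frac{V_{to} + \sqrt{V_{to}^2 - 2\,g\,h_{diff}}}{g},$$

and the FT method reports $\hat h = g\,FT^2/8$ with percentage error
$(\hat h - h)/h \times 100$. Composing the pipeline algebraically gives

$$\hat h = \frac{(\sqrt{h} + \sqrt{h - h_{diff}})^2}{4},$$

in which $g$ cancels: the *percentage* error is exactly
$g$-independent, so the choice of $g = 9.81\ \mathrm{m\,s^{-2}}$
(configurable everywhere) affects absolute times only. The suite checks
this to $10^{-10}$ relative between 9.81 and 9.80665.

The correction inverts the flight equations. Because $h_{diff}$ is not
measurable without motion capture, it is replaced by the anthropometric
estimate

$$\hat h_{diff} = l_{at}\big(\sin(\alpha_{to}+\beta) -
\sin(\alpha_{land}+\beta)\big), \qquad
\hat h_c = \frac{1}{2g}\Big(\frac{g\,FT}{2} -
\frac{\hat h_{diff}}{FT}\Big)^2.$$

Two sign conventions coexist here and are easy to conflate: the flight
equations use the *landing-minus-takeoff* $h_{diff}$ (negative for a
flatter landing), whereas the correction's $\hat h_{diff}$ is oriented
*takeoff-minus-landing* (positive in the same scenario). The package's
canonical internal quantity is the signed landing-minus-takeoff value;
`corrected_height()` accepts the positively-oriented estimate and
negates it internally, so the round trip
`true_height_from_flight(measured_flight_time(v, hd), hd) = h` is exact
to $10^{-12}$ and a flatter landing always yields a *smaller* corrected
height than $g\,FT^2/8$. Each function's documentation states which
orientation it expects.

$\hat h_{diff}$ omits the foot-mass shrinkage factor 0.9855, so the
correction is not a perfect inverse: over the default grid the corrected
heights stay within 2 mm of truth (about 1 mm at the worst case), which
is what makes the corrected-versus-true regression's $r^2$ round to 1.00
rather than equal 1 exactly. Correcting with the exact model $h_{diff}$
instead gives slope 1, intercept 0 and $r^2 = 1$ to machine precision —
the suite tests both.

## The simulation design

`jump_grid()` reproduces the reference study conditions by default:

* 100 statures evenly spaced on $[1.435, 1.984]$ m — three standard
  deviations below the female average to three above the male average;
* takeoff plantarflexion fixed at 40°, with the landing angle reduced by
  a change of 0–40° in 1° steps (41 positions; 40° is the flat-foot
  landing, the largest change the model admits);
* true jump heights 0.10, 0.20, 0.30, 0.40 m ("poor" to "above
  average");

i.e. 16,400 conditions. The takeoff angle and the 1°-step change set are
the one place the design is stated indirectly (only the position count
and the flat-foot endpoint are fixed); 40° takeoff with integer-degree
changes is the unique choice consistent with both, and it reproduces the
published worked examples within rounding. The per-condition pipeline is
entirely closed-form — no randomness, no integration — so a run is
deterministic down to byte-identical CSV output, and the full grid takes
well under a second. All tests and the acceptance script run the full
16,400-row design.

```{r grid}
sim <- jump_grid() |> simulate_jumps()
max_error(sim) |> select(stature_m, jump_height_m, change_deg, h_error_pct)
validate_correction(sim, h_max = 0.20)
```

Worst affected are tall bodies (longer feet, larger $l_{at}$) doing low
jumps (short flights, so a fixed extra airborne time inflates the
relative error most) with large ankle changes; the error surface is
strictly monotone in all three axes, which the suite checks slice by
slice.

## What the simulation does and does not emulate

The generator *is* the study: a deterministic geometric model of one
error mechanism. It emulates the ankle-position change between takeoff
and landing and nothing else. Real jump measurements also contain device
timing quantization, knee/hip/torso posture changes, arm swing and
biological trial-to-trial variability — none of which are modelled, so
passing tests demonstrate the internal consistency of the
ankle-mechanism model and its correction, not the total error budget of
any real device. Absolute standing CoM heights are likewise nominal
(they cancel from every reported quantity). The anthropometric fractions
are population averages; per-individual foot geometry will deviate, and
the correction inherits that deviation through $l_{at}$.

## Numerical choices

* Angles are degrees at every interface and radians internally.
* $l_{at}$ and $\beta$ always come from the exact component expressions,
  never the rounded 0.126 coefficient.
* At $h_{diff} = 0$ the flight pipeline reduces algebraically to the
  symmetric case ($FT = FT_{true}$, $\hat h = h$); the code applies
  those reductions explicitly so that zero-change conditions report an
  error of exactly zero instead of a $10^{-14}$ ulp residue.
* Degenerate inputs: $h = 0$ is allowed in the forward ballistic
  operations (all-zero flight) but rejected by the percentage error,
  which is undefined there. A landing height above the apex
  ($h_{diff} > h$) raises an "unreachable landing height" error rather
  than producing complex arithmetic. Stature is sanity-bounded to
  (0.5, 3) m.
* The validation regression is ordinary least squares with intercept,
  via `stats::lm()`; its $r^2$ is reported at full precision and rounded
  to two decimals only for display parity.

## Known limitations

The model is two-dimensional, single-joint and quasi-static at the
posture level: it cannot speak to arm-swing compensation, bilateral
asymmetry, or the interaction between ankle and knee changes. The
correction requires the two ankle angles, typically from 2D video; its
accuracy degrades with the accuracy of those angles, which is not
simulated. Device timing resolution — often the second-largest error
source for FT methods — is deliberately out of scope.
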