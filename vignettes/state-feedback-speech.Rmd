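---
title: "A state-feedback control model of speech motor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A state-feedback control model of speech motor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`speechsfc` simulates speech production as hierarchical state feedback
control. The controlled quantities are not articulator positions but seven
*constriction task variables* — lip aperture (LA) and protrusion (PRO),
tongue-body and tongue-tip constriction degree and location (TBCD, TBCL,
TTCD, TTCL), and velic aperture (VEL). An utterance is specified as a
*gestural score*: a timed schedule of gestures, each of which drives one
task variable toward a target with critically damped second-order
point-attractor dynamics,

$$\ddot x = M^{-1}\left(-B\,\dot{\tilde x} - C\,(\tilde x - x_0)\right),$$

evaluated on the *estimated* task state $\tilde x$. The task command is
mapped to articulator accelerations through the weighted Jacobian
pseudoinverse of the task-to-articulator kinematics,

$$\ddot a = J^*(\tilde a)\,\ddot x - J^*(\tilde a)\,\dot J(\tilde a,
\dot{\tilde a})\,\dot{\tilde a},$$

optionally augmented with a null-space attractor (below). The plant
integrates the command with classical fourth-order Runge–Kutta, adds motor
noise, and emits two noisy sensory streams: a 20-dimensional somatosensory
channel (articulator positions and velocities, identity map) and a
3-dimensional auditory channel (formants F1–F3).

Neither controller sees the plant directly. An *observer* — an
augmented-state unscented Kalman filter (UKF) — integrates the efference
copy of each motor command through the same integrator the plant uses,
predicts the sensory consequences (the auditory branch through a *learned*
articulatory-to-formant map), and corrects the predicted state with the
Kalman-weighted sensory prediction errors. Task-level state is then
re-derived from the corrected articulatory estimate by forward kinematics
($\tilde x = f(\tilde a)$, $\dot{\tilde x} = J\,\dot{\tilde a}$), closing
the loop with a one-step delay.

## The surrogate vocal tract

The plant geometry is deliberately simple but preserves the features the
control problem needs — smoothness, nonlinearity, and redundancy. A fixed
temporomandibular joint sits at the origin; the palate/pharynx outline is
the polar curve $R(\varphi) = R_0 + R_1 \cos(\varphi - \varphi_0)$
(defaults 5.0 cm, 0.8 cm, $\pi/2$); the tongue body is a circle of radius
2 cm centered at polar position (CL, JA + CA); the tongue tip rides at
polar offset (TTL, TTA) from the tongue-body center. TBCD is the radial
gap between tongue surface and outline; LA couples the lip verticals with
the jaw angle ($\kappa_j = 2$ cm/rad). The jaw therefore participates in
both lip and tongue constrictions — the redundancy that the mechanical
perturbation experiment exploits.

Acoustics are a closed-form formant map driven only by (TBCD, TBCL, PRO):
with $d = \max(\mathrm{TBCD}, 0)$ and coupling $c(d) = e^{-d/0.5}$, F1–F3
are sums of a neutral value (500, 1500, 2500 Hz) and constriction terms.
The map is calibrated so a tight palatal constriction yields (310, 2200)
Hz and a wide tract (500, 1500) Hz — consistent with the formant ranges
the forward-model fit is benchmarked against. It is many-to-one in the
articulators by construction, which is the property that makes auditory
state estimation genuinely ill-posed.

## The learned auditory forward model

The observer's auditory prediction uses a map trained on self-generated
"babbling": low-pass-filtered random walks through the articulator range
box, paired with noise-free formants from the plant. The learner is a
locally weighted projection-regression scheme:

1. a global cubic polynomial ridge fit provides gradient estimates whose
   averaged outer product identifies the low-dimensional *regression
   subspace* the formants actually vary along (3–5 of 10 dimensions; the
   babble dimensions are sampled near-independently, so the subspace
   estimate is clean);
2. Gaussian receptive fields are placed at k-means centers of the
   projected inputs (default 2400 fields, bandwidth 0.8 times the
   within-cluster RMS radius — defaults chosen to meet the held-out error
   budget of 4.2 Hz for F1 and 6.6 Hz for F2 at the default training size
   of 5×10⁴ samples);
3. each field fits a local quadratic by weighted ridge regression, and
   predictions blend the local models with normalized field weights.

Inference is deterministic. `tidy()` exposes per-field centers,
bandwidths, and local sample counts; the test suite shows causally (by
depleting a region of training data) that sparse coverage degrades local
fit.

## Noise model and calibration

Noise levels are dimensionless: the standard deviation on a channel is
`level × norm`, where the norms are RMS values per channel group
(positions, velocities, formants, motor command) measured once from a
noiseless, unperturbed run of the same score with an ideal observer. The
baseline levels are 1e-4 (motor/process), 1e-2 (auditory), 1e-6
(somatosensory), and the observer's internal noise estimates equal the
true levels unless overridden. Channel gating (somatosensory-only,
auditory-only, none) removes observation rows categorically rather than
inflating their noise.

## Numerical choices

* **Unscented transform.** Scaled parameterization with
  $\lambda = \alpha^2(L + \kappa) - L$, $\alpha = 10^{-3}$, $\kappa = 0$,
  $\beta = 2$; augmented state = articulatory state (20) + process noise
  (10) + observation noise (23), noise blocks re-centered each step.
* **Covariance update.** $P \leftarrow P - K P_{yy} K^\top$, with $P$
  propagated across steps and initialized as $10^{-2} I$; process and
  observation blocks are the respective noise covariances.
* **Innovation sign.** Corrections use the standard innovation
  $y - \hat y$ with $+K$. The equivalent formulation with
  $\Delta y = \hat y - y$ requires $-K$; composing $\hat y - y$ with $+K$
  would drive the estimate away from the observations, so the standard
  convention is used and documented here deliberately.
* **Conditioning.** Internal noise variances are floored at $(10^{-8})^2$
  so that sigma-point deviations stay resolvable in double precision under
  zero-noise configurations. Covariances are kept symmetric; when
  round-off pushes one off the PSD cone, eigenvalues are floored at
  $10^{-12}$ of the spectral radius. A matrix indefinite beyond that is
  treated as filter failure, and the trial is flagged divergent (a trial
  is also divergent when any true or estimated articulator strays more
  than 5× its range-box extent from the box center). An ill-conditioned
  innovation covariance (condition number above $10^{12}$) is inverted by
  eigenvalue-truncated pseudo-solve.
* **Pseudoinverse.** $J^* = W^{-1} J_a^\top (J_a W^{-1} J_a^\top +
  \varepsilon I)^{-1}$ with $\varepsilon = 10^{-8}$ and $W = I$ by
  default.
* **Integration.** dt = 5 ms for control and integration; trials of
  1.0–1.5 s (200–300 steps). RK4 is exact for the piecewise-constant
  accelerations used here, and the observer shares the plant's integrator
  bit-for-bit, which makes the noiseless efference-copy prediction exact.

## Design decisions in the open

* **Inactive tasks.** Gestural activation is a step function; inactive
  tasks receive a zero task-space command. Uncontrolled articulator drift
  is bounded instead by a **null-space attractor** toward the neutral
  posture, $(I - J^*J_a)(-k_n(a - a_0) - b_n \dot a)$ with $k_n = 10$ s⁻²
  and critical $b_n$; it cannot disturb active tasks (the projector
  annihilates it in task space) and can be switched off.
* **Jaw perturbation.** "Fixing the jaw in place" is implemented as a
  position clamp (the jaw angle frozen, velocity zeroed), with a
  constant-bias-acceleration variant behind `jaw_clamp$mode = "bias"`.
  The clamp is scheduled from the midpoint of the consonant gesture's
  activation interval to the end of the utterance, and the observer is
  not told. The bundled [aba]/[ada] scores use a closure gesture whose
  activation midpoint falls mid-movement, so the clamp catches the jaw
  on its way to closure.
* **Fixture scores.** All gesture targets, stiffnesses (400 s⁻², settling
  in ≈0.3 s) and durations are repository constants calibrated to the
  surrogate plant, not measurements of any utterance.

## What the simulations show — and a caveat about noise scales

The packaged experiments reproduce the architecture's qualitative
signatures: task-specific compensation to jaw clamping (lip response for
a bilabial, none for a tongue-tip closure); monotone opposite noise-sweep
trends (somatosensory-only accuracy improves as its noise shrinks;
auditory-only accuracy *worsens*, because a more trusted auditory channel
pulls the estimate through a many-to-one map); and destabilization of the
auditory-only regime at very low noise, which never happens with
somatosensory feedback.

Two quantitative outcomes deserve an honest caveat, both rooted in the
same precision arithmetic. With the baseline levels, somatosensation
observes the full state with noise four orders of magnitude below the
auditory channel's state-equivalent noise. A correctly weighted filter
then gives the auditory innovation a steady-state influence of roughly
$\sum_k g_k^2\,r_{somat}/r_{aud}$ (with $g$ the formant sensitivities in
Hz per state unit) — about $10^{-9}$ of a perceived-formant shift. The
acceptance computation accordingly reports a compensation many orders of
magnitude below the shift at the default configuration. The compensation
mechanism itself is sound: when somatosensory noise is raised so the two
channels carry comparable information (levels of order $10^{-1}$), the
model produces a positive, partial compensation that increases with
somatosensory noise and decreases with auditory noise, exactly the
trade-off the mechanism tests assert. Likewise, under feedback
deprivation, auditory-only variability exceeds the no-feedback condition
at the defaults: the chasing noise injected by a trusted-but-ambiguous
auditory channel is larger than the open-loop motor-noise drift at these
scales. The orderings auditory-only > somatosensory-only (variability)
and none > both (prediction error) are robust.

## Problem sizes used by the packaged checks

The test suite trains the forward model at the study size (5×10⁴
samples), runs 100 trials per feedback condition for the deprivation
experiment with 1000-resample bootstrap intervals, 25 trials per level
for the noise sweeps over levels $10^{-2}$–$10^{-8}$, and 20 seed pairs
for the perturbation experiment; unit tests use a 6×10³-sample map.

## Limitations

The plant is kinematic: no tissue dynamics, gravity, or muscle model, and
no waveform synthesis. Sensory transmission is instantaneous — no
delays — which is known to matter for speech. Gestural scores are inputs;
no linguistic planning, no gesture blending on a shared task variable, no
activation ramps. The surrogate geometry and formant map are calibrated
stand-ins, so quantitative results (variability magnitudes, compensation
percentages) are specific to this plant even where the qualitative
structure is general. Passing tests on babbled synthetic data show that
the learner meets its error budget on a smooth, exactly-realizable map;
real articulatory-to-acoustic data are noisier and less stationary.
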