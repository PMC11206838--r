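---
title: "Methods: delayed CoM feedback reconstruction of reactive balance EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed CoM feedback reconstruction of reactive balance EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Reactive muscle activity during a perturbation of stance is modelled as
delayed linear feedback of task-level body motion: the anterior-posterior
position of the centre of mass (CoM) relative to the ankle, its velocity,
and its acceleration. Each muscle receives two half-wave rectified
channels. The *balance-correcting* pathway drives a muscle when the CoM
moves in the direction that muscle opposes (plantar flexors for forward
motion, tibialis anterior for backward motion). The *antagonistic* pathway
is the mirror image — it drives the muscle for CoM motion in the opposite
direction — and its gains (the "prime" gains k′) quantify co-activation
drive: in a nervous system with intact reciprocal inhibition they should
be near zero.

For a plantar flexor:

    EMG_recon(t) = ⌊ e0 + k_d d(t−τ) + k_v v(t−τ) + k_a a(t−τ) + k_s a_init(t−τ) ⌋
                 + ⌊ k_d′ (−d) + k_v′ (−v) + k_a′ (−a) ⌋ (t−τ)

and for tibialis anterior the signs of d, v, a are flipped in both
pathways and the stiction term is absent. Assumptions worth keeping in
mind:

* **A single common delay** τ = 100 ms stands in for all neural
  transmission and processing; it is not estimated.
* **Rectification** ⌊·⌋ represents excitatory drive to a motor pool;
  inhibitory surpluses are simply not expressed, which makes the model
  piecewise linear rather than linear.
* **The stiction term** a_init is the CoM acceleration gated from
  perturbation onset until the ankle angle has changed 0.5°, a proxy for
  the initial spindle burst tied to muscle short-range stiffness. It is
  absent for tibialis anterior, which is shortened first in this
  perturbation direction, and the gated signal is zero before onset.
* **Task-level feedback only**: joint-angle feedback models are out of
  scope by design.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| τ (delay) | 0.100 | s | physiological transmission + processing time; an exact 10-sample shift at the 100 Hz analysis rate |
| gain bounds | [0, 10] | /m, s/m, s²/m | box constraints of the estimation problem; negative gains are not physiological in this parameterisation |
| prime-gain penalty | 1e-4 | — | discourages antagonistic drive unless it clearly improves the fit |
| stiction threshold | 0.5 | deg | approximate ankle rotation that exhausts short-range stiffness |
| fit window | [−0.5, 1.5] | s | covers quiet stance (anchoring e0 and baseline) plus the full response |
| GOF window | [0, 1.5] | s | post-onset response only |
| EMG band-pass | 10–450 | Hz | interference-signal content; 450 Hz requires fs > 900 Hz |
| envelope low-pass | 40 | Hz | linear-envelope smoothing |
| Savitzky–Golay | order 5, window 11 | — | acceleration from velocity without amplifying noise |
| time bins (EMG) | 0–150–250–400 | ms | quiet period, first plantar flexor peak, switch to tibialis anterior |
| time bins (kinematics) | shifted −100 | ms | the kinematics are the sensory cause of the binned EMG |
| CCI windows | [0, 0.4), [−0.5, 1.5) | s | reactive window; full model window |

## Fitting

The cost is the sum of squared differences between reconstructed and
measured envelope over the fit window plus `1e-4 · Σ k′²`. e0 is **not**
optimised: it is the mean of the measured scaled envelope over
[−0.5, 0) s. (The source description of e0 — "the measured data 0.5 s
before onset" — is ambiguous between a point value and a window average;
the window average is used because a single sample of a noisy envelope is
a poor anchor. This is a deliberate, configurable reading.)

Because rectification makes the cost piecewise smooth, gains are fitted by
bounded multi-start L-BFGS-B with an analytic subgradient: starts at the
origin, the centre of the gain box, and six seeded uniform points in the
lower part of the box, followed by a high-precision polish from the best
local solution. The fit is deterministic given the configured seed. Gains
within 1e-6 of a bound are flagged (`at_bound`). The simple model variant
pins the prime gains at zero and optimises only the balance-correcting
gains, so the simple problem is nested in the extended one and the
extended optimum can never be worse — the percent cost improvement
`100·(simple − extended)/simple` is non-negative whenever both fits
converge, and the test suite asserts this over 100 seeded fits.

Two cost conventions are fixed and documented rather than configurable:
the fit-window sum is over raw samples at the analysis rate (100 Hz), so
the effective weight of the prime-gain penalty is tied to that rate; and
delayed regressor samples that would precede the recording are filled with
the channel's quiet-stance (pre-onset) mean, which avoids discarding
fit-window samples and is exact for signals at rest before onset.

## Numerical choices

* **Zero-phase filtering.** Both Butterworth stages are applied
  forward-backward (odd signal extension, steady-state initial
  conditions). The source chain does not state phase handling; causal
  filtering would lag the envelope by tens of milliseconds, which would
  bias 100–150 ms time bins, so zero-phase is the defensible choice. The
  stated 4th order is the design order per pass. Filters are implemented
  as cascaded biquads from the analog Butterworth prototype via the
  bilinear transform (no DSP package is assumed); during development the
  design was checked against an independent reference implementation —
  identical coefficients, agreement to ~1e-7 away from boundaries.
* **Negative envelope samples** after the low-pass are floored at zero: a
  rectified signal is non-negative by meaning, low-pass ringing can
  undershoot.
* **Analysis grid.** All modelling happens at 100 Hz (the kinematic rate)
  over [−0.6, 1.5] s, with EMG envelopes decimated after the 40 Hz
  low-pass. 100 Hz sampling of a 40 Hz-limited envelope is marginal
  against Nyquist; it is accepted because the delay becomes an exact
  integer shift and the envelopes are strongly oversmoothed relative to
  the bin widths. Resampling is piecewise linear (no overshoot on
  already-smoothed signals).
* **Derivatives.** CoM velocity is a central difference; acceleration is
  a first-derivative Savitzky–Golay filter (order 5, window 11), exact
  for quintic polynomials in the interior. The first and last five
  samples come from one-sided fits of the terminal windows and carry no
  interior accuracy guarantee.
* **CoM re-smoothing** before differentiation is available as a config
  toggle (default off): in the source pipeline joint angles are low-pass
  filtered upstream of CoM computation, a step that lives outside this
  package's input format.
* **Half-open bins and windows** `[start, end)` prevent double counting;
  membership is by time stamp, so non-100 Hz grids work.
* **Weights.** ω = 1/var(y) within each outcome × group × condition cell;
  variances below 1e-8 are floored with a warning so a degenerate
  synthetic cell cannot dominate a fit.
* **Mixed models** are estimated by maximum likelihood (lme4) and effects
  are tested by likelihood-ratio tests; the estimation method and
  degrees-of-freedom correction are not stated in the source analysis, so
  ML + LRT was chosen for nesting consistency and calibration is verified
  by simulation (null rejection rate within the binomial band around 5%).
  Participants are nested within group; with globally unique subject ids
  a single per-subject random intercept encodes exactly that.
* **Holm correction** is implemented as the explicit step-down rule and
  reported with the step-wise alpha levels; families are one per outcome
  type (bins, CCI, gains, cost improvement) and are explicit in the
  configuration, because the source does not enumerate them.

## The synthetic generator: what it does and does not establish

The generator is signal-level, not mechanistic. Platform profiles are
raised-cosine displacement pulses (backward translation, then a toe-up
rotation delayed 150 ms); level amplitudes are chosen so translation
displacement repeats L1=L2 < L3=L4 while peak platform velocity and
acceleration grow with every level. CoM and ankle trajectories are smooth
pulses with the qualitative structure that matters to the analysis: a
forward CoM excursion that reverses exactly once, and early monotone
dorsiflexion crossing 0.5° before 150 ms. Amplitudes (forward CoM peak
2–6 cm, ankle dorsiflexion 3–7°) are what a paediatric balance lab would
call realistic for moderate platform perturbations; they were fixed once,
up front. EMG envelopes are produced by running the feedback model
forward from known gains plus clipped Gaussian envelope noise (default sd
0.02 normalised units — a few percent of a typical response peak), with a
2% lognormal-style amplitude jitter on the kinematics across trials, and
a tonic baseline e0 = 0.05. Group archetypes encode the scientific
contrast: TD-like prime gains near zero; CP-like balance-correcting gains
roughly doubled and the prime velocity gain five times the TD-like value.
Per-subject gains vary lognormally (sd 0.25 on the log scale) around the
archetype. An optional raw-EMG mode amplitude-modulates band-limited
noise so the full filter chain can be exercised.

Because the envelopes are generated by the *same equations* the fitter
inverts, a green recovery test establishes that the estimation machinery
inverts the forward model correctly — it does **not** establish that real
EMG follows the model, that real CoM trajectories look like these pulses,
or that the archetypes match any clinical population. Real data also
contain artifacts, non-stationary baselines, heteroscedastic noise and
electromechanical delays that the generator deliberately omits.

## Identifiability and the recovery criterion

Two effects limit exact gain recovery even from noiseless data. First,
structural: a gain multiplying a regressor that is never expressed inside
the rectified active region cannot move the reconstruction
(`gain_identifiability()` flags this by the norm of the masked regressor).
Second, the prime-gain penalty shifts the global optimum away from the
truth by a predictable amount: linearising with the rectification masks
fixed at the truth, the penalised optimum is

    truth − λ (JᵀJ + λP)⁻¹ P · truth

with J the masked regressor matrix and P the prime selector. For
near-collinear prime regressors (prime displacement here) this bias can
exceed one percent although the gain is structurally identifiable; the
fitted optimum matches this closed form and has *lower* cost than the
truth, so it is a property of the stated cost, not an optimiser failure.
`recoverable_gains()` therefore reports a gain as recoverable at relative
tolerance r when it is structurally identifiable, strictly positive, and
its predicted penalty bias is below r/2 — and the recovery acceptance
tests assert 1% (noiseless) and 15% median (noisy) on exactly that set.
The long-window CCI separates groups less than the reactive-window CCI in
this stated world (both groups share the same tonic baseline, which
dominates the long quiet tail), so detection-rate acceptance is evaluated
on the reactive-window CCI.

## Known limitations

* The delay τ is fixed, not estimated; systematic subject-level delay
  differences would alias into the gains.
* Kinematic-bin Z1 starts at onset rather than −50 ms, so the "shift by
  100 ms" correspondence between EMG and kinematic bins is exact only for
  Z2/Z3.
* At 100 Hz the 40 Hz envelope sits close to Nyquist (see above).
* Savitzky–Golay edge samples are one-sided estimates.
* The generator's trials are exchangeable within a level; it does not
  model fatigue, adaptation, or stepping that depends on the response
  itself (stepping is an independent Bernoulli flag used to exercise
  exclusion logic).
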