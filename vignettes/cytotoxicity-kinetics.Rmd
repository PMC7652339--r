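---
title: "Disentangling T-cell killing and proliferation from live-cell imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling T-cell killing and proliferation from live-cell imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Imaging-based killing assays co-culture engineered T cells (effectors) with
adherent, peptide-loaded target cells in a 384-well plate and scan each well
every 2-4 hours in three channels: phase contrast (target confluency), green
(a vital dye loaded into the effectors), and red (Annexin V / propidium
iodide marking dead and dying cells). Three per-well measurements result at
each scan: the live effector count `E_live` (green-positive, red-negative
objects), the total red pixel area, and the phase-occupied pixel area.
`tcellkin` turns those raw series into per-cell kinetic quantities that
separate two conflated phenotypes — antigen-dependent proliferation and
antigen-dependent cytotoxicity — and summarises each as a dose-response
(EC50, Emax) per receptor construct and effector:target (E:T) ratio.

# The kinetic quantities

All quantities are computed on a 6-hour grid anchored at the 2-hour settling
scan (t0 = 2 h; earlier scans are unreliable because cells have not settled).
Native 2-h or 4-h cadences are linearly interpolated onto the grid
(`resample_to_grid()`); values at coinciding times pass through exactly.

* Fold proliferation: `P(t,c) = E_live(t,c) / E_live(2,c)` — expansion
  relative to the settled count, correcting for seeding differences.
* Death fraction: `T_dead(t,c) = 100 * red_px / phase_px` (%) — dead-cell
  area relative to the confluency surrogate, robust to well-to-well
  variation in target numbers.
* Specific killing: `K(t,c) = T_dead(t,c) / T_dead(t,0)` — normalisation to
  the 0 uM control removes nonspecific and allo-reactive killing; `K(t,0) = 1`
  identically.
* Per-T-cell killing: `S(t,c) = [T_dead(t,c)/E_live(t-6,c)] /
  [T_dead(t,0)/E_live(t-6,0)]` — killing observed at t is attributed to the
  effectors present 6 h earlier (the lag is a parameter, default 6 h).
* Proliferation rate: `P'(t,c) = 100 * 4 * (E_live(t) - E_live(t-6)) /
  E_live(t-6)` in % per day (the factor 4 converts the 6-h difference to a
  day). Negative rates are reported, not truncated: a declining effector
  count is biologically meaningful.
* Kill rate: `K'(t,c) = [(K(t) - K(t-6)) / E_live(t-6)] / 6` per T cell per
  hour.

Replicate wells are averaged after the per-well computation of `P` and
`T_dead`; the normalised quantities are computed from the averaged curves
using the group's averaged 0 uM control. The aggregation order is a design
choice (the alternative — normalising per well, then averaging — differs only
at second order but is more sensitive to a noisy control well).

## Degenerate inputs, clamps and flags

Denominators can legitimately hit zero. The rules, each of which raises a
flag that propagates into every downstream table:

* `E_live(2) = 0`: the well is unusable for `P` (`e0_zero`).
* `phase_px = 0`: that timepoint is excluded (`phase_zero`).
* Control death below the *one-pixel floor* — the death fraction a single
  red pixel would produce, `100/phase_px` — is clamped to the floor
  (`control_floor`). If the dosed well is *also* below the floor there is no
  death signal at all and `K` is undefined (`no_death_signal`, `NA`); this
  typically affects only the earliest scans. At c = 0 the identities
  `K(t,0) = 1` and `S(t,0) = 1` hold by definition and are exempt from both
  rules.
* Zero lagged effector counts clamp to 1 cell (`e_floor`).

# Dose-response summaries

Responses are reduced to one value per positive concentration using the
assay's peak-time conventions: proliferation at the grid time nearest 72 h,
per-T-cell killing at the grid time nearest 48 h, and the two rates as the
per-concentration maximum over grid times in the 30-72 h window. "Nearest
grid time" resolves the 4-h-cadence case where 48/72 h are not grid points
(on the canonical 6-h grid anchored at 2 h these are 50 h and 74 h).

Each readout is fitted with the four-parameter logistic
`r(c) = bottom + (top - bottom) / (1 + (ec50/c)^slope)` in log10-dose space
by Levenberg-Marquardt least squares with five log-spaced EC50 starting
points across the dose range. Zero-dose wells are excluded from fits (log
dose is undefined); they serve only the normalisation. Bounds: Hill slope in
[0.1, 10], EC50 within [min dose / 10, max dose x 10]. Emax is the fitted top
plateau, not the maximum observed response — the summary reports curve
parameters, and the plateau estimate is what remains comparable when the top
dose sits at different multiples of the EC50.

A fit is flagged *flat* ("no dose dependence") when the 4PL does not beat a
constant-response model: an F-test p-value of at least 0.01, or a fitted span
below 5% of the mean absolute response, or zero response variance. The two
rules are deliberately redundant: the F-test controls false dose-dependence
on pure noise, the span rule catches statistically "significant" but
practically negligible trends.

Concentration banding relative to a fitted EC50 assigns each positive dose to
High (`c >= 100*ec50`), Mid (`ec50 <= c < 100*ec50`) or Low (`c < ec50`). The
verbal convention leaves both boundaries open; here each boundary goes to the
higher band so that the three bands partition the doses.

# The co-culture simulator

No public dataset accompanies this assay family, so the package ships a
stochastic generative model (`sim_config()`, `simulate_plate()`) whose
emitted measurements have the statistical structure the analysis assumes.
It is a model chosen for plausibility and testability, not a claim about
mechanism.

Per scan interval dt (discrete-time binomial thinning; exact exponential
hazards per step, chosen over an event-driven scheme for speed and
reproducibility — at dt of 2 h the discretisation error is negligible):

* each live target dies with probability
  `1 - exp(-(h0 + h1 * hill_k(c) * rho_E) * dt)`, where `hill_k` is a Hill
  curve in dose, `rho_E = E/(E+T)` the instantaneous effector density, `h1`
  the saturating specific hazard and `h0` the effector-independent background
  hazard. Background death (spontaneous target death plus dye background) is
  deliberately *not* scaled by effector density: if it were, the specific
  killing ratio would saturate fastest at high E:T and its Emax would
  *increase* toward lower E:T — the opposite of what such assays report. With
  an effector-independent background, both the ratio normalisation and the
  per-cell normalisation order Emax as 3:1 > 1:1 > 1:3.
* each effector divides with probability `1 - exp(-r * dt/24)`, with
  `r = (baseline + max * hill_p(c)) * (1 - coupling * f_kill)` per day and
  `f_kill = 1 - exp(-24 * total kill hazard)` the per-day kill fraction
  implied by the current hazard. The coupling term encodes the inverse
  relationship between cytotoxic activity and proliferation: at saturating
  dose and high effector density, division slows.
* live targets grow logistically toward the well's carrying capacity.

All draws are inverse-CDF transforms (`qbinom`, `qpois`) of per-step uniforms
drawn in a fixed order, so runs with a common well seed are coupled across
doses: raising the dose can only increase the realized deaths step by step.
This makes the monotonicity properties testable without sampling slack, and
fixed seeds reproduce byte-identical output.

Emitted measurements are deterministic functions of the latent state plus
optional Poisson observation noise on the effector count: `red_px` is the
red area per dead cell times the cumulative dead count (an exponential decay
constant for the red signal is exposed but defaults to 0 — no clearance),
`phase_px` is the phase footprint per target times live plus dead targets.

## Default study conditions and why

The defaults describe one well of the emulated assay: 2000 seeded targets,
E:T in {3:1, 1:1, 1:3}, a 21-point 3-fold titration from 100 uM (the
protocol's "serially diluted 3-fold twenty times"; its lowest dose is then
~29 pM) plus a 0 uM control, scans every 2 h for 96 h.

Rate parameters were fixed once, at design time, from the magnitudes such
assays report and a closed-form identifiability analysis; they are not fitted
to any dataset:

* `kill_max_hazard = 0.025 /h` and `nonspecific_hazard = 0.003 /h`: at 3:1
  this kills ~65% of targets at the top dose by 48 h (near-complete clearance
  by 96 h) over a 10-15% background — strong but unsaturated killing. Keeping
  the cumulative specific hazard near 1 at the 48 h readout matters for
  identifiability: the measured response is `1 - exp(-H * hill(c))`, whose
  midpoint sits below the Hill midpoint by an amount that grows with `H`;
  beyond `H ~ 1.5` that compression alone moves the apparent EC50 by more
  than 2-fold.
* `prolif_baseline = 0.05 /d`, `prolif_max_rate = 0.35 /d`: a ~2-3x fold
  increase by 72 h at stimulating doses, matching the fold-increase range
  such assays report.
* `prolif_EC50 = kill_EC50 / 7`: proliferation is the more sensitive readout;
  a ~7-fold offset is the ratio reported for the best-characterised construct
  in this assay family. Saturating proliferation *before* killing lets the
  proliferation/killing coupling dominate the upper dose range, producing the
  characteristic interior proliferation optimum (highest response in the Mid
  band).
* `coupling_strength = 0.9`: strong proliferation suppression while killing
  is active. This both reproduces the inverse dose relationship at 3:1 and —
  through the per-cell normalisation — partially compensates the saturation
  compression of the killing EC50.
* Hill slopes 1.5 for both arms: pMHC-triggered responses are typically
  cooperative. A steeper rising edge also localises the fitted EC50: with
  slope 1, the coupling droop at high doses pulls the fitted proliferation
  top down enough to shift its apparent EC50 ~0.3 decades left of truth.
* `target_growth_rate = 0.2 /d` toward a carrying capacity of 8000 cells:
  slow adherent-line growth in assay medium.
* `red_area_per_dead_cell = 100 px`, `phase_area_per_target = 200 px` at
  1 um/px: a dead, rounded cell occupies roughly half the footprint of a
  spread adherent cell.

## What the generator emulates — and what it does not

It emulates: dose-dependent killing and proliferation with separate
sensitivities, effector-density-dependent killing, nonspecific background
death estimated by the 0 uM control, logistic target growth, counting noise,
and the two qualitative signatures of such assays — per-T-cell killing Emax
decreasing toward lower E:T, and an inverse proliferation/killing
relationship across doses at high E:T.

It does not emulate: spatial structure, migration, or synapse formation;
donor variability; cytokine feedback; dead-effector dynamics (the live count
is green-positive/red-negative; dead effectors are folded into the net
division rate); red-signal clearance (default); green dye dilution with
division (the renderer exposes per-frame intensity control to stress-test
thresholds, but the default keeps intensity constant); and — importantly —
any T-cell *activation ramp*. Hazards are constant from co-culture start, so
the specific-killing ratio `K(t,c)` is highest at the earliest informative
scans and declines as control death accumulates; the kill rate `K'` is
consequently non-positive over most of the 30-72 h window and its
dose-response is correctly flagged flat. Real assays show kill rates that
rise to a peak near 24 h, which implies an activation delay this model does
not include. Passing tests therefore demonstrate the *pipeline's* ability to
recover what the generator encodes, not that real kill-rate kinetics would be
recovered.

A related identifiability caveat is intrinsic to the per-T-cell readout
itself: `S` divides by the dose-dependent effector count, so when
proliferation and killing share the same EC50 the inflated denominator at
high dose compresses the top of the `S` dose-response and drags its apparent
EC50 well below the generative value. With the default 7-fold sensitivity
offset the two normalisations nearly cancel instead. Users fitting `S` on
real data should be aware that its EC50 is only interpretable when
proliferation saturates below the killing range.

One further consequence of fitting the 4PL top as Emax: the fitted Emax
estimates the *asymptotic* plateau and is therefore insensitive to where the
top dose sits relative to the EC50. Across scenarios that differ only in
EC50, realized top-dose responses differ slightly, but fitted Emax values do
not order by that difference — the estimator removes it by design.

# The synthetic frame renderer and segmentation

The renderer (`render_frame()`) draws non-overlapping disks on a noisy
background: effectors as green disks with diameters sampled uniformly within
6-14 um (kept strictly inside the 5-15 um classification gate so rendering
quantisation cannot move an object across the gate), live and dead targets as
phase-occupied disks (~200 px), dead cells with a concentric red core
(~100 px), and optional red-positive effectors. It returns the ground-truth
label map alongside the frame, which is what makes the segmentation testable.

The segmentation (`count_effectors()`, `red_area()`, `phase_area()`) is a
transparent analogue of instrument software, which is proprietary and not
reproducible: per-channel thresholding (explicit values, or Otsu's method
with a foreground guard), connected-component labelling, and a gate on
equivalent diameter (`2*sqrt(area/pi)` in um — the operative definition of
"size"), circularity (`4*pi*area/perimeter^2`, minimum 0.4 — "shape" needs a
formula; rasterised small disks can exceed 1 because pixel-count perimeters
underestimate length, so the gate is a lower bound only), and red exclusion
(mean red intensity below the red threshold). Dead targets and dead effectors
are *not* separated in the red channel; the death measurement is total red
area, which is exactly what the downstream equations consume.

The Otsu foreground guard exists because Otsu's method always splits a
histogram: on a channel containing only background noise (the red channel
before any cell has died) the split lands inside the noise and everything
bright-ish is called foreground. The guard declares foreground only when the
between-class mean separation exceeds four background standard deviations;
otherwise nothing passes the threshold. The guard can miss a genuinely tiny
foreground (one or two dead cells in a large field); explicit calibrated
thresholds, as on a real instrument, avoid this and are recommended for
image-mode analyses.

# Numerical choices

* Grid interpolation is linear (`stats::approx`); no smoothing or denoising
  beyond it — rates are honest finite differences of the measured curves.
* 4PL fitting uses `minpack.lm::nls.lm` on residuals parameterised by
  log10(EC50), which makes the EC50 scale-free and keeps the Jacobian well
  conditioned across ten orders of magnitude of dose; noiseless data are
  recovered to ~1e-9 relative error from any of the multi-start points.
* Peak-time ties ("nearest grid time") resolve toward the earlier time.
* Per-well seeds derive from the master seed via one `sample.int` call, so
  plate-level runs are reproducible and independent of well order.
* Problem sizes in the test suite: the Monte-Carlo recovery experiment runs
  three sensitivity scenarios (kill EC50 5e-4, 5e-2, 5 uM, proliferation EC50
  matched at the default 7-fold offset) x 100 seeded duplicate plates at 2000
  targets with Poisson counting noise; the cross-mode comparison renders a
  scaled-down plate (80 targets/well, 10 doses, 4-h scans) so frames stay
  sparse enough for the non-overlap renderer.

# Known limitations

Beyond the generator's non-goals above: the pipeline does not model or detect
periodic fine structure in kill-rate curves; confidence intervals for 4PL
parameters are not computed (a bootstrap hook is a natural extension); the
segmentation is validated only against synthetic ground truth and is not a
substitute for instrument-calibrated analysis of real exports; and clustered
cells are not split into instances — which is consistent with the area-based
death measurement but makes the effector count unreliable at high densities
(the renderer's non-overlap mode sidesteps this; real data at high confluency
would not).
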