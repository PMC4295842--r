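---
title: "Models and methods: C-ring stoichiometry and exchange dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: C-ring stoichiometry and exchange dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cringdyn)
```

This vignette documents the statistical models behind the package, the
choices made where the procedures admit more than one reasonable
implementation, and what validation on the bundled synthetic generator does
— and does not — establish about real data.

## Reference-standard stoichiometry

**Model.** A diffraction-limited focus containing $n$ fluorophores has an
integrated intensity $n \cdot u$, with $u$ the (unknown) per-fluorophore
photon yield. Imaging a target protein and a reference complex of known
stoichiometry $n_{\mathrm{ref}}$ under identical conditions cancels $u$:

$$\hat n = n_{\mathrm{ref}} \,
  \frac{\overline{\langle I \rangle}_{\mathrm{target}}}
       {\overline{\langle I \rangle}_{\mathrm{ref}}},$$

where $\langle I \rangle$ is a per-stack mean focus intensity and the outer
bar averages stacks — each stack is one independent observation, so
stack-level systematic differences (illumination, focus) enter the error
budget at the right level. The inner-membrane ring protein SctD/YscD with
its fixed 24 subunits serves as the reference.

**Detection.** Foci are local 3-D maxima above
$\mathrm{mean}_{bg} + 5\,\mathrm{SD}_{bg}$; peaks closer than 3 px
laterally (304 nm at the 101.3 nm/px calibration) are merged, keeping the
brighter. Both thresholds are arguments, not constants. Background
statistics use iterative 3$\sigma$ clipping (at most 10 iterations): the
procedure is parameter-free and removes the ~0.1% of voxels occupied by
foci without needing a mask. A constant stack has $\mathrm{SD}_{bg} = 0$
and yields no detections, since the threshold comparison is strict.

**Intensity.** Each focus is integrated over a fixed cylinder (lateral
radius 3 px — the same scale as the separation limit — over all z planes),
minus the expected background contribution
$(\text{outside-of-cell background} + \text{cellular autofluorescence})
\times n_{\mathrm{voxels}}$. The two correction terms are passed
explicitly; negative corrected intensities are reported, not clamped, so
noise-dominated ROIs stay visible. Foci whose cylinder leaves the lateral
field are flagged `edge` and dropped from stoichiometry. No subpixel
localization is attempted: copy-number ratios need unbiased intensities,
not nanometre centres.

**Spread.** The reported `sd_copies` is the per-focus intensity SD scaled
to copy units. Most of that spread is physical: intensity is measured in a
z-sectioned acquisition, and foci centred above or below the best plane
integrate fewer photons inside the stack. The generator reproduces this by
drawing each focus's axial position uniformly over the stack depth.

**Tie-breaks and determinism.** Candidate peaks are ordered by descending
intensity, then lexicographically by (z, y, x), making the min-distance
suppression deterministic. Coordinates are 1-based array indices in
(z, y, x) order — the native R array convention, used consistently in
memory and in the CSV ground-truth files.

## FRAP exchange kinetics

**Ratio and normalization.** Per frame, the spot ratio
$R = (I_S - I_0)/(I_B - I_0)$ divides out illumination drift and
acquisition photobleaching. The pre- and post-bleach reference levels are
means of 10 frames immediately before and after the bleach (acquired at
video rate, so negligible recovery occurs within the reference window),
and post-bleach frames are rescaled to the *unrecovered fraction*

$$N(t) = \frac{R_{\mathrm{pre}} - R(t)}{R_{\mathrm{pre}} - R_{\mathrm{post}}},$$

which starts near 1 and decays toward $1 - m$ ($m$ the mobile fraction).
This direction is the only one consistent with fitting bounds of
$start \in [0.9, 1.1]$ and $end \in [-0.1, 0.4]$: the curve must begin
near 1 and level off near the immobile fraction, and a typical mobile
fraction of ~80% appears as $end \approx 0.2$. The normalization is
invariant under any positive affine transform of the raw ratios, which is
tested as a property. If $R_{\mathrm{pre}} \le R_{\mathrm{post}}$ there was
no bleach and the trace is rejected with an error rather than fitted.

**Model and fit.** $N(t) = start + (start - end)(e^{-t/\tau} - 1)$ is
fitted by box-constrained Levenberg–Marquardt (`minpack.lm`). The fitted
$\tau$ is an e-folding time; the recovery half-time is $t_{1/2} = \tau \ln
2$ exactly, and the mobile fraction is $(start - end)/start$. $r^2$ is
computed on the normalized scale; fits with $r^2 < 0.4$, non-converged
fits, and zero-variance traces are flagged excluded (never errors), and
group summaries count only retained fits. The exclusion rule removes pure
noise reliably: at ratio-scale noise of $\sigma = 0.2$ with no recovery
signal, more than 90% of traces are excluded.

**Multi-start.** The objective can have a boundary local minimum when the
acquisition window covers few half-lives: the optimizer then trades a too
small $\tau$ against $end$ pinned at 0.4. Deterministic restarts at
$\tau_0 \in \{20, 60, 180, 600\}$ s cover exchange from seconds to
many minutes; the 600 s start is required for half-times approaching the
acquisition span (a 500 s half-time observed over a 600 s window). The
lowest-SSR start wins; no randomness is involved.

**Group statistics.** Condition means are reported with the SEM over
retained fits; two conditions are compared with Welch's two-sided
unequal-variance t-test on half-times — a deliberate choice, since the
variance of fitted half-times differs between fast- and slow-exchange
regimes.

**Generator.** Traces are emitted as raw $(I_S, I_B, I_0)$ columns, so the
analysis path from ratios onward is exercised rather than bypassed. The
bleach is instantaneous at $t = 0$ (the real pulse lasts 20 ms, three
orders of magnitude below the half-times of interest); the spot ratio
recovers as $R(t) = 1 - b\,(1 - m\,(1 - 2^{-t/t_{1/2}}))$ with bleach depth
$b$ (default 0.9) and Gaussian noise on the ratio scale. At $t = t_{1/2}$
exactly half the mobile amplitude has recovered, which is tested in closed
form.

## Single-molecule mobility

**Linking.** Localizations are linked frame to frame by minimizing total
displacement over an optimal assignment (a Jonker–Volgenant solver written
for this package, cross-checked against brute-force enumeration), with a
hard gate: pairs farther than `max_displacement` (default 0.5 µm ≈ 5 SD of
a single-axis step at the 0.15 µm²/s threshold and 15.26 ms frame
interval) never link, and each unmatched end or localization is charged
one gate distance, so any within-gate link is preferred over leaving both
sides unmatched. There is no gap closing — a missed frame terminates the
track — and tracks shorter than 5 localizations are discarded.

**Classification.** Each track's single-step diffusion coefficient
$D^* = \overline{\Delta r^2}/(4 \Delta t)$ labels it mobile when strictly
greater than 0.15 µm²/s (a value exactly at the threshold is bound).
Classification is per track/molecule; the pooled per-step coefficients are
also returned for step-wise histograms. With localization error
$\sigma_{\mathrm{loc}}$ per axis, $\mathbb E[D^*] = D +
\sigma_{\mathrm{loc}}^2/\Delta t$; no correction is applied — matching the
thresholding convention — but the bias formula is documented and verified
against simulation, and should be considered when choosing thresholds for
other imaging conditions.

**Density matters.** Linking quality degrades when many molecules are
active simultaneously: if a molecule bleaches and another activates nearby
within one frame, the linker can bridge them, and a single bridged jump
can push a bound track's $D^*$ above threshold. The generator therefore
defaults to a photoactivation-style acquisition — a few hundred molecules
spread over 15 000 frames (well under one active molecule per frame in a
2 × 1 µm cell), where chimeric links are rare. Crowded data would need
activation-rate control upstream of this analysis.

## Ring-packing geometry

A globular protein of mass $M$ occupies volume $M \bar v$ ($\bar v = 0.73$
cm³/g; 1 Da at this $\bar v$ is $1.212 \times 10^{-3}$ nm³), giving a
sphere diameter $d = 2\,(3 M \bar v / 4\pi)^{1/3}$ — 4.30 nm for a
34.4 kDa subunit. A closed ring of $n$ touching spheres has centre-circle
circumference $\approx n d$, hence diameter $n d / \pi$: 30.1 nm for
$n = 22$, against ~28 nm for the putative C-ring density in subtomogram
averages and 34–57 nm for flagellar C-rings. "Diameter" here always means
the circle through sphere centres; the outer envelope (one subunit
diameter larger) is reported separately, and the inverse mapping
$n = \pi D / d$ round-trips exactly. Both $M$ and $\bar v$ are exposed so
refined subunit dimensions can be substituted. The model ignores hydration
and non-spherical shape; at this level of approximation the predicted
diameter is good to a few percent at best.

## Supporting kinetics analyses

The enzymatic export-rate assay yields fluorescence traces whose "linear
increasing region" is not a standard quantity; the package defines it as
the contiguous window (default 10 points) with the largest OLS slope among
windows whose $R^2 \ge 0.95$, falling back to the overall maximal-slope
window with a warning when nothing is linear enough. Zero-variance windows
count as perfectly linear so flat traces return slope 0 silently. Slopes
are shift-invariant and scale-equivariant by construction. Rates normalize
to a reference sample (100%); titration analyses regress mean foci per
cell on the quantified protein amount by OLS, warning when a titration
point rests on fewer than 170 cells.

## The synthetic generator: what it does and does not emulate

Emulated: integer fluorophore counts per focus atop a cytosolic
background; a separable 3-D Gaussian PSF ($\sigma_{\mathrm{lat}}$ 100 nm,
$\sigma_{\mathrm{ax}}$ 300 nm — the standard far-field approximation,
sufficient for intensity *ratios*); 150 nm z-sectioning over 7–15 planes
with uniform axial focus offsets; Poisson shot noise plus Gaussian read
noise (no EM-gain excess factor — gain cancels in every downstream ratio);
exponential FRAP recovery with a mobile fraction, emitted as raw intensity
columns; two-population Brownian motion with reflective cell boundaries,
geometric track lengths (memoryless photobleaching) and per-frame Gaussian
localization error.

Not emulated: realistic cell morphology and membrane curvature,
fluorophore blinking and incomplete maturation, stage drift, depth-dependent
aberrations, diffusion-coupled (non-exponential) FRAP, and focus overlap in
crowded fields. Passing recovery tests therefore demonstrates that the
estimators are unbiased under the stated statistical model at realistic
noise levels — not that these instrument- and photophysics-level effects
are harmless on any given microscope. The photon budget per fluorophore
(`unit_intensity`, default 400 photons) is a free parameter chosen so that
foci of the studied copy numbers clear the 5 SD detection threshold at any
axial offset; at marginal signal-to-noise, detection becomes
intensity-selective and would bias stoichiometry upward for the dimmer
group — the generator's defaults deliberately avoid that regime, and
instrument calibration must establish it on real data.

## Problem sizes and determinism

Validation uses the cohort sizes of the underlying study design: 11 stacks
per group with at least 100 foci per stack for stoichiometry (recovery to
within 5% for copy numbers 6–48 against the 24-copy reference); FRAP
cohorts of 9–20 traces at ratio noise 0.05 (half-time recovery within
10%, or 15% at $n = 9$); and several hundred molecules per tracking run.
Every simulation is driven by an explicit integer seed in its config, and
identical seed + config gives bit-identical output, which is tested. The
brute-force oracles (exhaustive voxel scans, enumeration of assignments
and matchings) run on deliberately small instances — stacks up to
$32^3$ voxels and scenes of at most 4 simultaneous molecules — where
exhaustive computation is exact.

## Known limitations

- Stoichiometry assumes equal per-fluorophore brightness and maturation in
  target and reference fusions; a maturation difference scales the estimate
  linearly and cannot be detected internally.
- The FRAP model is a single exponential: reaction-dominant exchange. If
  recovery were diffusion-limited the half-time would conflate binding and
  transport; the $r^2$ gate does not distinguish these regimes.
- $D^*$ over a handful of steps is a noisy, biased estimator; the
  threshold convention and the localization-error bias formula are
  documented, but per-track classification near the threshold remains
  probabilistic (a few percent error even for well-separated populations).
- The ring model's subunit size comes from mass alone; a 10% error in the
  effective subunit diameter moves the predicted ring diameter by 10%.
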