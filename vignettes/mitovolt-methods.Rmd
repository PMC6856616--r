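---
title: "Quantifying intramitochondrial membrane-potential heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intramitochondrial membrane-potential heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Monovalent cationic dyes (TMRE, TMRM, Rho123) distribute across membranes
according to the local membrane potential. At equilibrium the concentration
ratio between two compartments obeys the Nernst relation, so a potential
difference can be read off two fluorescence intensities:

$$\Delta\psi_{a-b} \;=\; \kappa \,\ln\frac{F_a}{F_b},
\qquad \kappa = \frac{1000\,R\,T}{z\,F}\ \mathrm{mV},\ z = +1 .$$

At 310.15 K (37&nbsp;°C), $\kappa \approx 26.73$ mV; `nernst_kappa()` computes it
from CODATA constants and the temperature is a configuration parameter,
because source acquisitions rarely state it.

With super-resolution live imaging (Airyscan-class, ~140 nm lateral
resolution) the inner mitochondrial membrane resolves into cristae
(transverse invaginations) and the inner boundary membrane (IBM). Applying
the Nernst conversion *within* one organelle — crista versus adjacent IBM,
detached vesicle versus IBM — quantifies sub-organelle electrochemical
heterogeneity: polarized cristae (positive $\Delta\psi_{\mathrm{Cr-IBM}}$ of
order 10 mV in controls), its pharmacological modulation (raised by ATP-synthase
inhibition, collapsed by uncoupling), its loss when crista junctions are
disrupted (MICOS/OPA1 knockouts), hyperpolarized detached vesicles, flickering,
and wave-like propagation of laser-induced depolarization.

The analysis chain is: rolling-ball background subtraction → segmentation on
the *structural* channel (NAO / MitoTracker Green; potential-independent, so
depolarization cannot bias geometry) → skeleton long-axis extraction → axial
intensity profiling → crista peak detection → pixel classification
(crista / IBM / matrix / vesicle) → Nernstian potential tables → time-domain
analyses (tracking, flicker decomposition, variability, partial
depolarization, wave fronts).

## What the simulator states

No images are published with the source study, so the package ships a
forward simulator whose presets *are* the stated world; every analysis claim
is validated as parameter recovery against its ground truth.

A phantom is a 2-D capsule (default 6 × 0.8 µm, 40 nm pixels) with a 1-px
IBM ring, 1-px transverse crista bands (0.3 µm spacing), and optional
vesicle disks. Membranes are drawn below the resolution limit on purpose;
the Gaussian PSF (FWHM 140 nm default) creates their apparent width.
Potentials add: cytosol 0, matrix 150 mV (a typical textbook polarization),
IBM = matrix + 5 mV, crista = IBM + offset, vesicle = IBM + offset. The
*crista offset is the condition parameter*: 10.11 mV (control), 10.67
(control MEF), 25.85/39.55 mV for the knockout vesicles — the published
point estimates — while oligomycin (18 mV), FCCP (3 mV on a 40 mV matrix,
shorter/rounder geometry) and the MICOS/OPA1 knockouts (2–3 mV, fewer
cristae) use plausible values chosen once, since only directions are
published for them.

The potentiometric channel is rendered as
$F = e^{\psi/\kappa} + \frac{f}{1-f}\,e^{\psi_0/\kappa}$: free dye
re-equilibrates instantaneously with the event-modified potential $\psi$,
while the second term is membrane-bound, potential-independent dye frozen at
the baseline field $\psi_0$. The bound fraction $f$ is defined as a fraction
of *baseline total signal*, so a full depolarization leaves exactly $f$ of
the baseline fluorescence — the published flicker decomposition (~85% lost,
~15% remaining, crista and matrix plateaus equal) is then an arithmetic
consequence, which is what the acceptance test checks. Rendering applies the
PSF, a photon gain (2 photons per concentration unit; cytosol ≈ 2 photons,
matrix ≈ 550, cristae ≈ 800 — a realistic live-cell budget), Poisson shot
noise and Gaussian read noise (SD 2), all reproducible from one integer
seed.

Events modify the potential field per frame: *flicker* scales all potentials
by $1-\mathrm{depth}$ during its window (default timing 9 → 16 s, as in the
canonical flicker sequence); *wave* scales potentials behind a front
advancing from the exposure site at a set speed, and the depolarization
persists (laser damage does not recover); *partial depolarization* removes
only the crista-minus-IBM offset of targeted cristae. Later events override
earlier ones per pixel.

What the simulator does **not** emulate — and hence what a green test does
not establish: 3-D geometry and out-of-focus light, dye photobleaching and
quenching, organelle motion/deformation, cytosolic autofluorescence
structure, vendor detector artifacts. Tests demonstrate *method* correctness
(the estimators recover the stated world), not instrument calibration.

## Numerical choices that matter

**PSF contrast restoration.** A 1-px membrane blurred with a 140 nm PSF
mixes with matrix and cytosol, so raw intensity ratios are biased — the
crista/IBM ratio is actually *inflated* (the IBM shell borders dim cytosol),
reading ~26 mV apparent for a true 10 mV. Rather than deconvolve, the
pipeline calibrates: it renders noise-free phantoms matching the *measured*
geometry (width, crista spacing, or vesicle radius) across a grid of true
offsets, pushes them through the same measurement code, and inverts the
monotone apparent→true map (linear extrapolation beyond the grid, memoized
per geometry). This is a calibration against the package's own forward
model, enabled by default (`calibrate_contrast`); `delta_psi_raw_mv` is
always reported alongside. The calibration assumes the configured matrix
polarization (150 mV) and optics; a mismatch (e.g. the FCCP preset's 40 mV
matrix) degrades absolute accuracy but preserves ordering, which is all the
pharmacology comparisons claim. Consequence of the same physics: the *raw*
IBM compartment mean is diluted toward cytosol by ~10 mV under default
optics; the null-case test therefore checks the calibrated crista-IBM value
(0 ± 1 mV) and matrix/crista agreement, not the raw IBM row.

**IBM placement.** Threshold masks overshoot the membrane ridge by the blur
halo; the label map insets the boundary shell by `ibm_inset_px` (default 1,
matched to the stated optics) so it sits on the true ring — verified at
≥ 90% per-class pixel agreement against ground truth. IBM pixels within
±1 px (axially) of a crista stay labelled IBM but are excluded from the IBM
*quantification* mask, because crista signal bleeds into them.

**Vesicle intensity.** The vesicle mean uses the brightest quartile of the
detected component (its central plateau): the detection threshold
(2 × median matrix intensity) grows the component into the blurred edge by
an amount that depends on vesicle brightness, and an edge-contaminated mean
would couple the potential estimate to the detection threshold.

**Crista detection.** Peaks on the structural axial profile with prominence
≥ 10% of the profile dynamic range and spacing ≥ 120 nm (the resolution
limit), leftmost plateau tie-break, parabolic sub-pixel refinement. A bright
structural peak whose band is mostly vesicle pixels is a vesicle, not a
crista, and is dropped (vesicles are bright in both channels; genuine crista
bands touch the IBM, vesicles are detached by definition — the 8-adjacency
rule separates them).

**Wave classification.** The operational rule (the source describes the
distinction qualitatively): *instantaneous* if ≥ 90% of the axis is below
50% of baseline within one frame of onset; *wavelike* if the front (largest
contiguous depolarized run from the site) needs ≥ 2 frames to cross; front
speed by least squares of front position on time. The distal band is
≥ 10 µm from the site, falling back to ≥ 0.6 × length for shorter
organelles. These definitions reproduce the published temporal-resolution
argument: identical 2 µm/s physics classifies wavelike at 0.3 s frames and
instantaneous at 5 s frames.

**Statistics.** Group comparisons average within experiment first, then
apply a two-tailed two-sample Student *t* (pooled variance by default, Welch
optional) — the averaging convention of the source analyses. Degenerate
identical groups report $t=0, p=1$.

**Tie-breaks and degenerate inputs.** Tracking links detections greedily by
smallest displacement (resolving crossings by minimal total displacement),
bridges gaps ≤ 2 frames, and scales the jump limit with the bridged span.
Zero-variance profiles have undefined correlation → `NA`. Objects whose
skeleton is shorter than twice the equivalent-disk radius are flagged
`low_elongation`. An independent component ≥ the measured signal flags the
value missing rather than producing negative intensities.

## Design choices where the design was open

- The spec's ratio formula is implemented as a log *difference*, making
  antisymmetry exact in floating point.
- Geometry is anchored on frame 1 (profiles, classification, traces), with
  per-frame re-detection only for tracking; the phantoms are static and
  drift correction is out of scope.
- The axis is oriented canonically (arclength 0 at the leftmost end) so
  site coordinates are reproducible.
- The rolling-ball uses the classic min-downsample-by-4 speed-up for radii
  ≥ 16 px; tests compare the exact path against an independently written
  opening oracle.
- Temperature, reference mode (`adjacent_IBM` default; `mito_mean` is the
  whole-organelle reference used for compartment tables; `cytosol` exists
  but is fragile after background subtraction), and the assumed bound
  fraction (5%, the published control bound) are all configuration fields.

## Known limitations

2-D only; single-object scenes are the validated regime (multi-object
stacks analyze independently but cross-object light is not modeled);
calibration accuracy degrades when the true matrix polarization differs
substantially from the configured one; wave speeds are measurable only when
the front is sampled by ≥ 2 frames, which bounds measurable speed by
length/(2·Δt); unit tests run invariants at 2–5 seeds (the acceptance suite
runs the stated 20) to stay within practical runtimes.
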