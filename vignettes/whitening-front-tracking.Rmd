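---
title: "Whitening-front tracking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whitening-front tracking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whitefront)
```

## The problem

Crack-extension resistance curves (R-curves) express fracture toughness as a
function of crack extension $\Delta a$ rather than as a single critical value.
For quasi-brittle materials such as cortical bone they are the right
description — toughness rises as the damage zone develops — but they require
measuring $\Delta a$ during the test. In specimens a millimetre or less
across, the crack itself is often invisible on video: what *is* visible is the
stress-whitening zone, a bright halo of micro-crack light scattering that
develops ahead of the crack tip and propagates with it at an essentially
constant offset. `whitefront` turns that observation into a measurement
pipeline: track the top edge of the whitening zone on bend-test video, use it
as an effective crack tip, and evaluate nonlinear fracture mechanics along the
synchronised load–displacement record.

The pipeline has five stages, each exposed as ordinary functions and mirrored
by a config-driven runner (`run_track()`, `run_rcurve()`, ...):

1. **Load & synchronise** (`load_frames()`, `sync_frames()`): subsample the
   captured video (default: keep 1 of every 15 frames of a 60 fps recording),
   stamp frame $X$ with elapsed time $X/\mathrm{fps}$, and interpolate force
   and displacement at the frame times.
2. **Register & subtract** (`register_pair()`, `difference_image()`): estimate
   the rigid shift of each frame against the first frame by DFT-upsampled
   cross-correlation (default resolution 1/100 px), align, subtract, clip
   negatives. Whitening is an intensity increase, so it survives; static
   texture cancels.
3. **Segment & localise** (`segment_whitening()`, `locate_front()`): threshold
   the difference inside a rectangular ROI around the notch, clean with a
   2-px-diameter disc morphological operator, and take the top-most occupied
   row; of that row's left and right extrema, the front is the pixel farther
   from the notch tip.
4. **Assemble the R-curve** (`build_rcurve()`): convert the monotonicised
   front displacement to crack extension, and evaluate $K$, $J$ and
   $K_\mathrm{eff}$ at every synced frame.
5. **Correct the modulus** (`mesh_beam()`, `solve_bend()`,
   `fit_correction()`): a small plane-stress FE model quantifies how a
   machined notch depresses the measured bend stiffness, so the modulus used
   in $J_{el}$ refers to the material rather than to the notched section.

## Synchronisation

The tester records force, displacement and elapsed time as columns of one
acquisition record. Because camera and tester start together, frame $X$ lives
at $t = X/\mathrm{fps}$, and both channels are interpolated there *on the
shared sample index*. Matching frames to the record through the force value
would be equivalent before peak load but ambiguous after it (force is no
longer monotonic), which is why the package merges on time over the common
record instead. Frames beyond the record are flagged `synced = FALSE` and
excluded from R-curve assembly.

## Registration and subtraction

`register_pair()` implements single-step DFT-upsampled cross-correlation: the
integer-pixel correlation peak is found with one FFT, then the correlation is
re-evaluated on a $1/u$-px grid in a 1.5-px neighbourhood of the peak by a
matrix-multiply DFT. Only translation is estimated — the specimen must not be
deformed by the registration, which is the point of using a rigid method.
Frame means are removed first so the DC term does not flatten the peak. On
band-limited textures the estimator is accurate to a few thousandths of a
pixel at `upsample_factor = 100`.

The aligned reference is resampled bilinearly; border pixels without source
data are invalidated (set to zero in the difference). The estimated shift is
also used to map the located front pixel back into reference-frame
coordinates — with jitter of a pixel or less this *jitter correction* is what
keeps the displacement series clean — and the corrected position is snapped
to the pixel grid, since the localiser itself is pixel-quantised.

## Segmentation choices

Three parameters matter and all are in the config:

* **Threshold.** Default: Otsu's threshold computed once on the *final*
  frame's difference image (the fully developed whitening zone) and applied
  globally, so all frames are segmented consistently. Otsu lands near the
  midpoint between the noise floor and the whitening amplitude — roughly a
  3.5σ margin each way at a contrast-to-noise ratio of 10. That is adequate
  for area-type measurements but thin for *top-most pixel* localisation,
  where a single supra-threshold noise pixel above the front is an error. For
  data whose whitening contrast is known (as with the synthetic scenarios,
  whose amplitude is a parameter) the recommended setting is a fixed
  threshold at 60% of the whitening amplitude. The difference image carries
  noise from both frames (σ√2 ≈ 0.14 of the amplitude at CNR 10), and the
  two failure modes are asymmetric in structure: a false *positive* above
  the front needs one supra-threshold pixel, while a false *negative* (the
  halo's top row eroded away) needs a coincidence of sub-threshold drops
  among its supporting pixels; 60% of the amplitude puts both tails at
  roughly 4σ, which balances the exposures.
* **Operator.** The cleaning step names both readings of the published
  description: `"closing"` (dilate–erode; joins neighbouring whitening
  patches by filling small dark islands — the default) and `"opening"`
  (erode–dilate; additionally deletes isolated bright specks). For front
  localisation the recommended choice is *opening*: a single noise pixel
  above the front survives closing and would become the front, while opening
  removes it; the halo itself, being solid and several pixels wide, keeps
  its exact top row under opening (the row below restores it on dilation).
* **Displacement mode.** `locate_front()` reports either the Euclidean
  distance from the notch tip (the literal "distance between" reading) or its
  vertical projection. The crack extension entering $a_i = a_0 + \Delta a_i$
  is a through-width length, so `build_rcurve` workflows use
  `displacement_mode = "vertical"`; Euclidean remains the default for the
  standalone localiser.

## Fracture mechanics

All lengths are mm, forces N; then $J$ comes out in N/mm ≡ kJ/m², moduli in
MPa, and $K$ converts via $1\,\mathrm{N\,mm^{-3/2}} =
0.0316228\,\mathrm{MPa\sqrt{m}}$. Per frame $i$:

$$K_i = \frac{F_i S}{B W^{3/2}}\, f(a_i/W), \qquad
  J_i = \underbrace{\frac{K_i^2 (1-\nu^2)}{E}}_{J_{el}}
      + \underbrace{\frac{\eta\, A_{pl,i}}{B\, b_0}}_{J_{pl}}, \qquad
  K_{\mathrm{eff},i} = \sqrt{\frac{J_i E}{1-\nu^2}},$$

with $f$ the standard SE(B) geometry polynomial, $b_0 = W - a_0$ the initial
ligament, $\eta = 1.9$ (configurable; the basic-procedure value for SE(B)),
and $\nu = 0.33$ by default. The plastic area $A_{pl}$ is the trapezoidal
area under force versus *plastic* load-line displacement
$d_{pl} = d - F/m$, accumulated over the record up to frame $i$ (total-area
form, not incremental updating). The linear stiffness $m$ is fitted on the
rising branch only, in the 10–50% of peak-force window: the post-peak
softening branch passes through the same force range at large displacement
and must not enter the fit. Frames with $a_i \ge W$ are truncated — the
effective crack tip has consumed the section and the SE(B) formulas no longer
mean anything there. No further E1820 qualification screening is applied.

The plane-strain factor $(1-\nu^2)$ is used in both conversions, matching
standard practice for through-thickness damage; a `plane = "stress"` switch
exists on `k_eff()`.

## The notched-beam modulus correction

The flexural modulus of a notched bar, evaluated with the reduced section
$E_f = S^3 m / (4B(W-a_0)^3)$, *overestimates* the material modulus: the
stress field around a notch is not that of a shallower rectangular beam. The
`notch_fe` stage regenerates this bias curve from first principles: a
displacement-driven, linear-elastic, plane-stress FE model (fully integrated
bilinear quads, 2×2 Gauss) of the three-point-bend test is solved at several
notch depths; each stiffness becomes an apparent $E_f$; and the ratio to the
un-notched apparent value is fitted with a second-order polynomial anchored
at ratio(0) = 1. `correct_modulus()` divides a measured notched value by the
fitted ratio, returning the modulus an un-notched specimen of the same
material would have given — which is the quantity the anchored model can
deliver exactly. Recovering the *material* constant instead is a one-step FE
inversion (`calibrate_E()`), linear in E.

Deliberate simplifications, documented as such: roller contact is replaced by
pinned support nodes and a prescribed load-point displacement (contact adds
no first-order information to a stiffness ratio and would drag in a nonlinear
solver); the notch is a zero-width slot made by node splitting (the
sharp-crack limit; the real saw-cut width is not modelled). Numerically, the
point constraints and the slot tip are stress singularities, so global
stiffness converges at roughly first order there — about 1.9% per mesh
halving at the slot against 0.9% for the smooth configuration at the default
element sizes (0.05 mm fine / 0.15 mm coarse, ~2000–4000 elements). The
convergence test therefore pins the smooth configuration. Comparisons with
Euler–Bernoulli beam theory are made on a slender geometry ($S/W = 15$):
at $S/W \approx 7$, shear deflection alone puts any plane-continuum solution
~7% away from the beam-theory formula, which is a statement about beam
theory's validity, not about the solver.

## The synthetic-data generator

`synth_video()` is a phenomenological forward model — the study conditions in
code, not a bone simulator. It renders, at 10 µm/px in a 128×128 view
(90 px of specimen width), a clipped band-limited speckle texture, a dark
machined notch, and a whitening halo that nucleates at the notch tip five
frames in and climbs one pixel per emitted frame until it reaches the top
surface; below the front the halo widens one pixel per row from a 5-px-wide
tip and extends a little below the notch tip. The speckle is clipped to
[0.1, 0.5] so that adding the default halo amplitude (0.5) never saturates:
the difference image then steps by the full amplitude at the front, and the
top-most above-threshold pixel of a noise-free rendering *is* the programmed
front, exactly. An optional 1-px dark crack line lags the front by a constant
offset (default 0.35 mm; drawn once from 0.30–0.40 mm if unspecified),
emulating the whole-bone observations; in the miniature-specimen scenarios it
is suppressed, matching the reported absence of a visible crack at this
optical scale.

The mechanics record is displacement-ramped at 0.01 mm/s with stiffness
$m = 4EB(W-a_0)^3/S^3$ — chosen consistent with the notched flexural
relation, so analysing the record recovers the programmed E exactly — linear
until the frame at which the front reaches the top surface, then decaying
exponentially (no unstable fracture; the decay shape is a free choice and
only its continuity and monotone decline are asserted). Sampling is at 20 Hz
on a grid containing every frame time, so synchronisation is exact at the
knots. The generator also emits a reference R-curve forward-computed from the
true front schedule *by the package's own fracture functions*: the tracking
closed loop then isolates front-recovery errors from any disagreement about
the mechanics.

**Jitter.** The default jitter model is whole-pixel frame displacements with
per-axis standard deviation 0.3 px. This is a deliberate choice: the front
localiser is pixel-quantised, so under fractional jitter a ±half-pixel
ambiguity in the recovered front is irreducible, and near $a \to W$ the
$f(a/W)$ sensitivity amplifies even one pixel of $\Delta a$ error into tens
of percent of $J$ — the closed-loop J comparison would then measure the
geometry function's singularity, not the tracker. With whole-pixel jitter the
registration (accurate to ~0.005 px) resolves every shift unambiguously and
recovery is exact, which is the regime in which a 1%-level closed loop is
meaningful. A continuous-jitter mode (`jitter_integer = FALSE`, bilinear
resampling) exists for realism testing, where the tracker holds ~0.5 px RMS.

**What passing these tests does not show.** Real whitening has soft,
time-varying contrast, non-rigid specimen motion, illumination drift, and a
front that is not a clean step; the generator has none of these. The
synthetic closed loops validate the algorithmic chain (registration algebra,
segmentation logic, synchronisation, unit bookkeeping, equation assembly),
not the biological imaging performance, which only real videos can.

## Problem sizes and numerical defaults

Default test-scale sizes, chosen as a balance of coverage and turnaround:
scenarios of 100 frames at 128×128 px (tracking a full scenario takes about a
second); FE meshes of a few thousand elements; 1000 Monte-Carlo draws for the
correlation calibration at $n = 60$ frames. Registration upsampling 100
(0.01 px); segmentation element diameter 2 px; `min_peak_corr = 0.05` flags
frames whose registration confidence collapses (they carry no front rather
than a wrong one). Ties in `locate_front()` break toward the top-left pixel
for determinism. All generators and runners are seed-deterministic and their
file outputs byte-reproducible.

## Known limitations

* Rigid registration only; a specimen that rotates or deforms visibly in
  frame will blur the difference image.
* One front per frame: branching damage zones resolve to their top-most
  extremum.
* The whitening threshold is global across frames; slow illumination drift
  would need per-frame normalisation (the gamma/windowing preprocessing is
  the provided tool for that).
* The FE correction is 2-D plane stress with a sharp slot; finite notch-root
  radii and 3-D effects are outside its scope.
* Crack-tip positions for the correlation study come from manual annotations
  supplied as CSV; the package deliberately does not auto-detect crack tips.
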