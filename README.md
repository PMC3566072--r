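# whitefront

Crack-extension resistance curves (R-curves) from three-point-bend
videography of miniature single-edge-notched bend — SE(B) — specimens.

## Why

Fracture toughness of cortical bone (and other quasi-brittle materials) is
best described by a resistance curve: J or K as a function of crack
extension Δa. In sub-millimetre specimens the crack itself is usually
invisible on video, but the **stress-whitening zone** — a bright halo of
light scattered by micro-cracks in the damage zone ahead of the crack tip —
is visible, propagates in sync with the crack, and leads it by a roughly
constant few hundred micrometres. `whitefront` tracks the top edge of that
whitening zone frame by frame and uses it as an effective crack tip, turning
an ordinary bend-test video plus the tester's load–displacement record into
a full R-curve.

## What it computes

Per retained video frame *i*, synchronised at t = (frame index)/fps with the
force–displacement record:

- subpixel rigid registration of the frame against the first frame
  (DFT-upsampled cross-correlation, default 1/100 px), difference image,
  threshold + morphological cleaning, whitening-front localisation, and the
  monotonicised front displacement Δa(i);
- the ASTM E1820 SE(B) stress intensity
  `K(i) = F(i)·S / (B·W^1.5) · f(a(i)/W)` with `a(i) = a0 + Δa(i)`;
- the J decomposition
  `J(i) = K(i)²(1−ν²)/E + η·A_pl(i)/(B·b0)` (kJ/m²), with A_pl the area
  under force vs plastic displacement `d − F/m` and b0 = W − a0;
- the effective stress intensity `K_eff(i) = sqrt(J(i)·E/(1−ν²))`
  (MPa·m^0.5);
- a plane-stress finite-element correction mapping the apparent flexural
  modulus of a *notched* bar, `E_f = S³m/(4B(W−a0)³)`, back to the modulus
  an un-notched specimen would give (second-order polynomial in a0,
  regenerated by the built-in FE solver);
- Pearson correlation and constant-lag statistics between whitening-front
  and (manually annotated) crack propagation.

A synthetic-data module generates ground-truth videos and mechanics channels
with the structure the pipeline assumes, so every stage is testable with no
external data.

## Worked example

Generate the default synthetic scenario (a 0.9 × 0.9 mm bone-like SE(B)
specimen, 0.35 mm notch, 6.15 mm span, imaged at 10 µm/px, whitening
contrast 10× the sensor noise), track the front, and assemble the R-curve:

```r
library(whitefront)

p  <- scenario_params(seed = 42)
sc <- synth_video(p)
sc$frames
#> frame_sequence: 100 frames of 128x128 px, 60 fps, stride 15

synced <- sync_frames(sc$frames, sc$mech)
tr <- track_front(sc$frames, synced, p$notch_tip_px, sc$calibration,
                  threshold = 0.6 * p$amplitude, join_operator = "opening",
                  roi = p$roi, displacement_mode = "vertical")

fit <- fit_linear_slope(sc$mech$force_N, sc$mech$disp_mm)  # m = 30.90 N/mm
E   <- flexural_modulus(fit$m, p$geometry)                 # 12000 MPa
rc  <- build_rcurve(tr, p$geometry, E = E)

as.data.frame(rc)[c(10, 30, 50), c("da_mm", "a_mm", "force_N",
                                   "J_kJm2", "Keff_MPa_sqrt_m")]
#>    da_mm a_mm force_N  J_kJm2 Keff_MPa_sqrt_m
#> 10  0.05  0.4   0.772  0.0144            0.44
#> 30  0.25  0.6   2.317  0.6348            2.92
#> 50  0.45  0.8   3.862 49.0143           25.69
```

Reading the output: the front has advanced 0.05 → 0.45 mm of the 0.55 mm
ligament; J and K_eff rise with Δa (a rising R-curve), slowly at first and
then steeply as the geometry function f(a/W) grows — K_eff is in the
single-digit MPa·m^0.5 range over the first half of the ligament, which is
the physically meaningful part of the curve. Points with a ≥ W are truncated
automatically. On this scenario the recovered Δa series matches the
generator's programmed front exactly, and the pipeline J(Δa) agrees with the
generator's forward-computed reference to machine precision.

The FE notch correction is regenerated with:

```r
run_fe_correct(list(geometry = list(B = 0.9, W = 0.9, a0 = 0.3, S = 6.15),
                    a0_values_mm = c(0, 0.075, 0.15, 0.3),
                    out_json = "correction.json"))
#> notch correction: ratio(a0) = 1 + 3.192 a0 + 4.692 a0^2 on a0 in [0, 0.3] mm (R2 = 1.0000)
```

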