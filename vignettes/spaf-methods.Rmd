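---
title: "Residue-guided local phasor filtering: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-guided local phasor filtering: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spafr)
```

## The problem

A wrapped phase map reports φ modulo 2π, in (−π, π]. Path-following
unwrappers integrate wrapped neighbor differences and are exact whenever the
true gradient stays below π per pixel. Noise breaks this in a specific,
topological way: it creates *residues*, 2×2 pixel loops around which the
wrapped differences sum to 2πn with n ≠ 0. Around a residue the integral of
the wrapped gradient is path-dependent, so any line-scan unwrapper drags 2π
error streaks across the image.

Filtering can remove residues, but a filter applied to the raw phase blurs
the sawtooth wrap boundaries that the unwrapper needs. The phasor transform
avoids that: exp(iφ) is continuous across wraps, so a windowed statistic of
the phasor followed by the argument,

ψ = arg{ L[exp(iφ)] },

denoises without touching the wrap structure. Applied globally (we call
this the PAF baseline, `global_paf()`), it still blurs everything. The
package's core procedure applies it *only where residues are*.

## The iterative procedure

Each iteration of `spaf()`:

1. compute the residue map and stop if the count is at the target
   (default 0);
2. phasor-filter the full map with the current window `wf`;
3. build the binary patch mask: the union of `wp × wp` squares around the
   anchor pixel of every nonzero charge (the "first pixel in the residue
   loop", top-left of the 2×2 loop);
4. substitute filtered values inside the mask only — pixels outside are
   bit-identical by construction, which is the locality contract the test
   suite asserts exactly;
5. recompute residues (filtering can shift them between neighboring
   pixels, so locations must not be cached across iterations).

When the residue count fails to drop below the best count seen so far, the
schedule escalates: `wf` grows by 2 (windows stay odd) up to `wf_max`; only
when the window is exhausted does `wp` grow by 1 (up to `wp_max`) and the
window escalation restart. Growing the patch before the window would spread
filtering artifacts over more pixels than necessary, which is why window
escalation comes first. The `(wp, wf)` sequence is therefore non-decreasing
lexicographically — a property the tests check on every trace.

Termination is by status, not error: `"residue-free"`, `"cap-reached"`
(both caps exhausted without further progress), or `"max-iter"`. A
`target_residues > 0` supports maps whose residues cannot all be removed.

### When can the count actually reach zero?

Residue charge is conserved under local filtering in the image interior:
the total charge always equals the winding of the boundary loop, so an
isolated vortex (net charge ±1) can be *moved* but never annihilated — only
charge-balanced configurations annihilate in place. Noisy maps nonetheless
reach zero because reflect padding lets filtering rewrite boundary pixels,
so net charge can exit through the image edge. This is also why the test
fixtures for convergence use ±1 vortex *pairs*, and why very small noisy
maps (where a large fraction of residues sit near the border) occasionally
stall at the caps with a handful of survivors while the full-size 400×600
study converges to zero.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `wf_start`, `wf_max` | 3, 15 | px (odd) | phasor filter window; escalated first, in steps of 2 |
| `wp_start`, `wp_max` | 2, 15 | px | patch size; `wp = 2` covers exactly the 2×2 residue loop; escalated second, in steps of 1 |
| `mode` | `"mean"` | — | phasor statistic; `"median"` = marginal median of real/imaginary parts |
| `max_iterations` | 1000 | — | proxy for "a reasonable timescale"; the schedule itself has at most 98 distinct `(wf, wp)` states at the defaults |
| `target_residues` | 0 | count | early-stop level for maps that cannot be fully cleaned |
| `escalation` | `"stall"` | — | escalate on stalled progress (default) or every iteration |

The patch cap of 15 px reflects the practice of bounding patches at a few
times the optical resolution element; with `wp_start = 2` the smallest
possible region (the residue loop itself) is always tried first. The
escalation *granularity* (steps of +2 / +1) and the *trigger* (stall
detection, i.e. no improvement over the best count so far) are package
design choices — the procedure's definition fixes only the order (window
before patch); both the trigger and an unconditional per-iteration
escalation are exposed via `escalation`.

### Mean vs. median phasor statistic

The technique's defining statistic is the phasor average; a windowed median
is the common robust alternative, so both are provided. The median is the
*marginal* median — median of the real parts and of the imaginary parts
independently — because the true geometric (spatial) median has no closed
form and costs an iterative solve per pixel. A consequence worth knowing:
the marginal median is tied to the coordinate axes of the complex plane, so
unlike the mean it does not commute with a global phase rotation
(gauge shift). The test suite asserts exact rotation equivariance for the
mean only. Both statistics can return the zero phasor on balanced antipodal
inputs; such pixels keep their input value and are counted in a message.

## Numerical choices

- **Wrapping interval** (−π, π], matching `Arg()`/`atan2` conventions; an
  input of exactly −π maps to +π. Wrapped differences inherit the tie: an
  exact ±π difference reports +π, which makes `wrap_diff` antisymmetric
  everywhere except on that measure-zero boundary.
- **Loop orientation** counter-clockwise in (row, col) image coordinates,
  charge anchored at the loop's top-left pixel. The orientation choice only
  flips all charge signs globally.
- **Charges** are `round(loop_sum / 2π)`; loop sums of wrapped differences
  are exact multiples of 2π up to ~1e−15 accumulation, far inside the
  rounding tolerance.
- **Border handling** is reflect padding in the filter kernel: zero padding
  would fabricate strong gradients at the border and with them spurious
  edge residues.
- **Patch anchoring**: squares are centered on the anchor pixel and extend
  right/down on ties, so even `wp` works and `wp = 2` covers exactly the
  four loop pixels.
- **Unwrapping exactness**: the 1D routine integrates wrapped differences
  (jump threshold fixed at π, as in the common `unwrap` implementations,
  column-first by default with a `rows-cols` switch). Because 2π is not
  representable in binary floating point, the result is snapped to
  `input + 2π·k` with integer `k`; pixels with `k = 0` are bit-identical to
  the input and the re-wrap agreement is asserted at 1e−12 — the strongest
  statement floating point admits.
- **Spectral curves**: the radial profile averages ln I over annuli of
  uniform thickness 1/`n_bins` in |k|/Nyquist (default 64 bins; corners
  beyond Nyquist ignored; empty annuli inherit their inner neighbor and are
  flagged). Zero intensities are floored at ε·max before the log. Curve
  comparison (`spectral_rse`) converts back to intensity and normalizes
  each curve to its own maximum, which makes the error invariant to global
  intensity rescaling; normalizing the log-curve instead would not be.
- The filter kernel (window mean/median of the phasor with reflect padding)
  is implemented in C++ (Rcpp); every pixel's statistic reads the full
  previous iterate, so patch pixels may be influenced by values outside the
  patch but never the reverse.

## The synthetic generators

`simulated_phase()` is the package's reference study condition: a centered
Gaussian bump of peak 30 rad (σ = 60 px, so the bump spans roughly half the
shorter dimension and wraps into several rings) on 400×600 px, corrupted in
the phasor domain — multiplicative speckle `z·(1 + u)` with `u` zero-mean
uniform of variance 2 (the `imnoise` speckle convention), then additive
complex white Gaussian noise scaled to a *linear* signal-to-noise power
ratio of 6 measured against the speckled field. The "variance 2 / SNR 6"
pairing is read distributively (speckle gets the variance, the additive
noise gets the SNR); a dB reading of the SNR is available via `snr_db`.
Noise lives on the complex field rather than on raw phase values because
residues are a phasor-domain phenomenon: speckle factors crossing zero flip
the local field sign (a π error), which is what seeds residue pairs.
The bump σ is a package choice — the study condition fixes height and image
size but not width.

`vortex_phase()` places exact topological charges for unit tests;
`textured_phase()` is a band-limited random phase with energy across the
band (spectral envelope 1/(1 + k/k₀), k₀ = 0.1 Nyquist), scaled so that no
neighbor difference reaches π — residue-free by construction — standing in
for a high-resolution natural image in resolution-preservation comparisons.
An optional hard band limit (`kmax`) produces strictly band-limited phases
for hologram round-trip tests.

What these generators do *not* emulate: spatially correlated speckle (real
speckle has a grain size set by the optics; ours is i.i.d. per pixel),
detector shot/readout structure, aberrations, and the morphology of real
cellular phase images. Passing tests therefore demonstrate the algorithmic
contract (residue elimination, locality, spectral preservation *ordering*)
under the stated noise model, not performance bounds on any particular
microscope's data.

## The hologram path

`simulate_hologram()` implements two-beam off-axis interference with a
carrier along x (`q` cycles/px), and `demodulate_hologram()` recovers the
object field by cropping a disk of radius `f_na` around the first
diffraction order and shifting it to DC. Separability (0 < f_na < q/2,
q ≤ Nyquist) is enforced at simulation and only warned about at
demodulation (recorded data may violate it). The crop center is refined to
the brightest bin near (+q, 0); consequently a carrier that does not sit on
a DFT bin leaves a sub-bin linear phase ramp across the recovered field —
simulation fixtures use bin-aligned carriers (q·ncols integer). The crop
edge is hard by default (a Gaussian roll-off is available via `soft_edge`),
and the recovered phase is band-limited to `f_na`, which is why round-trip
tests use phases band-limited well inside the crop.

## Problem sizes and runtime

The test suite exercises the full 400×600 study (ten noise seeds) in the
acceptance tests and reduced grids (60×80 to 256×256) elsewhere; one
400×600 run clears ~58k residues in well under a minute on a single core.
The resolution-preservation comparison uses a 256×256 textured phase: SPAF
output versus the global PAF at the smallest window that leaves it
residue-free (searched over odd windows up to 51).

## Known limitations

- Line-scan unwrapping after filtering assumes the *cleaned* map is
  residue-free; when SPAF ends at `"cap-reached"` the output still contains
  residues and `unwrap_phase()` warns. Quality-guided or network-flow
  unwrappers are deliberately out of scope; the output is a plain wrapped
  phase matrix, so any external unwrapper can take over.
- Anisotropic filter windows are supported in `phasor_filter()` but the
  `spaf()` schedule escalates isotropically; automatic anisotropy selection
  is not implemented.
- Net-charge maps (see above) cannot be fully cleaned in the interior; the
  status and trace report this honestly rather than forcing convergence.
- The marginal median mode is not rotation-equivariant (documented above).
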