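---
title: "Methods: simulating and tracking hidden objects through scattering media"
author: "speckletrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and tracking hidden objects through scattering media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speckletrack)
```

## The physical model

A hidden scene at distance $L_o$ behind a strongly scattering layer radiates
spatially incoherent, narrow-band light. Each scene point $x_o$ produces its
own speckle pattern $S(x_o, x_d)$ on a lensless detector at distance $L_s$
on the far side of the layer, and because the illumination is incoherent the
per-point speckles add in intensity:

$$I(x_d) = \int O(x_o)\, S(x_o, x_d)\, d^2x_o .$$

The forward model is therefore exactly linear in the scene $O$, and the
package discretizes it as a weighted sum over lit object pixels
(`renderFrame()`); there are no interference cross-terms between object
points.

Speckles from nearby points are not independent: the optical memory effect
makes the speckle of a point shifted by $\Delta x_o$ a shifted copy of the
original, up to a decorrelation envelope. The package uses the closed-form
intensity correlation

$$\mathcal{C}(\Delta x_o, \Delta x_d) =
  e^{-k^2\,|\Delta\theta_o - \Delta\theta_d|^2\,\sigma^2}\,
  \left(\frac{k\,|\Delta\theta_o|\,L}{\sinh(k\,|\Delta\theta_o|\,L)}\right)^2,$$

with $k = 2\pi/\lambda$, $\sigma$ the Gaussian width of the illumination
intensity profile on the layer, $L$ the layer thickness,
$\Delta\theta_o = \Delta x_o / L_o$ and $\Delta\theta_d = \Delta x_d / L_s$.
The first factor peaks where the detector lag matches the geometrically
scaled object lag; the second — `memoryEnvelope()` — is the memory-effect
decay that limits the isoplanatic patch.

**Units of the Gaussian factor.** Written with lags as lengths the exponent
would not be dimensionless; the package adopts the angular reading above
($\Delta\theta_o - \Delta\theta_d$, $\sigma$ in mm), which makes the
exponent dimensionless and is self-consistent with the simulator: for a
Gaussian beam whose *intensity* profile on the layer is
$\exp(-|\xi|^2/2\sigma^2)$ (variance $\sigma^2$), the speckle field
correlation is the Fourier transform of that profile, and the realized
intensity correlation versus lag mismatch is exactly
$e^{-k^2 \sigma^2 |\Delta\theta_o - \Delta\theta_d|^2}$. The aperture
amplitude used by both simulator backends is accordingly
$A(\xi) = \exp(-|\xi|^2/4\sigma^2)$.

Because the geometry is lensless and pinhole-like, the speckle image axes
are reversed relative to the hidden scene; object motion appears on the
detector scaled by $L_s/L_o$ and negated. `objectToDetectorShift()` /
`detectorToObjectShift()` implement this exact linear map (the default
configuration ships the reference geometry $L_o = 430$ mm, $L_s = 50$ mm,
so the scale factor is $50/430 \approx 0.116$).

## The correlation pipeline

All correlations are mean-subtracted, linear (zero-padded, never circular)
FFT correlations; for $n \times n$ frames the lag map is
$(2n-1)\times(2n-1)$ with zero lag at index $(n, n)$. Mean subtraction
removes the large constant term that would otherwise swamp the informative
structure; after optional windowing the residual mean is subtracted again,
so every map sums to exactly zero.

* `autocorrelate()` — within the memory range the *ensemble* (over screen
  disorder) autocorrelation of a frame is proportional to the object
  autocorrelation blurred by the kernel,
  $\langle I \star I\rangle \propto [O \star O] \otimes \mathcal{C}$,
  which `predictedAutocorrelation()` computes directly by summing, for
  every pair of lit object pixels, a diffraction-limited Gaussian lobe at
  the detector-mapped pair separation weighted by the memory envelope.
  The proportionality constant is never specified by the model, so all
  comparisons are made up to a fitted (or correlation-invariant) scale.
* `crossCorrelate()` between times $t_1$ and $t_0$ — for a scene of
  independently moving sub-objects the map splits into a static part plus
  a moving part that follows the mover.
* `differentialCorrelation()` —
  $I(t_1)\star I(t_0) - I(t_1)\star I(t_1)$. Every static-pair term
  appears identically in both and cancels; what remains is
  $[(o_k(t_0)-o_k(t_1)) \star I(t_1)] \otimes \mathcal{C}$: paired
  positive lobes (old position relative to each background structure) and
  negative lobes (new position), summing to zero for intensity-conserving
  motion. Both terms share one windowing path and one normalization
  factor, so the cancellation is exact — bit-for-bit zero for identical
  frames — rather than merely approximate.

Only relative motion is observable: autocorrelations of real images are
centrosymmetric, so absolute position never enters the maps.

## Simulator backends

A single thin phase screen has an essentially unlimited memory range, so
one backend cannot serve both purposes; the package ships two:

* **physical** (`scatteringScreen(..., backend = "physical")`): spherical
  wave from each source point, Gaussian aperture, uniform random phase
  screen, band-limited angular-spectrum propagation over $L_s$, intensity
  $|u|^2$. Fully developed speckle (unit contrast), exact $-L_s/L_o$
  shifts, near-perfect pairwise correlations. This is the physics oracle
  used for the model-verification and scale-recovery tests.
* **statistical** (`backend = "statistical"`): imposes the finite memory
  envelope directly. The screen field seen from source angle $\theta$ is
  synthesized as $E_\theta(\xi) = \sum_m c_m W_m(\xi)\,
  e^{i q_m \cdot k L \theta}$ with independent white complex Gaussian
  fields $W_m$ and weights $c_m^2$ sampling the 2-D spectral density of
  the target field correlation $\rho(t) = t/\sinh t$ (the square root of
  the intensity envelope, by the Siegert relation for circular Gaussian
  fields). Since $t/\sinh t = \prod_k (1 + t^2/k^2\pi^2)^{-1}$ is
  completely monotone in $t^2$, it is positive definite in two dimensions
  and the spectral weights are provably nonnegative (tiny numerical
  negatives from the Hankel quadrature are clipped, with a warning if the
  clipped mass ever exceeded 1%). This construction realizes the *full
  pairwise* correlation structure — any two source positions decorrelate
  according to their separation, not to a reference point — and, because
  the field is a deterministic function of position given the screen
  seed, a static object reproduces bit-identical speckle in every frame,
  exactly as a static layer does. An earlier design based on mixing each
  source field with a moving local reference realized only the
  correlations to the reference and made static objects weakly
  time-dependent; the spectral synthesis replaced it. Realized pairwise
  correlations in the acceptance sweep match the envelope to within a few
  hundredths, well inside the $\pm 0.1$ acceptance band.

The frequency grid is sized from the object-plane extent the screen must
cover (period $\ge 2.5\times$ the maximal separation in scaled-angle
units, truncated at 99.9% of the spectral mass, capped at 600
components), so thin layers collapse to a handful of components and
thick-layer scenes stay affordable.

Grain-size sanity is enforced everywhere: `expectedGrainDiameter()`
($\lambda L_s / D$ with $D = 4\sigma$ by default) must be at least two
detector pixels or the simulation refuses to run. Camera noise
(`addCameraNoise()`) is Poisson shot noise plus Gaussian read noise with
quantization and clipping, seeded deterministically. The default exposure
metadata (3 s) matches the reference acquisition; no intra-frame motion
blur is simulated.

## Scene generator

Scenes are sums of sub-objects (`SubObject`): nonnegative sprites (disks,
stars, rectangles, rings; 4x supersampled) anchored on the object plane.
`makeDotfieldScene()` builds the many-static-dots-plus-moving-star
tracking scene; `makeMultishapeScene()` the few-shape scene with any
subset mobile. `applyMotion()` re-rasterizes a mover each frame from the
pristine sprite (translation, rotation, scaling, sub-pixel allowed) with
bilinear, intensity-renormalized resampling — total intensity is conserved
to well under 1%, which the zero-mean property of the differential map
requires — while static sub-objects stay bit-identical across frames.
Motion records compose, so several sub-objects can move independently.

What the generator does *not* emulate: photometric DMD calibration,
parallax (depth enters only as apparent-size change), time-varying media,
and the exact shapes used in the reference experiment (the fixtures are
qualitative look-alikes). Passing tests therefore demonstrate the
correlation pipeline and tracker under the stated forward model, not
detector-specific artifacts of any particular camera.

## Tracking

`extractMotionFeatures()` detects lobes above `thresholdSigma` (default
5) times a robust noise level — $1.4826\times$ MAD of the map after
*overlap whitening* (dividing by $\sqrt{(n-|l_r|)(n-|l_c|)/n^2}$, since
the noise variance of a zero-padded correlation scales with the number of
overlapping pixels at each lag) — outside a central exclusion disk
(default radius 3 speckle grains, the residual self-term region), then
pairs negative with nearest positive lobes under an amplitude-ratio gate
of $[1/3, 3]$. Lobe positions are refined by a per-axis 3-point parabolic
fit (flagged integer-peak fallback at the map border).

For trajectories the tracker does not trust a single pair: every static
structure within the memory range votes for the same displacement, so
`buildTrajectory()` forms all admissible (+,−) combinations, clusters
their displacement votes (tolerance 2 px), and takes the SNR-weighted
mean of the heaviest cluster in which each physical lobe is counted once.
The mover's own old-times-new correlation — a strong positive lobe at
minus the displacement paired with the negative residual at zero lag — is
admitted as one more vote (exempt from the ratio gate, since the centre
residual collects every decorrelation term). A lobe pair is the
difference of two like-shaped blobs, $B(\mathrm{lag}) -
B(\mathrm{lag}-d)$, so whenever the step $d$ is comparable to the blob
width the opposite-sign tails push the two peaks apart and bias
peak-based estimates outward. Each selected pair is therefore refined by
a joint two-Gaussian fit along its axis (shared width, opposite signs;
perpendicular component from a per-lobe parabolic offset, where the
partner's gradient vanishes). For overlapping self-pairs a zero-crossing
fallback is used — the crossing between well and lobe sits at exactly
$d/2$ for any blob shape — and well-separated lobes fall back to the
plain parabolic peak, which is unbiased there. Pairing distance is capped
by the detector-mapped memory range, because a trackable step cannot
exceed it.

The reference lag is chosen adaptively among candidates (default
$\{1, 2, 5\}$): the lag whose vote cluster carries the largest total SNR
wins, with a 1.5x switching margin in favour of shorter lags (least
decorrelation); if no candidate reaches `minSnr` the step is declared
no-motion and contributes zero displacement. Steps are chained through
their reference frames (`cum[n] = cum[n - lag] + d`), so stop-and-go
motion accumulates correctly and the cumulative track — exactly the
prefix sum of the reported per-frame steps — can extend far beyond the
memory range, each step only requiring some static structure within range
of the mover ("mosaicing" the memory range). The differential map shows
motion in the mover's frame of reference; the tracker reports the mover's
motion relative to the static background, with the axis reversal undone,
so signs match the hidden-plane motion.

Rotation: for a sub-object rotating about a known pivot,
`estimateRotationAngle()` reads the signed angle subtended by a lobe pair
at the pivot's lag; the axis reversal negates both lobe vectors and
leaves the angle invariant.

## Numerical choices and degenerate inputs

* Zero-lag centre at index $(n, n)$ of the $(2n-1)$ map (even-size inputs
  use this convention throughout).
* Constant frames are rejected (`degenerate frame`) rather than returning
  NaN maps; shape and pitch mismatches are errors.
* `memoryEnvelope()` evaluates the analytic limit 1 below $x = 10^{-8}$
  and returns 0 above $x = 700$ (sinh overflow; true value $<10^{-300}$).
* Normalization modes: `raw` (plain sums, used by every oracle test) and
  `coeff` (values in $[-1, 1]$, default for display and tracking); the
  differential always applies one common factor to both terms.
* Windowing (Tukey $\alpha = 0.25$) is available for edge-artifact
  suppression but off by default; identity-based cancellation tests run
  unwindowed.
* All randomness descends from one integer seed through named
  sub-streams (screen / scene / noise), so every simulation is replayable
  bit-for-bit.

## Problem sizes used by the tests and the acceptance script

Simulation sizes were chosen as the smallest that leave comfortable
statistical margins: $256^2$ frames for the busy-scene zero-mean check
and the 50-screen ensemble verification of the blurred-autocorrelation
model; $128^2$–$160^2$ frames for the tracking studies (memory range 25
object pixels ≈ 1/6 of the field, a 9 px/frame straight run of 81 px ≈
3.2 memory ranges, and a closed 20 px-per-side square walked in 10 px
steps); 20 random motions
for displacement-recovery statistics. The statistical-backend fixtures
place background dots with a minimum separation of 17–18 px so that
distinct dots' lobe pairs stay resolvable at the simulated grain size
(about 2.5 detector px).

## Known limitations

* The tracker assumes one dominant mover per step when chaining a
  trajectory (multi-object *identity* tracking across crossings is out of
  scope; `extractMotionFeatures()` itself reports multiple pairs).
* Two sub-objects moving with exactly opposite displacements can alias
  their lobe votes; the consensus then follows the stronger mover.
* The statistical backend's spectral grid is built for a stated object
  extent; sources outside it wrap (a warning is issued).
* Anisotropic scattering, polarization, partial temporal coherence beyond
  the incoherent-sum assumption, and volumetric transport are not
  modelled; the layer thickness enters only through the memory envelope.
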