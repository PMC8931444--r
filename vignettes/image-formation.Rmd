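---
title: "Model-based image formation for handheld optoacoustic tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based image formation for handheld optoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msotpipe)
```

# The imaging problem

A handheld optoacoustic (photoacoustic) probe illuminates tissue with
nanosecond near-infrared laser pulses; absorbed light launches broadband
ultrasound that is recorded by an arc of piezoelectric detectors. In the
geometry this package models, 256 elements with a 4 MHz centre frequency
cover a 145-degree arc whose endpoint chord is 6 cm; the cavity between
the arc and the skin is filled with heavy water, whose speed of sound
(about 1397 m/s) differs from soft tissue (typically 1480-1560 m/s).
Multispectral acquisition cycles through 28 wavelengths, 700-970 nm in
10 nm steps, at 25 Hz (1.1 s per multispectral frame); pulse-echo
ultrasound (US) frames are interleaved at 6.25 Hz.

The reconstruction unknown is the initial pressure image $p_0$: the
acoustic pressure created at the instant of absorption, proportional to
the local absorbed optical energy. `msotpipe` implements the full
off-line formation chain — signal conditioning, model-based inversion,
motion-corrected compounding, spectral post-processing, US
co-registration, metrics and rendering — together with a synthetic
phantom simulator so every stage is testable without scanner hardware.

# The acoustic forward model

`assembleForwardModel()` discretizes the linear map $M$ from a
pixelized $p_0$ to stacked per-element time traces.

**Two-medium travel times.** The probe membrane is modeled as a planar
horizontal interface at configurable depth, heavy water above, tissue
below; each medium has one speed of sound. Propagation times follow
Fermat's principle over single-breakpoint paths crossing the interface.
The path time is convex in the breakpoint abscissa, so its derivative is
monotone and `msotpipe` finds the breakpoint by vectorized bisection
(90 halvings, i.e. to machine precision). With equal speeds this reduces
exactly to the straight ray. A planar interface is the minimal shape
consistent with a membrane resting on skin; curved membranes are out of
scope.

**Discretization.** Each pixel/element pair contributes a wavelet at its
arrival time: the fractional arrival sample is linearly interpolated onto
the sampling grid, scaled by two-dimensional geometric decay
$1/\sqrt{r}$ (with $r$ the refracted path length, floored at half a
pixel pitch), shaped by a discrete central temporal derivative (the
N-shaped signature of an instantaneous source), and convolved with the
total impulse response (TIR) of the detection chain. All of this is baked
into one sparse matrix, so the adjoint is exact by construction — the
dot-product identity holds to rounding error, which the test suite
checks explicitly. Pixels whose wavelet falls entirely outside the
recording window produce all-zero columns; this is reported as a message
rather than an error, because cropped far corners are routine.

**TIR.** The measured impulse response of a real scanner is not public;
the default synthetic kernel (`tirKernel()`) is a Gaussian-windowed
4 MHz sinusoid — an odd, band-limited, derivative-like signature with a
configurable fractional bandwidth (default 0.6). A measured kernel can be
loaded from a one-column text file (`readKernel()`). One shared temporal
kernel per probe is used; per-element kernels and spatial aperture
effects are deliberately out of scope, as the temporal component
dominates the resolution effect the correction targets.

**Sampling.** The acquisition rate is not dictated by the method; the
default is 40 MHz, comfortably above Nyquist for the 8 MHz upper filter
cut-off (geometry validation rejects rates below 16 MHz). The imaging
grid is pixel-centred, 40 mm x 40 mm onto 401 x 401 pixels at full
scale (0.1 mm pitch).

# Band-pass filtering

Signals are conditioned with a Butterworth band-pass: an 8th-order
low-pass at 8 MHz (matching transducer sensitivity) cascaded with a
2nd-order high-pass at one of three lower cut-offs (LCO), 100/300/700
kHz. Raising the LCO suppresses out-of-plane signal at the cost of
signal-to-noise; the three presets (`lcoPreset()`) feed different
renderings.

Whether the original processing was causal or zero-phase is not
determinable; `bandpass()` defaults to zero-phase (forward-backward)
filtering because causal group delay would shift arrival times and bias
the model fit, and keeps a `"causal"` mode whose single-pass magnitude
is the textbook -3 dB at each cut-off (the zero-phase response is its
square). Traces are reflect-padded by three times the cascade's
effective impulse-response length (measured where the response decays
below $10^{-8}$ of its peak) before filtering.

# Regularized non-negative inversion

Reconstruction solves
$$ p_0 = \arg\min_{p \ge 0} \; \lVert Mp - s\rVert_2^2
   + \alpha \lVert p \rVert_2^2 . $$

Two solvers back `reconstruct()`:

* **Unconstrained** (`nonneg = FALSE`): CGLS — conjugate gradients on the
  augmented system $[M; \sqrt{\alpha} I]\,p = [s; 0]$. On small instances
  this matches a dense solve of $(M^\top M + \alpha I)p = M^\top s$ to
  relative error below $10^{-6}$ (tested).
* **Non-negative** (default): a monotone accelerated projected-gradient
  scheme (FISTA with a monotonicity safeguard that keeps the best
  iterate and restarts momentum when the objective would rise). The step
  is $1/L$ with $L = 2(\lVert M\rVert_2^2 + \alpha)$ estimated by a
  deterministic power iteration. This guarantees a non-increasing
  objective across iterations, which a projected-restarted Krylov scheme
  would not, and is the reason this solver family was chosen.
  Initialization is $p = 0$; defaults are 300 iterations and a relative
  objective-change tolerance of $10^{-8}$, recorded in the image
  provenance together with a `converged` flag (a warning is raised when
  the cap is hit first).

**The meaning of alpha.** By default (`alphaScale = "relative"`) the
effective Tikhonov weight is $\alpha \lVert M \rVert_2^2$: alpha is a
fraction of the operator's spectral energy. This makes a chosen alpha
transferable across grid sizes and geometries, and it makes the L-curve
selection below exactly invariant to a joint rescaling of model and
signals (solutions are unchanged; the log-residual axis merely shifts,
which curvature ignores). `alphaScale = "absolute"` recovers the literal
convention.

**L-curve.** `selectAlphaLcurve()` reconstructs at every candidate
weight and selects the point of maximum curvature of the (log residual
norm, log solution norm) curve. Curvature is the Menger (circumcircle)
curvature of consecutive point triples, evaluated after normalizing the
curve into the unit box and merging points closer than 0.01 of its
diagonal: over-resolved flat stretches of the curve otherwise turn
solver noise into spurious corners. Ties are broken towards the larger
alpha (the smoother image). Known limitation, shared with L-curve
selection generally: at very low noise the error curve is nearly flat in
alpha and the corner sits above the error-optimal weight; the tests
therefore exercise selection at a 5% noise level where the corner is
meaningful.

# Motion correction and frame compounding

Breathing and probe drift move tissue between and within multispectral
frames. `correctAndAverage()` compounds (by default) three consecutive
frames with two levels of elastic registration:

1. **Intra-frame (T1).** Images at 700-890 nm are registered to the
   frame's 800 nm image, where hemoglobin contrast (skin, vessels) gives
   reliable landmarks. Above 900 nm fat dominates the contrast and
   direct registration to 800 nm is unreliable, so those images reuse
   the 890 nm field verbatim.
2. **Inter-frame (T2).** The per-frame mean of the T1-warped 700-890 nm
   images represents each frame; means are registered to the middle
   frame's mean.

Each image is finally warped once by the composed field ($T2 \circ T1$,
composed by resampling displacements) and averaged across frames.

`registerElastic()` maximizes a locally normalized cross-correlation
(square window, radius 4 px) by a demons-type iteration: the analytic
gradient of the local correlation with respect to the warped moving
image drives a force along the image gradient; the update is smoothed
(fluid, sigma 1 px), step-normalized to at most `stepSize` (1 px), added
to the field, and the total field re-smoothed (elastic, sigma 2 px).
Fifty iterations run at each of quarter, half and full resolution, each
level initializing the next. There is no randomness anywhere:
registration is bitwise reproducible. The window radius, smoothing
scales and iteration counts are package defaults chosen for 2-D frames
of this size; none of these hyperparameters is externally prescribed.

Two behaviors worth knowing:

* Registering an image to itself yields an exactly zero field (the local
  correlation force vanishes identically), so motion-free input
  compounds to the plain arithmetic mean exactly.
* Images at different wavelengths genuinely differ in appearance, so T1
  is legitimately nonzero even without motion when a scene mixes
  chromophores; local correlation is insensitive to local intensity
  scaling but not to structural contrast changes. This is the intended
  behavior of appearance-robust registration, not an artifact.

# Spectral median

Chromophore absorption varies smoothly with wavelength, whereas
electrical noise reconstructs into isochrone ring artifacts at arbitrary
single wavelengths. `spectralMedian()` replaces each pixel by the median
of its spectrum over a 40 nm window — five samples on the 10 nm grid —
centred at the display wavelength. At the grid boundary the window is
truncated to the available wavelengths rather than padded (no data is
invented). Order-statistic fine print: a spiked sample never survives
into the output, and the output is always one of the unspiked window
values; when the spiked sample was at or below the window median the
output shifts by exactly one order statistic, which for smooth spectra
is the adjacent wavelength's value.

# Chromophore unmixing

`unmix()` solves, per pixel, the non-negative least-squares system
$S c = p,\; c_i \ge 0$ with $S$ the stacked absorption spectra of
oxyhemoglobin, deoxyhemoglobin, fat and water (Lawson-Hanson NNLS via
`pracma::lsqnonneg`). No fluence correction is applied before unmixing;
depth-dependent spectral coloring therefore biases coefficients and the
maps are relative, not quantitative.

The bundled library (`defaultChromophoreLibrary()`) is **synthetic**:
smooth parametric curves reproducing the qualitative near-infrared
features that drive unmixing (deoxyhemoglobin falling across the range
with its ~760 nm bump, oxyhemoglobin rising, the lipid peak near 930 nm,
water rising towards 970 nm). Exact published tabulations could not be
redistributed here; any measured table can be swapped in as a CSV via
`readChromophoreLibrary()`, and all unmixing tests are
library-agnostic (they verify exact recovery of mixtures composed from
whatever library is in use).

# Ultrasound co-registration

Scanner US images assume one homogeneous speed of sound and are
therefore spatially distorted relative to the dual-SoS optoacoustic
frame. The correction estimates an affine between two reconstructions of
the *same* optoacoustic signals — one dual-SoS, one uniform — and
applies it to the US frames (`estimateAffine()`, `warpUS()`). The
similarity is global normalized cross-correlation, optimized by a
deterministic Nelder-Mead simplex over the six affine parameters at
quarter, half and full resolution, initialized at the identity; if the
optimum fails to improve on the identity, the identity is returned with
a warning. With equal speeds the two models coincide and the estimated
affine is the identity (tested to $\lVert A - I\rVert < 10^{-2}$).

US frames concurrent with one multispectral frame are averaged over the
closed interval $[t_0, t_0 + 1.1\,\mathrm{s}]$ — at 6.25 Hz that selects
$\lfloor 1.1 \cdot 6.25\rfloor + 1 = 7$ frames when acquisition starts
on the boundary. Inclusive endpoints are a convention choice; it is
recorded here because the alternative half-open rule selects one frame
fewer.

Tumor masks are *inputs* (drawn by a radiologist on the US images); the
package draws their contours but never computes them.

# Metrics

**CNR.** `computeCNR()` implements
$\mathrm{CNR} = 10\log_{10}\,(\mu_{OBJ}-\mu_{BKG})/(\sigma_{OBJ}+\sigma_{BKG})$
with $\sigma$ the *variance* within each region — the literal form this
pipeline reports — and a `denominator = "sd"` switch for the
conventional standard-deviation form. The object is the tissue band down
to 1.5 cm under the skin line, the background the area above it
(`regionMasksFromSkin()`). Consequences of the variance denominator,
both asserted in tests: CNR is invariant to adding a constant but *not*
to rescaling (multiplying by $k$ shifts it by $10\log_{10}(1/k)$);
averaging three i.i.d. frames raises it by $10\log_{10} 3 \approx
4.77$ dB. A non-positive numerator yields a flagged report rather than
an error so batch tables can skip undefined entries.

**FWHM.** `fwhm()` measures the linear-interpolated width between the
half-maximum crossings flanking the profile peak, with the half level
midway between the profile's minimum and maximum so the measure is
invariant under positive affine intensity rescaling.

# Visualization

All transforms are deterministic and shape-preserving; renders live in
$[0,1]^3$.

* `localContrastNorm()`: divide by the maximum of the L1-ball
  neighborhood mean (border-clipped) and a global percentile floor.
* `sigmoidNorm()`: logistic mapping anchored so the $P_a$/$P_b$
  percentiles land at $a$/$b$. Percentiles are computed over nonzero
  pixels by default (background-dominated images would pin low
  percentiles at zero); a switch restores all-pixel percentiles.
* `powerUnsharp()`: $I^\gamma$ then $I + \alpha (I - G_s * I)$.
* `enhanceUS()`: $e^{0.15 d}\,\sigma((I - 0.9)/0.2)$ with $d$ the depth
  below the tissue surface in centimetres, clamped to 0 above it.
* `renderDualBand()`: bilinear 2-D colormap over (low-band, high-band)
  pairs; default corners black / red / yellow / white so large
  low-frequency structures render red and fine high-frequency detail
  yellow-white. The corner colors are package defaults (fully
  configurable) — no external reference prescribes them.
* `renderUnmixing()`: oxyhemoglobin to red, deoxyhemoglobin to blue, fat
  to green; water is computed but never displayed.
* `renderHybrid()`: per channel $(1-a)\,US + a\,\mathrm{hue}$ with the
  blend weight $a$ equal to the normalized optoacoustic intensity — a
  standard alpha blend chosen here as the package's own convention —
  plus an optional mask contour (boundary pixels only; the interior is
  untinted).

# The synthetic phantom simulator

`vesselGridPhantom()` scatters pure-chromophore disk "vessels" under a
water/fat skin layer; `pressureMap()` converts concentrations to $p_0$
per wavelength through the library, with an optional single-exponential
depth fluence decay (off by default so ground truth stays linear in the
maps; switch it on to demonstrate spectral coloring).
`simulateSignals()` is a deliberately independent forward
implementation — dense per-element summation, travel times by coarse
breakpoint scanning plus golden-section refinement — so the sparse model
can be cross-checked against it (they agree to well below the 2% RMS
test bound). `injectSignalNoise()` adds white per-channel noise and a
channel-shared coherent trace (which reconstructs onto isochrone rings);
`injectNoiseAndMotion()` applies seeded smooth random warps and
multiplicative single-wavelength spikes, returning the ground-truth
fields for registration scoring.

What the simulator does *not* emulate — and what passing tests therefore
do not show about scanner data: acoustic attenuation and dispersion,
element directivity and finite aperture, 3-D (out-of-plane) propagation,
ultrasound speckle, fluence heterogeneity beyond a depth exponential,
and real electronics noise spectra. Results on synthetic data bound the
method's correctness, not its clinical image quality.

# Numerical choices and problem sizes

* Bisection/golden-section travel-time tolerances are at machine
  precision; the two implementations are independent by construction.
* The solver starts at $p = 0$; the power iteration for
  $\lVert M\rVert_2$ starts from a constant vector (40 iterations),
  keeping everything deterministic.
* L-curve ties break towards larger alpha; degenerate curves (all
  points identical, e.g. zero signals) are an error.
* Geometric decay is floored at half a pixel pitch to avoid a singular
  self-term.
* Tests and the acceptance script run at desk scale: grids of 20-101
  pixels per side, 4-64 elements, 512-1024 samples, three frames, full
  28-wavelength stacks where spectra matter. These sizes were chosen so
  the whole suite exercises every stage in a few minutes while the
  properties tested (adjoint identity, exact recovery, registration
  accuracy, order statistics) are size-independent. Full scale
  (401 x 401, 256 elements) is supported but not optimized — model
  assembly is the dominant cost.

# Known limitations

* 2-D modeling only; the elevational dimension is ignored.
* One planar interface, two homogeneous media; no heterogeneous maps.
* The tissue speed of sound is a per-scan configuration value; nothing
  estimates it from data.
* The bundled chromophore library is synthetic (see above).
* The L-curve corner over-smooths at very low noise.
* CNR with the variance denominator is intensity-scale dependent; use
  the `"sd"` switch for scale-free comparisons across normalizations.
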