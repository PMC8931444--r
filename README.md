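# msotpipe

Model-based image formation for handheld multispectral optoacoustic
(photoacoustic) tomography with co-registered ultrasound.

Optoacoustic scanners record broadband ultrasound generated by pulsed
near-infrared light absorption in tissue. Forming a faithful image of
the initial pressure p₀ from a handheld probe requires more than
delay-and-sum: the heavy-water coupling cavity and tissue have different
speeds of sound (with refraction at their interface), the detection
chain imprints its total impulse response (TIR) on every wavelet, the
patient and probe move between frames, and electrical noise reconstructs
into ring artifacts. `msotpipe` implements the complete off-line
formation chain for this setting, for researchers working on
optoacoustic reconstruction and image quality:

* **Acoustic forward model** — sparse operator with Fermat two-medium
  refracted travel times, 1/√r geometric decay, temporal derivative and
  TIR convolution (`assembleForwardModel`).
* **Band-pass conditioning** — 8th-order low-pass at 8 MHz + 2nd-order
  high-pass at 100/300/700 kHz (`bandpass`, `lcoPreset`).
* **Regularized inversion** — the non-negative Tikhonov problem

      p0 = argmin_{p >= 0}  || M p - s ||² + alpha || p ||²

  solved by monotone accelerated projected gradients (CGLS in
  unconstrained mode), with L-curve selection of alpha
  (`reconstruct`, `selectAlphaLcurve`).
* **Motion-corrected compounding** — two-level elastic registration
  (intra-frame T1 to the 800 nm image with T1-reuse above 890 nm, then
  inter-frame T2) driven by neighborhood cross-correlation at ¼/½/full
  resolution, followed by frame averaging (`registerElastic`,
  `correctAndAverage`).
* **Spectral processing** — per-pixel spectral median over a 40 nm
  window and non-negative least-squares chromophore unmixing
  (`spectralMedian`, `unmix`).
* **US co-registration** — affine between dual- and single-SoS
  reconstructions, applied to scanner ultrasound, plus concurrent-frame
  averaging (`estimateAffine`, `warpUS`, `averageConcurrentUS`).
* **Metrics and rendering** — CNR (variance-denominator form, in dB),
  FWHM line profiles, local-contrast/sigmoid/power/unsharp display
  transforms, US depth-gain enhancement, dual-band 2-D colormaps,
  unmixing RGB and hybrid optoacoustic/US overlays.
* **Synthetic phantoms** — a seeded vessel-phantom generator and an
  independent direct-summation signal simulator with white, coherent
  (ring-artifact) and single-wavelength spike noise plus smooth motion,
  so the whole pipeline is testable without scanner data.

## Worked example

Simulate a vessel phantom, reconstruct it, and measure image quality:

```r
library(msotpipe)

g <- probeGeometry(nElements = 64, samplingRate = 2e7, nSamples = 1024,
                   gridShape = c(101, 101), fov = c(40, 40))
phantom <- vesselGridPhantom(g, nVessels = 6, seed = 7)
p0 <- pressureMap(phantom, 800)                  # ground truth at 800 nm
signals <- simulateSignals(p0, g, wavelength = 800)
filtered <- bandpass(signals, lcoPreset(700))
model <- assembleForwardModel(g, tir = deltaKernel(), sosMode = "dual")
img <- reconstruct(filtered, model,
                   reconConfig(alpha = 1e-5, maxIterations = 300))
img
#> ReconImage: 101 x 101 px, lambda = 800 nm [alpha, alphaEffective, ...]
cor(as.vector(pixels(img)), as.vector(p0))
#> [1] 0.998

masks <- regionMasksFromSkin(skinLine = 3, shape = dim(pixels(img)),
                             pitch = 0.4)
computeCNR(pixels(img), masks)
#> CNR = 3.51 dB
#>   mu: 0.02944 / 0.002973  var: 0.01177 / 1.762e-05 (obj/bkg), denominator = variance

row <- which.max(apply(pixels(img), 1, max))
fwhm(pixels(img)[row, ], pitch = 400)            # 0.4 mm pixels
#> [1] 1996
```

The reconstruction correlates at r = 0.998 with the noiseless ground
truth; the CNR report carries the object/background means and variances
that enter the decibel figure, and the line profile across the brightest
vessel has a full width at half maximum of about 2.0 mm — the vessel's
actual diameter at this desk scale.

The methods vignette (`vignettes/image-formation.Rmd`) documents the
model, the solver, the registration scheme, every tunable parameter and
the design decisions in detail.

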