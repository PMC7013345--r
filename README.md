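# pdtmon

Quantitative monitoring of topical photodynamic therapy (PDT) with the
photosensitizer chlorin e6, for researchers running comparative light-dose
studies in thin layered tissue (the motivating system is the rabbit ear: a
1 mm skin / cartilage / skin sandwich irradiated at 405 or 660 nm).

The package implements, as tested reusable components:

* **Layered-tissue Monte Carlo dosimetry** — weighted-photon transport in a
  planar slab (isotropic scattering at the reduced coefficient μs′, Fresnel
  boundaries, Russian roulette), yielding the depth-resolved absorbed dose
  density A(z) (mm⁻¹, per photon launched per unit area) and the
  specular / diffuse-reflected / transmitted / absorbed energy fractions.
* **Photobleaching kinetics** — ROI segmentation of fluorescence images,
  the photobleaching efficiency PE = (If₁ − If₂)/If₁ · 100 %, and
  nonlinear-least-squares fits of the decay If(D) = If₁ e^(−αD) with the
  rate α in inverse dose units (J/cm²)⁻¹.
* **Red-to-blue ratio depth inference** — the ratio Rλ = If660/If405 rises
  with photosensitizer penetration depth; a Monte Carlo forward model
  (excitation fluence × concentration × escape fraction) builds a monotone
  Rλ(d) calibration curve that `estimateDepth()` inverts.
* **Synthetic sessions and ordinal outcomes** — a generator for
  dual-wavelength image sessions with single-exponential bleaching at the
  tabulated rates (blue-light procedure: α = 0.011/0.009 (J/cm²)⁻¹ at
  405/660 nm excitation; red-light: 0.014/0.017), multiplicative noise, and
  four-level edema grade tables over the 20 exposure regimes.
* **An end-to-end pipeline** — `runMonitoringPipeline()` chains
  segmentation → intensities → PE → rate fits → Rλ trend → depth estimate →
  dosimetry into a serializable report.

## Worked example

A blue-light 50 J/cm² procedure on a synthetic session (5 % measurement
noise), followed by standalone dosimetry at 405 nm:

```r
library(pdtmon)

rep <- runMonitoringPipeline(runConfig(regime = "PDT_b50", seed = 7))
rep
#> RunReport (PDT_b50)
#>   405 nm: alpha = 0.01276 (J/cm2)^-1, PE = 50.8%
#>   660 nm: alpha = 0.008823 (J/cm2)^-1, PE = 35.2%
#>   R-lambda trend: rising; PS depth ~ 0.10 mm (out of range)

m405 <- defaultRabbitEarModel(405)
r405 <- simulateTransport(m405, transportConfig(nPhotons = 1e6, seed = 1))
r405
#> TransportResult: 1e+06 photons, 100 depth bins of 0.01 mm
#>   specular 0.0337 | diffuse 0.1479 | transmitted 0.0166 | absorbed 0.8018
round(layerAbsorbedFractions(r405, m405), 4)
#>    skin_top   cartilage skin_bottom
#>      0.6907      0.0083      0.1028
```

Reading the output: the fitted rates straddle the generating values
(0.011/0.009 (J/cm²)⁻¹) within the noise of a single 3-point-per-decade
session; the bleaching efficiency at 405 nm exceeds the ~40 % level
conventionally read as a successful procedure; and the **rising** red-to-blue
ratio is the blue-light signature (superficial layers bleach fastest). The
depth estimate is flagged out-of-range because the synthetic session uses
equal initial intensities at both excitations (ratio 1.0) with an
uncalibrated instrument constant κ = 1 — the flag, not a number, is the
correct answer there. The dosimetry table shows 69 % of the launched energy
absorbed in the top 0.4 mm skin layer at 405 nm; the same run at 660 nm
spreads its (smaller) absorbed fraction through the whole depth.

## Documentation

The methods vignette (`vignettes/pdt-monitoring.Rmd`) explains the
transport model and its similarity-domain assumption, the estimator
choices, what the synthetic generator does and does not emulate, and the
package's numerical conventions. Function-level documentation is in the
roxygen comments under `R/`.
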