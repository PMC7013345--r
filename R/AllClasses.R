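## S4 classes for the PDT monitoring toolkit.

#' TissueModel: planar layered optical tissue model
#'
#' An ordered stack of optical layers (top layer first), each described by its
#' thickness (mm), refractive index and the absorption and reduced scattering
#' coefficients (mm^-1) at the working wavelength. The slab is bounded by
#' ambient media (air by default) above and below.
#'
#' @slot layers data.frame with columns \code{name}, \code{thickness_mm},
#'   \code{n}, \code{mua}, \code{musp}; one row per layer, top first.
#' @slot nAmbientTop,nAmbientBottom refractive indices of the bounding media.
#' @slot wavelength working wavelength in nm (\code{NA} if unspecified).
#' @export
setClass("TissueModel",
  representation(layers = "data.frame",
                 nAmbientTop = "numeric", nAmbientBottom = "numeric",
                 wavelength = "numeric"))

setValidity("TissueModel", function(object) {
  ly <- object@layers
  need <- c("name", "thickness_mm", "n", "mua", "musp")
  if (!all(need %in% names(ly)))
    return(paste("layers must have columns", paste(need, collapse = ", ")))
  if (nrow(ly) < 1) return("at least one layer is required")
  num <- ly[c("thickness_mm", "n", "mua", "musp")]
  if (!all(vapply(num, is.numeric, logical(1)))) return("layer fields must be numeric")
  if (any(!is.finite(ly$thickness_mm)) || any(ly$thickness_mm <= 0))
    return("layer thickness must be finite and > 0")
  if (any(ly$n < 1)) return("layer refractive index must be >= 1")
  if (any(ly$mua < 0) || any(ly$musp < 0))
    return("mua and musp must be non-negative")
  if (any(ly$mua == 0 & ly$musp == 0))
    return("a layer with mua = 0 and musp = 0 supports no transport")
  if (length(object@nAmbientTop) != 1 || object@nAmbientTop < 1 ||
      length(object@nAmbientBottom) != 1 || object@nAmbientBottom < 1)
    return("ambient refractive indices must be single values >= 1")
  TRUE
})

#' TransportConfig: Monte Carlo run configuration
#'
#' @slot nPhotons number of photon packets to launch.
#' @slot zBin depth bin width in mm.
#' @slot rouletteThreshold packet weight below which Russian roulette starts.
#' @slot rouletteSurvival roulette survival probability.
#' @slot seed integer seed; runs are bit-identical for a fixed seed.
#' @export
setClass("TransportConfig",
  representation(nPhotons = "numeric", zBin = "numeric",
                 rouletteThreshold = "numeric", rouletteSurvival = "numeric",
                 seed = "integer"))

setValidity("TransportConfig", function(object) {
  if (length(object@nPhotons) != 1 || object@nPhotons < 1)
    return("nPhotons must be >= 1")
  if (length(object@zBin) != 1 || object@zBin <= 0) return("zBin must be > 0")
  if (object@rouletteSurvival <= 0 || object@rouletteSurvival >= 1)
    return("rouletteSurvival must lie in (0, 1)")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("an integer seed is required")
  TRUE
})

#' TransportResult: depth-resolved absorbed dose and boundary fractions
#'
#' \code{absorbedDensity} is A(z): photons absorbed per unit volume per photon
#' launched per unit area (mm^-1), on the depth grid \code{zCenters} (z = 0 at
#' the irradiated surface, increasing downward). The four energy fractions
#' (specular reflectance, diffuse reflectance, transmittance, total absorbed)
#' sum to one up to Monte Carlo noise.
#'
#' @export
setClass("TransportResult",
  representation(zCenters = "numeric", absorbedDensity = "numeric",
                 rSpecular = "numeric", rDiffuse = "numeric",
                 transmitted = "numeric", absorbedTotal = "numeric",
                 nPhotons = "numeric", zBin = "numeric", seed = "integer"))

setValidity("TransportResult", function(object) {
  fr <- c(object@rSpecular, object@rDiffuse, object@transmitted,
          object@absorbedTotal)
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12))
    return("energy fractions must lie in [0, 1]")
  if (length(object@zCenters) != length(object@absorbedDensity))
    return("zCenters and absorbedDensity lengths differ")
  if (abs(object@absorbedTotal -
          sum(object@absorbedDensity) * object@zBin) > 1e-9)
    return("absorbedTotal must equal the integral of absorbedDensity")
  TRUE
})

#' FluorescenceFrame: one 2-D fluorescence image with acquisition metadata
#'
#' @slot pixels non-negative intensity matrix (arbitrary units).
#' @slot excitationNm excitation wavelength, 405 or 660.
#' @slot cumulativeDose cumulative delivered light dose in J/cm^2.
#' @export
setClass("FluorescenceFrame",
  representation(pixels = "matrix", excitationNm = "numeric",
                 cumulativeDose = "numeric"))

setValidity("FluorescenceFrame", function(object) {
  if (!is.numeric(object@pixels)) return("pixels must be numeric")
  if (any(object@pixels < 0)) return("pixel intensities must be non-negative")
  if (!object@excitationNm %in% c(405, 660))
    return("excitationNm must be 405 or 660")
  if (object@cumulativeDose < 0) return("cumulativeDose must be >= 0")
  TRUE
})

#' DoseSeries: ROI-mean fluorescence versus cumulative delivered dose
#'
#' @slot doses strictly increasing cumulative doses (J/cm^2) starting at 0.
#' @slot intensities positive ROI-mean fluorescence intensities (a.u.).
#' @slot excitationNm excitation wavelength, 405 or 660.
#' @export
setClass("DoseSeries",
  representation(doses = "numeric", intensities = "numeric",
                 excitationNm = "numeric"))

setValidity("DoseSeries", function(object) {
  if (length(object@doses) != length(object@intensities))
    return("doses and intensities lengths differ")
  if (length(object@doses) < 1) return("empty series")
  if (object@doses[1] != 0) return("dose grid must start at 0")
  if (any(diff(object@doses) <= 0)) return("doses must be strictly increasing")
  if (any(object@intensities <= 0)) return("intensities must be positive")
  if (!object@excitationNm %in% c(405, 660))
    return("excitationNm must be 405 or 660")
  TRUE
})

#' BleachFit: single-exponential photobleaching fit If(D) = If1 exp(-alpha D)
#'
#' @slot if1 fitted initial intensity (a.u.).
#' @slot alpha photobleaching rate in inverse dose units, (J/cm^2)^-1.
#' @slot alphaSe standard error of \code{alpha} from the fit covariance.
#' @slot rSquared goodness of fit in [0, 1].
#' @slot nPoints number of dose points used.
#' @export
setClass("BleachFit",
  representation(if1 = "numeric", alpha = "numeric", alphaSe = "numeric",
                 rSquared = "numeric", nPoints = "integer"))

setValidity("BleachFit", function(object) {
  if (object@if1 <= 0) return("if1 must be positive")
  if (object@rSquared < 0 || object@rSquared > 1)
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' PSProfile: photosensitizer depth profile after topical application
#'
#' Either uniform from the surface down to \code{depth} (the default for a
#' topically applied drug) or exponentially decaying with 1/e depth
#' \code{depth}.
#'
#' @export
setClass("PSProfile",
  representation(shape = "character", depth = "numeric",
                 concentrationScale = "numeric"))

setValidity("PSProfile", function(object) {
  if (!object@shape %in% c("uniform", "exponential"))
    return("shape must be 'uniform' or 'exponential'")
  if (object@depth <= 0) return("depth must be positive")
  if (object@concentrationScale < 0)
    return("concentrationScale must be non-negative")
  TRUE
})

#' FluorescenceForwardConfig: tissue models for the ratio-depth forward model
#'
#' Holds the excitation tissue models at 405 and 660 nm, the emission-band
#' model used for the escape function, the instrument ratio calibration
#' constant kappa and the Monte Carlo configuration.
#'
#' @export
setClass("FluorescenceForwardConfig",
  representation(model405 = "TissueModel", model660 = "TissueModel",
                 emissionModel = "TissueModel", kappa = "numeric",
                 mcConfig = "TransportConfig"))

setValidity("FluorescenceForwardConfig", function(object) {
  if (object@kappa <= 0) return("kappa must be positive")
  t1 <- sum(object@model405@layers$thickness_mm)
  t2 <- sum(object@model660@layers$thickness_mm)
  if (abs(t1 - t2) > 1e-9)
    return("excitation models must share the same total thickness")
  TRUE
})

#' RatioDepthCurve: monotone lookup from red-to-blue ratio to PS depth
#'
#' @slot depths increasing grid of photosensitizer penetration depths (mm).
#' @slot ratios model red-to-blue ratios at those depths (strictly increasing
#'   on the default rabbit-ear model).
#' @slot kappa instrument calibration constant the ratios were computed with.
#' @export
setClass("RatioDepthCurve",
  representation(depths = "numeric", ratios = "numeric", kappa = "numeric"))

setValidity("RatioDepthCurve", function(object) {
  if (length(object@depths) < 2) return("at least two depth points required")
  if (length(object@depths) != length(object@ratios))
    return("depths and ratios lengths differ")
  if (any(diff(object@depths) <= 0))
    return("depths must be strictly increasing")
  TRUE
})

#' SessionSpec: generative model for a synthetic dual-wavelength session
#'
#' Encodes a single-exponential photobleaching session: initial intensities
#' and bleaching rates at both excitation wavelengths, the cumulative dose
#' grid, multiplicative measurement noise (coefficient of variation), and the
#' image geometry (a bright fluorescing disc on a dark background).
#'
#' @export
setClass("SessionSpec",
  representation(if1405 = "numeric", if1660 = "numeric",
                 alpha405 = "numeric", alpha660 = "numeric",
                 doses = "numeric", noiseCv = "numeric",
                 nReplicates = "integer", seed = "integer",
                 imageDim = "integer", roiCenter = "numeric",
                 roiRadius = "numeric", background = "numeric"))

setValidity("SessionSpec", function(object) {
  if (object@if1405 <= 0 || object@if1660 <= 0)
    return("initial intensities must be positive")
  if (object@alpha405 < 0 || object@alpha660 < 0)
    return("bleaching rates must be non-negative")
  if (object@doses[1] != 0 || any(diff(object@doses) <= 0))
    return("doses must start at 0 and increase strictly")
  if (object@noiseCv < 0 || object@noiseCv >= 1)
    return("noiseCv must lie in [0, 1)")
  if (object@nReplicates < 1) return("nReplicates must be >= 1")
  if (length(object@imageDim) != 2 || any(object@imageDim < 4))
    return("imageDim must be two dimensions >= 4")
  if (object@roiRadius <= 0) return("roiRadius must be positive")
  r <- object@roiRadius; ctr <- object@roiCenter
  if (ctr[1] - r < 1 || ctr[1] + r > object@imageDim[1] ||
      ctr[2] - r < 1 || ctr[2] + r > object@imageDim[2])
    return("ROI disc must fit inside the image")
  if (object@background < 0) return("background must be >= 0")
  TRUE
})

#' RunReport: end-to-end monitoring pipeline results
#'
#' @slot fits named list of \linkS4class{BleachFit} per excitation wavelength.
#' @slot pe named numeric, photobleaching efficiency (%) per excitation.
#' @slot ratioSeries data.frame with dose and red-to-blue ratio columns.
#' @slot ratioTrend "rising", "falling" or "flat".
#' @slot depthEstimate estimated PS penetration depth (mm).
#' @slot depthOutOfRange TRUE if the observed ratio fell outside the curve.
#' @slot doseSummary list of per-layer absorbed fractions per wavelength.
#' @slot provenance list with config echo, hash, seeds and package version.
#' @export
setClass("RunReport",
  representation(fits = "list", pe = "numeric", ratioSeries = "data.frame",
                 ratioTrend = "character", depthEstimate = "numeric",
                 depthOutOfRange = "logical", doseSummary = "list",
                 provenance = "list"))
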