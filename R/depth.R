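## Ratio-to-depth forward model and inversion.
##
## The forward model composes three Monte Carlo quantities on a common depth
## grid: the excitation fluence-equivalent profile Phi(z) (recovered from the
## transport result as A(z)/mua(z), valid because every layer of the default
## model absorbs), the photosensitizer concentration profile C(z), and the
## escape fraction E(z) for isotropic emission at depth z through the top
## surface. The detected intensity is the quadrature
##   I = sum_z Phi(z) C(z) E(z) dz,
## and the red-to-blue ratio R(d) = kappa * I_660exc(d) / I_405exc(d) grows
## with photosensitizer depth because red excitation light penetrates deeper.

#' Photosensitizer depth profile
#'
#' @param shape "uniform" (constant concentration from the surface to
#'   \code{depth}, the default for topical application) or "exponential"
#'   (exp(-z/depth)).
#' @param depth penetration depth d in mm (> 0).
#' @param concentrationScale relative concentration scale (a.u., > 0).
#' @return A \linkS4class{PSProfile}.
#' @export
psProfile <- function(shape = c("uniform", "exponential"), depth,
                      concentrationScale = 1) {
  new("PSProfile", shape = match.arg(shape), depth = as.numeric(depth),
      concentrationScale = as.numeric(concentrationScale))
}

#' Forward-model configuration for ratio-depth curves
#'
#' @param model405,model660 excitation \linkS4class{TissueModel}s at the two
#'   wavelengths.
#' @param emissionModel tissue model for the 702-842 nm detection band; the
#'   660 nm optics are the default stand-in (nearest tabulated band; red/NIR
#'   skin properties vary slowly).
#' @param kappa instrument ratio calibration constant (> 0, default 1).
#' @param mcConfig a \linkS4class{TransportConfig}.
#' @return A \linkS4class{FluorescenceForwardConfig}.
#' @export
fluorescenceForwardConfig <- function(model405 = defaultRabbitEarModel(405),
                                      model660 = defaultRabbitEarModel(660),
                                      emissionModel = model660,
                                      kappa = 1, mcConfig) {
  new("FluorescenceForwardConfig", model405 = model405, model660 = model660,
      emissionModel = emissionModel, kappa = as.numeric(kappa),
      mcConfig = mcConfig)
}

# mua at each depth-bin center, by layer lookup.
.muaAtDepth <- function(model, zCenters) {
  zb <- boundaryDepths(model)
  idx <- findInterval(zCenters, zb, rightmost.closed = TRUE)
  idx[idx > nrow(model@layers)] <- nrow(model@layers)
  model@layers$mua[idx]
}

# Fluence-equivalent depth profile from a transport result: Phi = A / mua.
.fluenceProfile <- function(result, model) {
  mua <- .muaAtDepth(model, result@zCenters)
  if (any(mua <= 0))
    stop("fluence recovery needs mua > 0 in every layer")
  result@absorbedDensity / mua
}

#' Escape fraction for isotropic emission at depth
#'
#' Fraction of photons launched isotropically at each depth that exit the top
#' surface at any angle, under the given (emission-band) tissue model.
#'
#' @param model a \linkS4class{TissueModel}.
#' @param z depths in mm (within the slab).
#' @param config a \linkS4class{TransportConfig}; \code{nPhotons} packets are
#'   launched per depth.
#' @return Numeric vector of escape fractions in [0, 1].
#' @export
escapeFunction <- function(model, z, config) {
  stopifnot(is(model, "TissueModel"), is(config, "TransportConfig"))
  ly <- model@layers
  .mc_escape_cpp(ly$thickness_mm, ly$n, ly$mua, ly$musp,
                 model@nAmbientTop, model@nAmbientBottom,
                 z, config@nPhotons, config@rouletteThreshold,
                 config@rouletteSurvival, config@seed)
}

.concentrationAtDepth <- function(ps, zCenters) {
  c0 <- ps@concentrationScale
  switch(ps@shape,
         uniform = ifelse(zCenters < ps@depth, c0, 0),
         exponential = c0 * exp(-zCenters / ps@depth))
}

#' Detected fluorescence intensity for a photosensitizer profile
#'
#' Quadrature of excitation fluence x concentration x escape fraction over
#' the depth grid. Deterministic for fixed Monte Carlo seeds (the escape run
#' uses a sub-seed derived from \code{mc@seed}).
#'
#' @param tissueAtExcitation \linkS4class{TissueModel} at the excitation
#'   wavelength.
#' @param emissionModel \linkS4class{TissueModel} for the detection band.
#' @param ps a \linkS4class{PSProfile}; a uniform profile deeper than the
#'   slab is an error.
#' @param mc a \linkS4class{TransportConfig}.
#' @return Detected intensity (a.u.).
#' @export
simulateFluorescenceResponse <- function(tissueAtExcitation, emissionModel,
                                         ps, mc) {
  tot <- totalThickness(tissueAtExcitation)
  if (ps@shape == "uniform" && ps@depth > tot + 1e-9)
    stop("photosensitizer profile extends deeper than the slab")
  tr <- simulateTransport(tissueAtExcitation, mc)
  phi <- .fluenceProfile(tr, tissueAtExcitation)
  esc <- escapeFunction(emissionModel, tr@zCenters,
                        transportConfig(nPhotons = mc@nPhotons,
                                        zBin = mc@zBin,
                                        rouletteThreshold = mc@rouletteThreshold,
                                        rouletteSurvival = mc@rouletteSurvival,
                                        seed = deriveSeed(mc@seed, 7)))
  conc <- .concentrationAtDepth(ps, tr@zCenters)
  sum(phi * conc * esc) * mc@zBin
}

#' Build the red-to-blue ratio versus depth calibration curve
#'
#' For each depth d on the grid, computes the model ratio
#' R(d) = kappa * I_660exc(d) / I_405exc(d) for a photosensitizer distributed
#' uniformly from the surface to d. The excitation fluence profiles and the
#' escape function are each computed once from dedicated Monte Carlo runs and
#' reused across depths. On the default rabbit-ear model the curve is
#' strictly increasing; a non-monotone curve (beyond Monte Carlo noise)
#' raises an error rather than being silently accepted.
#'
#' @param config a \linkS4class{FluorescenceForwardConfig}.
#' @param depths increasing grid of candidate depths (mm), at least 3, within
#'   the slab.
#' @return A \linkS4class{RatioDepthCurve}.
#' @examples
#' \donttest{
#' cfg <- fluorescenceForwardConfig(
#'   mcConfig = transportConfig(nPhotons = 2e4, seed = 7))
#' curve <- buildRatioDepthCurve(cfg, seq(0.2, 0.8, 0.2))
#' estimateDepth(curve, 1.0)
#' }
#' @export
buildRatioDepthCurve <- function(config, depths) {
  stopifnot(is(config, "FluorescenceForwardConfig"))
  mc <- config@mcConfig
  tot <- totalThickness(config@model405)
  if (length(depths) < 3) stop("at least 3 depths are required")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (min(depths) <= 0 || max(depths) > tot + 1e-9)
    stop("depths must lie inside the slab")

  mcAt <- function(offset) transportConfig(
    nPhotons = mc@nPhotons, zBin = mc@zBin,
    rouletteThreshold = mc@rouletteThreshold,
    rouletteSurvival = mc@rouletteSurvival,
    seed = deriveSeed(mc@seed, offset))
  tr405 <- simulateTransport(config@model405, mcAt(1))
  tr660 <- simulateTransport(config@model660, mcAt(2))
  if (length(tr405@zCenters) != length(tr660@zCenters))
    stop("excitation models produced different depth grids")
  z <- tr405@zCenters
  phi405 <- .fluenceProfile(tr405, config@model405)
  phi660 <- .fluenceProfile(tr660, config@model660)
  esc <- escapeFunction(config@emissionModel, z, mcAt(3))

  w405 <- cumsum(phi405 * esc) * mc@zBin   # I(d) for d at each bin edge
  w660 <- cumsum(phi660 * esc) * mc@zBin
  idx <- findInterval(depths - 1e-12, z)   # bins with center < d
  idx[idx < 1] <- 1
  ratios <- config@kappa * w660[idx] / w405[idx]
  if (any(diff(ratios) <= 0))
    stop("model failure: ratio-depth curve is not strictly increasing")
  new("RatioDepthCurve", depths = as.numeric(depths),
      ratios = as.numeric(ratios), kappa = config@kappa)
}

#' @describeIn buildRatioDepthCurve invert a measured red-to-blue ratio into
#'   a photosensitizer penetration depth by monotone piecewise-linear
#'   interpolation on the curve. Ratios outside the curve's range are clamped
#'   to the end depths and flagged in the \code{outOfRange} attribute.
#' @param curve a \linkS4class{RatioDepthCurve}.
#' @param r measured ratio(s).
#' @export
setMethod("estimateDepth", "RatioDepthCurve", function(curve, r) {
  d <- approx(curve@ratios, curve@depths, xout = r, rule = 2)$y
  flag <- r < min(curve@ratios) | r > max(curve@ratios)
  attr(d, "outOfRange") <- flag
  d
})

#' Write / read a ratio-depth curve as JSON
#'
#' @param curve a \linkS4class{RatioDepthCurve}.
#' @param path file path.
#' @export
writeRatioDepthCurve <- function(curve, path) {
  jsonlite::write_json(list(kappa = curve@kappa,
                            depths_mm = curve@depths,
                            ratios = curve@ratios),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeRatioDepthCurve
#' @export
readRatioDepthCurve <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RatioDepthCurve", depths = as.numeric(js$depths_mm),
      ratios = as.numeric(js$ratios), kappa = as.numeric(js$kappa))
}

setMethod("show", "RatioDepthCurve", function(object) {
  cat(sprintf(
    "RatioDepthCurve: %d points, d = %.3g..%.3g mm, R = %.3g..%.3g (kappa = %g)\n",
    length(object@depths), min(object@depths), max(object@depths),
    min(object@ratios), max(object@ratios), object@kappa))
  invisible(NULL)
})
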