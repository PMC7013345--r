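## Tissue model construction, accessors and I/O.

#' Construct a planar layered tissue model
#'
#' @param layers data.frame with columns \code{name}, \code{thickness_mm},
#'   \code{n}, \code{mua}, \code{musp}; one row per layer, top (irradiated)
#'   layer first. Coefficients are in mm^-1.
#' @param nAmbientTop,nAmbientBottom refractive indices of the media bounding
#'   the slab (default 1.0, air: an ear flap is air-backed on both sides).
#' @param wavelength working wavelength in nm, for bookkeeping.
#' @return A \linkS4class{TissueModel}.
#' @examples
#' tissueModel(data.frame(name = "skin", thickness_mm = 1, n = 1.4,
#'                        mua = 0.3, musp = 4.6))
#' @export
tissueModel <- function(layers, nAmbientTop = 1.0, nAmbientBottom = 1.0,
                        wavelength = NA_real_) {
  layers$name <- as.character(layers$name)
  new("TissueModel", layers = as.data.frame(layers),
      nAmbientTop = nAmbientTop, nAmbientBottom = nAmbientBottom,
      wavelength = as.numeric(wavelength))
}

# Optical properties of skin and cartilage used for the rabbit-ear dosimetry,
# per wavelength band. Human values stand in for rabbit tissue.
.rabbitEarProperties <- list(
  `405` = data.frame(
    name = c("skin_top", "cartilage", "skin_bottom"),
    thickness_mm = c(0.4, 0.2, 0.4),
    n = c(1.45, 1.4, 1.45),
    mua = c(1.3, 0.08, 1.3),
    musp = c(5.4, 3.0, 5.4)),
  `660` = data.frame(
    name = c("skin_top", "cartilage", "skin_bottom"),
    thickness_mm = c(0.4, 0.2, 0.4),
    n = c(1.45, 1.4, 1.45),
    mua = c(0.3, 0.01, 0.3),
    musp = c(4.6, 1.0, 4.6))
)

#' Default three-layer rabbit-ear tissue model
#'
#' Skin (0.4 mm) / cartilage (0.2 mm) / skin (0.4 mm), 1 mm total, with
#' tabulated absorption and reduced scattering coefficients at the two
#' treatment wavelengths, bounded by air on both sides.
#'
#' @param wavelength_nm 405 or 660.
#' @return A \linkS4class{TissueModel}.
#' @examples
#' defaultRabbitEarModel(405)
#' @export
defaultRabbitEarModel <- function(wavelength_nm) {
  key <- as.character(wavelength_nm)
  if (length(wavelength_nm) != 1 || !key %in% names(.rabbitEarProperties))
    stop("optical properties are tabulated only for 405 and 660 nm, not ",
         paste(wavelength_nm, collapse = ","))
  tissueModel(.rabbitEarProperties[[key]], wavelength = wavelength_nm)
}

#' Read / write a tissue model as CSV
#'
#' Columns: \code{layer,thickness_mm,n,mua_per_mm,musp_per_mm}, one row per
#' layer, top first.
#' @param path file path.
#' @param wavelength working wavelength recorded on the returned model.
#' @return \code{readTissueCSV} returns a \linkS4class{TissueModel};
#'   \code{writeTissueCSV} returns \code{path} invisibly.
#' @export
readTissueCSV <- function(path, wavelength = NA_real_) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("layer", "thickness_mm", "n", "mua_per_mm", "musp_per_mm")
  if (!all(need %in% names(tb)))
    stop("tissue CSV must have columns ", paste(need, collapse = ","))
  tissueModel(data.frame(name = tb$layer, thickness_mm = tb$thickness_mm,
                         n = tb$n, mua = tb$mua_per_mm, musp = tb$musp_per_mm),
              wavelength = wavelength)
}

#' @rdname readTissueCSV
#' @param model a \linkS4class{TissueModel}.
#' @export
writeTissueCSV <- function(model, path) {
  ly <- model@layers
  write.csv(data.frame(layer = ly$name, thickness_mm = ly$thickness_mm,
                       n = ly$n, mua_per_mm = ly$mua, musp_per_mm = ly$musp),
            path, row.names = FALSE)
  invisible(path)
}

#' @describeIn tissueModel layer table accessor.
#' @param x a \linkS4class{TissueModel}.
#' @export
setMethod("tissueLayers", "TissueModel", function(x) x@layers)

#' @describeIn tissueModel total slab thickness in mm.
#' @export
setMethod("totalThickness", "TissueModel",
          function(x) sum(x@layers$thickness_mm))

# Depths of the layer boundaries, starting at 0 (irradiated surface).
boundaryDepths <- function(model) c(0, cumsum(model@layers$thickness_mm))

setMethod("show", "TissueModel", function(object) {
  cat(sprintf("TissueModel: %d layer(s), %.3g mm total",
              nrow(object@layers), totalThickness(object)),
      if (!is.na(object@wavelength)) sprintf(" @ %g nm", object@wavelength),
      "\n", sep = "")
  print(object@layers, row.names = FALSE)
  invisible(NULL)
})
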