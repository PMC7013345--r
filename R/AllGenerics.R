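#' @export
setGeneric("tissueLayers", function(x) standardGeneric("tissueLayers"))

#' @export
setGeneric("totalThickness", function(x) standardGeneric("totalThickness"))

#' @export
setGeneric("doses", function(x) standardGeneric("doses"))

#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setGeneric("excitationNm", function(x) standardGeneric("excitationNm"))

#' @export
setGeneric("absorbedFraction",
           function(result, z0, z1) standardGeneric("absorbedFraction"))

#' @export
setGeneric("fitBleachRate", function(series) standardGeneric("fitBleachRate"))

#' @export
setGeneric("estimateDepth",
           function(curve, r) standardGeneric("estimateDepth"))
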