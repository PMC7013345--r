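## Fluorescence photobleaching quantification.

#' Construct a fluorescence frame
#'
#' @param pixels non-negative intensity matrix.
#' @param excitationNm excitation wavelength, 405 or 660.
#' @param cumulativeDose cumulative delivered dose in J/cm^2.
#' @return A \linkS4class{FluorescenceFrame}.
#' @export
fluorescenceFrame <- function(pixels, excitationNm, cumulativeDose) {
  new("FluorescenceFrame", pixels = pixels,
      excitationNm = as.numeric(excitationNm),
      cumulativeDose = as.numeric(cumulativeDose))
}

#' Construct a dose-indexed intensity series
#'
#' @param doses strictly increasing cumulative doses (J/cm^2), starting at 0.
#' @param intensities positive ROI-mean intensities (a.u.).
#' @param excitationNm excitation wavelength, 405 or 660.
#' @return A \linkS4class{DoseSeries}.
#' @export
doseSeries <- function(doses, intensities, excitationNm) {
  new("DoseSeries", doses = as.numeric(doses),
      intensities = as.numeric(intensities),
      excitationNm = as.numeric(excitationNm))
}

#' @describeIn doseSeries dose grid accessor.
#' @param x a \linkS4class{DoseSeries}.
#' @export
setMethod("doses", "DoseSeries", function(x) x@doses)

#' @describeIn doseSeries intensity accessor.
#' @export
setMethod("intensities", "DoseSeries", function(x) x@intensities)

#' @describeIn doseSeries excitation wavelength accessor.
#' @export
setMethod("excitationNm", "DoseSeries", function(x) x@excitationNm)

setMethod("show", "DoseSeries", function(object) {
  cat(sprintf("DoseSeries (%g nm excitation): %d points, D = %g..%g J/cm2\n",
              object@excitationNm, length(object@doses),
              min(object@doses), max(object@doses)))
  invisible(NULL)
})

.framePixels <- function(frame) {
  if (is(frame, "FluorescenceFrame")) frame@pixels else frame
}

#' Segment the fluorescing area of a frame
#'
#' Pixels at or above \code{thresholdFraction} times the 99th-percentile
#' intensity are kept (the percentile makes the rule robust to hot pixels),
#' and only the largest connected component is retained. This realizes the
#' "entire fluorescing area" over which intensities are averaged.
#'
#' @param frame a \linkS4class{FluorescenceFrame} or a numeric matrix.
#' @param thresholdFraction fraction of the 99th-percentile intensity used as
#'   the cut, in (0, 1); default 0.2.
#' @return Logical matrix (the ROI mask), same shape as the frame.
#' @export
segmentFluorescingArea <- function(frame, thresholdFraction = 0.2) {
  px <- .framePixels(frame)
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  if (max(px) <= 0) stop("no fluorescence detected: frame is empty")
  thr <- thresholdFraction * quantile(px, 0.99, names = FALSE)
  mask <- px >= thr & px > 0
  if (!any(mask)) stop("no fluorescence detected: empty mask")
  lab <- EBImage::bwlabel(mask + 0)  # numeric 0/1 matrix for labelling
  sizes <- tabulate(lab[lab > 0])
  mask[] <- lab == which.max(sizes)
  mask
}

#' Mean intensity over a region of interest
#'
#' @param frame a \linkS4class{FluorescenceFrame} or a numeric matrix.
#' @param roi logical mask of the same shape, with at least one TRUE pixel.
#' @return Arithmetic mean of the masked pixel intensities.
#' @export
meanIntensity <- function(frame, roi) {
  px <- .framePixels(frame)
  if (!identical(dim(px), dim(roi)))
    stop("ROI mask shape does not match the frame")
  if (!any(roi)) stop("empty ROI")
  mean(px[roi])
}

#' Photobleaching efficiency
#'
#' PE = (If_before - If_after) / If_before * 100, the percent drop in
#' ROI-mean fluorescence over a procedure. Scale-invariant; at most 100.
#'
#' @param ifBefore ROI-mean intensity before the procedure (> 0).
#' @param ifAfter ROI-mean intensity after the procedure (>= 0).
#' @return Efficiency in percent.
#' @examples
#' photobleachingEfficiency(100, 58)  # 42
#' @export
photobleachingEfficiency <- function(ifBefore, ifAfter) {
  if (any(ifBefore <= 0)) stop("ifBefore must be positive")
  if (any(ifAfter < 0)) stop("ifAfter must be non-negative")
  (ifBefore - ifAfter) / ifBefore * 100
}

#' Model-implied photobleaching efficiency at a given dose
#'
#' Under the single-exponential model If(D) = If1 exp(-alpha D), the
#' efficiency after delivering dose D is PE(D) = 100 (1 - exp(-alpha D)).
#'
#' @param alpha photobleaching rate, (J/cm^2)^-1.
#' @param dose delivered dose, J/cm^2.
#' @return Efficiency in percent.
#' @export
modelBleachEfficiency <- function(alpha, dose) {
  if (any(alpha < 0) || any(dose < 0)) stop("alpha and dose must be >= 0")
  100 * (1 - exp(-alpha * dose))
}

#' Fit the single-exponential photobleaching model
#'
#' Fits If(D) = If1 exp(-alpha D) by nonlinear least squares on the linear
#' intensity scale (so multiplicative noise does not bias the high-dose
#' points), initialized from the log-linear regression of ln If on D. The
#' rate standard error comes from the fit covariance.
#'
#' @param series a \linkS4class{DoseSeries} with at least 3 points.
#' @return A \linkS4class{BleachFit}.
#' @examples
#' d <- seq(0, 50, 10)
#' fitBleachRate(doseSeries(d, 100 * exp(-0.011 * d), 405))
#' @export
setMethod("fitBleachRate", "DoseSeries", function(series) {
  d <- series@doses; I <- series@intensities
  if (length(d) < 3) stop("at least 3 dose points are required for the fit")
  ini <- lm(log(I) ~ d)
  start <- list(If1 = exp(coef(ini)[[1]]), alpha = -coef(ini)[[2]])
  fit <- minpack.lm::nlsLM(I ~ If1 * exp(-alpha * d), start = start,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-15, ptol = 1e-15, maxiter = 500))
  cf <- summary(fit)$coefficients
  res <- I - predict(fit)
  sst <- sum((I - mean(I))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  new("BleachFit", if1 = cf["If1", "Estimate"],
      alpha = cf["alpha", "Estimate"], alphaSe = cf["alpha", "Std. Error"],
      rSquared = min(max(r2, 0), 1), nPoints = length(d))
})

setMethod("show", "BleachFit", function(object) {
  cat(sprintf(
    "BleachFit: If1 = %.4g, alpha = %.4g +/- %.2g (J/cm2)^-1, R2 = %.4f (n = %d)\n",
    object@if1, object@alpha, object@alphaSe, object@rSquared,
    object@nPoints))
  invisible(NULL)
})

#' Red-to-blue fluorescence signal ratio
#'
#' R_lambda = If660 / If405, the ratio of ROI-mean fluorescence excited at
#' 660 nm to that excited at 405 nm; a proxy for photosensitizer penetration
#' depth since red excitation probes deeper tissue.
#'
#' @param if660 intensity under 660 nm excitation.
#' @param if405 intensity under 405 nm excitation (> 0).
#' @return The ratio.
#' @export
redBlueRatio <- function(if660, if405) {
  if (any(if405 <= 0)) stop("if405 must be positive")
  if660 / if405
}

#' Red-to-blue ratio series over a PDT session
#'
#' Aligns the two excitation series on a common dose grid (linear
#' interpolation onto the coarser grid when the grids differ) and computes
#' the ratio at each dose. The overall trend ("rising", "falling" or "flat")
#' is the sign of the least-squares slope of the ratio against dose: rising
#' when the 405-excited signal bleaches faster (blue-light PDT), falling when
#' the 660-excited one does (red-light PDT).
#'
#' @param series660,series405 \linkS4class{DoseSeries} at the two excitations.
#' @return data.frame with columns \code{dose} and \code{ratio}; attribute
#'   \code{trend}.
#' @export
ratioSeries <- function(series660, series405) {
  stopifnot(is(series660, "DoseSeries"), is(series405, "DoseSeries"))
  d660 <- series660@doses; d405 <- series405@doses
  if (identical(d660, d405)) {
    d <- d660
    r <- redBlueRatio(series660@intensities, series405@intensities)
  } else {
    lo <- max(min(d660), min(d405)); hi <- min(max(d660), max(d405))
    if (lo >= hi) stop("dose ranges of the two series do not overlap")
    base <- if (length(d660) <= length(d405)) d660 else d405
    d <- base[base >= lo & base <= hi]
    i660 <- approx(d660, series660@intensities, xout = d)$y
    i405 <- approx(d405, series405@intensities, xout = d)$y
    r <- redBlueRatio(i660, i405)
  }
  out <- data.frame(dose = d, ratio = r)
  slope <- coef(lm(r ~ d))[[2]]
  attr(out, "trend") <-
    if (abs(slope) * (max(d) - min(d)) < 1e-9 * mean(r)) "flat"
    else if (slope > 0) "rising" else "falling"
  out
}

#' Delivered light dose from an exposure
#'
#' dose (J/cm^2) = fluence rate (mW/cm^2) x duration (s) / 1000. At the
#' study's surface fluence rate of 200 mW/cm^2, 250 s delivers 50 J/cm^2.
#'
#' @param fluenceRate_mWcm2 surface fluence rate in mW/cm^2 (>= 0).
#' @param duration_s irradiation time in seconds (>= 0).
#' @return Dose in J/cm^2.
#' @export
doseFromExposure <- function(fluenceRate_mWcm2, duration_s) {
  if (any(fluenceRate_mWcm2 < 0) || any(duration_s < 0))
    stop("fluence rate and duration must be non-negative")
  fluenceRate_mWcm2 * duration_s / 1000
}

#' Read / write a dose-intensity series as CSV
#'
#' Columns: \code{dose_Jcm2,excitation_nm,intensity}. A file may hold both
#' excitations; \code{readSeriesCSV} returns a named list of
#' \linkS4class{DoseSeries}, one per excitation present.
#' @param path file path.
#' @export
readSeriesCSV <- function(path) {
  tb <- read.csv(path)
  need <- c("dose_Jcm2", "excitation_nm", "intensity")
  if (!all(need %in% names(tb)))
    stop("series CSV must have columns ", paste(need, collapse = ","))
  out <- lapply(split(tb, tb$excitation_nm), function(g) {
    g <- g[order(g$dose_Jcm2), ]
    doseSeries(g$dose_Jcm2, g$intensity, g$excitation_nm[1])
  })
  out
}

#' @rdname readSeriesCSV
#' @param seriesList list of \linkS4class{DoseSeries}.
#' @export
writeSeriesCSV <- function(seriesList, path) {
  if (is(seriesList, "DoseSeries")) seriesList <- list(seriesList)
  tb <- do.call(rbind, lapply(seriesList, function(s)
    data.frame(dose_Jcm2 = s@doses, excitation_nm = s@excitationNm,
               intensity = s@intensities)))
  write.csv(tb, path, row.names = FALSE)
  invisible(path)
}
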