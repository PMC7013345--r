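## Synthetic fluorescence sessions and ordinal outcome tables.
##
## The generator encodes the study conditions the analysis assumes:
## single-exponential photobleaching at the tabulated rates, multiplicative
## Gaussian measurement noise, a bright fluorescing disc on a dark
## background, and regime-dependent red-to-blue ratio trends (rising under
## blue-light PDT, falling under red-light PDT).

#' Specify a synthetic dual-wavelength photobleaching session
#'
#' Defaults mirror a 50 J/cm^2 procedure sampled every 10 J/cm^2 with n = 3
#' replicates and 5% multiplicative measurement noise. The preset rates are
#' the tabulated photobleaching rates: blue-light PDT bleaches the 405-excited
#' signal faster (0.011 vs 0.009 (J/cm^2)^-1), red-light PDT the 660-excited
#' one (0.017 vs 0.014).
#'
#' @param preset "pdt_b" (blue-light procedure) or "pdt_r" (red-light);
#'   overrides the two rates.
#' @param if1405,if1660 initial ROI-mean intensities (a.u.).
#' @param alpha405,alpha660 bleaching rates ((J/cm^2)^-1) when no preset is
#'   given.
#' @param doses cumulative dose grid (J/cm^2), starting at 0.
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param nReplicates number of replicate series/sessions.
#' @param seed integer seed.
#' @param imageDim image size in pixels (rows, columns).
#' @param roiCenter,roiRadius fluorescing disc geometry (pixels).
#' @param background dark-background intensity (a.u.).
#' @return A \linkS4class{SessionSpec}.
#' @export
sessionSpec <- function(preset = NULL, if1405 = 100, if1660 = 100,
                        alpha405 = 0.011, alpha660 = 0.009,
                        doses = seq(0, 50, by = 10), noiseCv = 0.05,
                        nReplicates = 3, seed, imageDim = c(64, 64),
                        roiCenter = NULL, roiRadius = 14, background = 1) {
  if (missing(seed)) stop("a seed is required")
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("pdt_b", "pdt_r"))
    if (preset == "pdt_b") { alpha405 <- 0.011; alpha660 <- 0.009 }
    else                   { alpha405 <- 0.014; alpha660 <- 0.017 }
  }
  if (is.null(roiCenter)) roiCenter <- (imageDim + 1) / 2
  new("SessionSpec", if1405 = if1405, if1660 = if1660,
      alpha405 = alpha405, alpha660 = alpha660, doses = as.numeric(doses),
      noiseCv = noiseCv, nReplicates = as.integer(nReplicates),
      seed = as.integer(seed), imageDim = as.integer(imageDim),
      roiCenter = as.numeric(roiCenter), roiRadius = as.numeric(roiRadius),
      background = background)
}

.specRate <- function(spec, excitationNm) {
  switch(as.character(excitationNm),
         `405` = c(spec@if1405, spec@alpha405),
         `660` = c(spec@if1660, spec@alpha660),
         stop("excitationNm must be 405 or 660"))
}

#' Generate replicate dose-intensity decay series
#'
#' Intensities follow If1 exp(-alpha D) (1 + eps) with eps ~ N(0, noiseCv),
#' drawn independently per dose point and replicate. Reproducible for a
#' fixed spec seed; the 405 and 660 nm streams are decoupled.
#'
#' @param spec a \linkS4class{SessionSpec}.
#' @param excitationNm 405 or 660.
#' @return List of \code{nReplicates} \linkS4class{DoseSeries}.
#' @examples
#' s <- generateBleachSeries(sessionSpec(preset = "pdt_b", seed = 1), 405)
#' fitBleachRate(s[[1]])
#' @export
generateBleachSeries <- function(spec, excitationNm) {
  p <- .specRate(spec, excitationNm)
  if1 <- p[1]; alpha <- p[2]
  mu <- if1 * exp(-alpha * spec@doses)
  withLocalSeed(deriveSeed(spec@seed, if (excitationNm == 405) 0 else 1), {
    lapply(seq_len(spec@nReplicates), function(i) {
      eps <- rnorm(length(mu), 0, spec@noiseCv)
      doseSeries(spec@doses, pmax(mu * (1 + eps), .Machine$double.eps),
                 excitationNm)
    })
  })
}

.discMask <- function(dim, center, radius) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

#' Generate a dual-wavelength fluorescence image session
#'
#' One frame per dose and excitation wavelength: a bright disc whose interior
#' mean follows the decay model (with frame-level multiplicative noise) over
#' a dark background, plus per-pixel multiplicative noise at the same CV.
#' ROI means recovered through \code{\link{segmentFluorescingArea}} and
#' \code{\link{meanIntensity}} round-trip to the generating curve within
#' noise (exactly, for \code{noiseCv = 0}).
#'
#' @param spec a \linkS4class{SessionSpec} (replicate 1 of its streams).
#' @return List with \code{frames} (list of \linkS4class{FluorescenceFrame},
#'   dose-major, 405 before 660 at each dose) and \code{manifest}
#'   (data.frame: \code{index, excitation_nm, cumulative_dose_Jcm2}).
#' @export
generateSessionImages <- function(spec) {
  dim <- spec@imageDim
  disc <- .discMask(dim, spec@roiCenter, spec@roiRadius)
  frames <- list(); man <- NULL
  k <- 0L
  withLocalSeed(deriveSeed(spec@seed, 2), {
    for (d in spec@doses) {
      for (ex in c(405, 660)) {
        p <- .specRate(spec, ex)
        mu <- p[1] * exp(-p[2] * d)
        ampl <- mu * (1 + rnorm(1, 0, spec@noiseCv))
        px <- matrix(spec@background, dim[1], dim[2])
        px[disc] <- ampl
        if (spec@noiseCv > 0)
          px <- px * (1 + matrix(rnorm(prod(dim), 0, spec@noiseCv),
                                 dim[1], dim[2]))
        px[px < 0] <- 0
        k <- k + 1L
        frames[[k]] <- fluorescenceFrame(px, ex, d)
        man <- rbind(man, data.frame(index = k, excitation_nm = ex,
                                     cumulative_dose_Jcm2 = d))
      }
    }
  })
  list(frames = frames, manifest = man)
}

#' Write / read an image session (16-bit TIFF + JSON sidecars + manifest)
#'
#' Frames are written as 16-bit grayscale TIFFs with a per-session intensity
#' scale recorded in each JSON sidecar
#' (\code{{excitation_nm, cumulative_dose_Jcm2, scale}}); the manifest CSV
#' lists frames in dose order.
#'
#' @param session output of \code{\link{generateSessionImages}}.
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
writeSession <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scale <- max(vapply(session$frames, function(f) max(f@pixels), numeric(1)))
  if (scale <= 0) scale <- 1
  man <- session$manifest
  man$file <- sprintf("frame_%03d_%dnm.tif", man$index, man$excitation_nm)
  for (i in seq_along(session$frames)) {
    f <- session$frames[[i]]
    tiff::writeTIFF(f@pixels / scale, file.path(dir, man$file[i]),
                    bits.per.sample = 16)
    jsonlite::write_json(list(excitation_nm = f@excitationNm,
                              cumulative_dose_Jcm2 = f@cumulativeDose,
                              scale = scale),
                         file.path(dir, sub("\\.tif$", ".json", man$file[i])),
                         auto_unbox = TRUE, digits = I(17))
  }
  manifestPath <- file.path(dir, "manifest.csv")
  write.csv(man, manifestPath, row.names = FALSE)
  invisible(manifestPath)
}

#' @rdname writeSession
#' @param manifestPath path to a session manifest CSV.
#' @export
readSession <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop("manifest not found: ", manifestPath)
  dir <- dirname(manifestPath)
  man <- read.csv(manifestPath)
  frames <- lapply(seq_len(nrow(man)), function(i) {
    side <- jsonlite::read_json(
      file.path(dir, sub("\\.tif$", ".json", man$file[i])),
      simplifyVector = TRUE)
    px <- tiff::readTIFF(file.path(dir, man$file[i])) * side$scale
    fluorescenceFrame(px, side$excitation_nm, side$cumulative_dose_Jcm2)
  })
  list(frames = frames, manifest = man)
}

## ---- Ordinal outcome tables -------------------------------------------

#' The twenty exposure regime codes
#'
#' Red (660 nm), blue (405 nm) and combined-wavelength exposures at total
#' doses of 50-150 J/cm^2, each with ("PDT_") and without ("IRR_")
#' photosensitizer administration.
#' @return Character vector of the 20 regime codes.
#' @export
regimeCodes <- function() {
  c(paste0("PDT_r", c(50, 75, 100, 150)), paste0("PDT_b", c(50, 75, 100, 150)),
    paste0("IRR_r", c(50, 75, 100, 150)), paste0("IRR_b", c(50, 75, 100, 150)),
    "PDT_rb100", "PDT_rb150", "IRR_rb100", "IRR_rb150")
}

#' Symbols of the four-level edema grading
#' @return Character vector mapping grades 0:3 to (-, +, ++, +++).
#' @export
gradeSymbols <- function() c("-", "+", "++", "+++")

# Grade menus per colour and dose; a draw is later clamped by the ordering
# rules. Blue exposures react more strongly than red; reactions peak at day 4
# and relax by day 7, except the severe blue regimes.
.gradeMenus <- function(colour, dose, timepoint) {
  key <- paste(colour, timepoint)
  if (colour == "r") {
    if (dose <= 75) switch(timepoint, post = 0:1, day4 = 0:1, day7 = 0:1)
    else switch(timepoint, post = 0:1, day4 = 1, day7 = 0:1)
  } else if (colour == "b") {
    if (dose <= 75) switch(timepoint, post = 1, day4 = 1:2, day7 = 0:1)
    else switch(timepoint, post = 1:2, day4 = 2:3, day7 = 2:3)
  } else {  # combined red + blue
    if (dose <= 100) switch(timepoint, post = 1, day4 = 1:2, day7 = 0:1)
    else switch(timepoint, post = 1:2, day4 = 2:3, day7 = 1:2)
  }
}

# Regimes with severe outcomes (focal necrosis / stasis) where the reaction
# does not relax by day 7.
.severeRegimes <- c("PDT_b100", "PDT_b150")

#' Generate a plausibility-shaped ordinal outcome table
#'
#' Draws an edema grade (0-3) for each of the 20 exposure regimes at the
#' three observation timepoints (immediately after, day 4, day 7) from small
#' ordered menus, then enforces the qualitative ordering of the observed
#' outcomes: a red-light regime never exceeds the grade of the equal-dose
#' blue-light regime; grades relax from day 4 to day 7 except for the
#' severe-outcome blue regimes (PDT_b100, PDT_b150); and the mildest regime
#' (PDT_r50) never exceeds weak edema.
#'
#' @param seed integer seed.
#' @return data.frame with columns \code{regime}, \code{timepoint}
#'   (post/day4/day7) and \code{grade} (integer 0-3).
#' @export
generateOutcomeTable <- function(seed) {
  tps <- c("post", "day4", "day7")
  regs <- regimeCodes()
  info <- do.call(rbind, lapply(regs, function(rg) {
    m <- regmatches(rg, regexec("^(PDT|IRR)_(rb|r|b)(\\d+)$", rg))[[1]]
    data.frame(regime = rg, family = m[2], colour = m[3],
               dose = as.numeric(m[4]))
  }))
  g <- withLocalSeed(deriveSeed(seed, 3), {
    out <- expand.grid(regime = regs, timepoint = tps,
                       stringsAsFactors = FALSE)
    out <- merge(out, info, by = "regime", sort = FALSE)
    out$grade <- vapply(seq_len(nrow(out)), function(i) {
      menu <- .gradeMenus(out$colour[i], out$dose[i], out$timepoint[i])
      if (length(menu) == 1) menu else sample(menu, 1)
    }, numeric(1))
    out
  })
  # Relaxation by day 7, except the severe regimes.
  for (rg in regs) {
    if (rg %in% .severeRegimes) next
    i4 <- g$regime == rg & g$timepoint == "day4"
    i7 <- g$regime == rg & g$timepoint == "day7"
    g$grade[i7] <- min(g$grade[i7], g$grade[i4])
  }
  # Red never exceeds the equal-dose blue regime of the same family.
  for (fam in c("PDT", "IRR")) for (dose in c(50, 75, 100, 150))
    for (tp in tps) {
      ir <- g$regime == paste0(fam, "_r", dose) & g$timepoint == tp
      ib <- g$regime == paste0(fam, "_b", dose) & g$timepoint == tp
      g$grade[ir] <- min(g$grade[ir], g$grade[ib])
    }
  # The mildest regime shows at most weak edema.
  i <- g$regime == "PDT_r50"
  g$grade[i] <- pmin(g$grade[i], 1)
  g$timepoint <- factor(g$timepoint, levels = tps)
  g[order(match(g$regime, regs), g$timepoint),
    c("regime", "timepoint", "grade")]
}
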