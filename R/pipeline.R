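## End-to-end monitoring pipeline and outcome summarization.

#' Build a run configuration
#'
#' Either \code{manifest} points at an existing image-session manifest CSV,
#' or a synthetic session is generated from \code{preset}. Tissue CSVs
#' override the built-in rabbit-ear optics when given.
#'
#' @param regime exposure regime label (one of \code{\link{regimeCodes}}).
#' @param seed master integer seed; all stage seeds derive from it.
#' @param preset synthetic session preset, "pdt_b" or "pdt_r".
#' @param manifest optional path to a session manifest CSV.
#' @param tissue405,tissue660 optional tissue CSV paths (top layer first).
#' @param roiThreshold ROI segmentation threshold fraction.
#' @param mcPhotons photon packets per Monte Carlo stage.
#' @param kappa instrument ratio calibration constant.
#' @param zBin Monte Carlo depth bin width (mm).
#' @param depthGrid candidate PS depths for the ratio-depth curve (mm).
#' @param doses cumulative dose grid for synthetic sessions (J/cm^2).
#' @param noiseCv synthetic measurement noise CV.
#' @param outputDir optional directory for report artifacts.
#' @return A named list of validated settings (class \code{"runConfig"}).
#' @export
runConfig <- function(regime = "PDT_b50", seed, preset = NULL,
                      manifest = NULL, tissue405 = NULL, tissue660 = NULL,
                      roiThreshold = 0.2, mcPhotons = 5e4, kappa = 1,
                      zBin = 0.01, depthGrid = seq(0.1, 0.9, by = 0.1),
                      doses = seq(0, 50, by = 10), noiseCv = 0.05,
                      outputDir = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (!regime %in% regimeCodes())
    stop("unknown regime label: ", regime)
  for (p in c(manifest, tissue405, tissue660))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  if (is.null(manifest) && is.null(preset))
    preset <- if (grepl("_b", regime, fixed = TRUE)) "pdt_b" else "pdt_r"
  cfg <- list(regime = regime, seed = as.integer(seed), preset = preset,
              manifest = manifest, tissue405 = tissue405,
              tissue660 = tissue660, roiThreshold = roiThreshold,
              mcPhotons = mcPhotons, kappa = kappa, zBin = zBin,
              depthGrid = depthGrid, doses = doses, noiseCv = noiseCv,
              outputDir = outputDir)
  class(cfg) <- "runConfig"
  cfg
}

#' @rdname runConfig
#' @param path YAML file whose keys are \code{runConfig} arguments.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(runConfig, yaml::read_yaml(path))
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full PDT monitoring pipeline
#'
#' Executes segmentation, ROI-mean intensity extraction, photobleaching
#' efficiency, exponential rate fits at both excitation wavelengths, the
#' red-to-blue ratio series and its trend, inversion of the pre-procedure
#' ratio into a photosensitizer penetration depth via the Monte Carlo
#' forward model, and depth-resolved light dosimetry at both wavelengths.
#' Deterministic for a fixed config seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @param verbose log each stage.
#' @return A \linkS4class{RunReport}.
#' @examples
#' \donttest{
#' rep <- runMonitoringPipeline(runConfig(regime = "PDT_b50", seed = 1,
#'                                        mcPhotons = 1e4))
#' rep
#' }
#' @export
runMonitoringPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  session <- .stage("session", verbose, {
    if (!is.null(config$manifest)) readSession(config$manifest)
    else generateSessionImages(sessionSpec(preset = config$preset,
                                           doses = config$doses,
                                           noiseCv = config$noiseCv,
                                           seed = config$seed))
  })
  series <- .stage("intensities", verbose, {
    man <- session$manifest
    out <- list()
    for (ex in c(405, 660)) {
      sel <- which(man$excitation_nm == ex)
      sel <- sel[order(man$cumulative_dose_Jcm2[sel])]
      means <- vapply(sel, function(i) {
        f <- session$frames[[i]]
        meanIntensity(f, segmentFluorescingArea(f, config$roiThreshold))
      }, numeric(1))
      out[[as.character(ex)]] <-
        doseSeries(man$cumulative_dose_Jcm2[sel], means, ex)
    }
    out
  })
  pe <- .stage("photobleaching efficiency", verbose,
    vapply(series, function(s)
      photobleachingEfficiency(s@intensities[1],
                               s@intensities[length(s@intensities)]),
      numeric(1)))
  fits <- .stage("rate fits", verbose, lapply(series, fitBleachRate))
  rs <- .stage("ratio series", verbose,
               ratioSeries(series[["660"]], series[["405"]]))
  models <- .stage("tissue models", verbose, list(
    `405` = if (is.null(config$tissue405)) defaultRabbitEarModel(405)
            else readTissueCSV(config$tissue405, 405),
    `660` = if (is.null(config$tissue660)) defaultRabbitEarModel(660)
            else readTissueCSV(config$tissue660, 660)))
  depth <- .stage("depth inference", verbose, {
    fwd <- fluorescenceForwardConfig(
      model405 = models[["405"]], model660 = models[["660"]],
      kappa = config$kappa,
      mcConfig = transportConfig(nPhotons = config$mcPhotons,
                                 zBin = config$zBin,
                                 seed = deriveSeed(config$seed, 11)))
    curve <- buildRatioDepthCurve(fwd, config$depthGrid)
    estimateDepth(curve, rs$ratio[1])
  })
  dosim <- .stage("dosimetry", verbose, {
    out <- list()
    for (ex in c("405", "660")) {
      tr <- simulateTransport(models[[ex]],
        transportConfig(nPhotons = config$mcPhotons, zBin = config$zBin,
                        seed = deriveSeed(config$seed,
                                          12 + as.integer(ex == "660"))))
      out[[ex]] <- list(
        layer_fractions = as.list(layerAbsorbedFractions(tr, models[[ex]])),
        r_specular = tr@rSpecular, r_diffuse = tr@rDiffuse,
        transmitted = tr@transmitted, absorbed_total = tr@absorbedTotal)
    }
    out
  })
  new("RunReport", fits = fits, pe = pe, ratioSeries = rs,
      ratioTrend = attr(rs, "trend"),
      depthEstimate = as.numeric(depth),
      depthOutOfRange = attr(depth, "outOfRange"),
      doseSummary = dosim,
      provenance = list(config = unclass(config),
                        configHash = .configHash(config),
                        package = as.character(packageVersion("pdtmon"))))
}

setMethod("show", "RunReport", function(object) {
  cat("RunReport (", object@provenance$config$regime, ")\n", sep = "")
  for (ex in names(object@fits)) {
    f <- object@fits[[ex]]
    cat(sprintf("  %s nm: alpha = %.4g (J/cm2)^-1, PE = %.1f%%\n",
                ex, f@alpha, object@pe[[ex]]))
  }
  cat(sprintf("  R-lambda trend: %s; PS depth ~ %.2f mm%s\n",
              object@ratioTrend, object@depthEstimate,
              if (isTRUE(object@depthOutOfRange)) " (out of range)" else ""))
  invisible(NULL)
})

#' Serialize / deserialize a run report as JSON
#'
#' JSON is the source of truth for a run: every numeric field of the report
#' is written at full precision together with provenance, so the round trip
#' is lossless.
#'
#' @param report a \linkS4class{RunReport}.
#' @param path file path.
#' @export
writeRunReport <- function(report, path) {
  fits <- lapply(report@fits, function(f)
    list(If1 = f@if1, alpha = f@alpha, alpha_se = f@alphaSe,
         r_squared = f@rSquared, n_points = f@nPoints))
  jsonlite::write_json(list(
    regime = report@provenance$config$regime,
    bleach_fits = fits, pe_percent = as.list(report@pe),
    ratio_series = report@ratioSeries, ratio_trend = report@ratioTrend,
    depth_mm = report@depthEstimate,
    depth_out_of_range = report@depthOutOfRange,
    dose_summary = report@doseSummary,
    provenance = report@provenance[c("configHash", "package")]),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeRunReport
#' @export
readRunReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Summarize ordinal outcomes as a regime-by-timepoint grade table
#'
#' Pivots edema grade records to the modal grade per regime and timepoint,
#' rendered with the (-, +, ++, +++) encoding. Ties are resolved to the
#' higher grade (conservative for safety reporting).
#'
#' @param grades data.frame with columns \code{regime}, \code{timepoint},
#'   \code{grade} (as from \code{\link{generateOutcomeTable}}).
#' @return data.frame of grade symbols, one row per regime present, one
#'   column per timepoint present; numeric grades in attribute
#'   \code{"grades"}.
#' @examples
#' summarizeOutcomes(generateOutcomeTable(seed = 1))
#' @export
summarizeOutcomes <- function(grades) {
  if (nrow(grades) < 1) stop("no grade records")
  bad <- setdiff(unique(as.character(grades$regime)), regimeCodes())
  if (length(bad)) stop("unknown regime label(s): ", paste(bad, collapse = ","))
  tps <- intersect(c("post", "day4", "day7"),
                   unique(as.character(grades$timepoint)))
  regs <- intersect(regimeCodes(), unique(as.character(grades$regime)))
  num <- matrix(NA_integer_, length(regs), length(tps),
                dimnames = list(regs, tps))
  for (rg in regs) for (tp in tps) {
    g <- grades$grade[grades$regime == rg & grades$timepoint == tp]
    if (!length(g)) next
    tab <- table(g)
    modes <- as.integer(names(tab)[tab == max(tab)])
    num[rg, tp] <- max(modes)  # conservative tie-break
  }
  sym <- as.data.frame(matrix(gradeSymbols()[num + 1], nrow(num),
                              dimnames = dimnames(num)))
  attr(sym, "grades") <- num
  sym
}
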