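## Batch runner: execute the default check suite, assign quality tiers,
## write a summary table, log and rendered outputs.

#' Default batch configuration
#'
#' Returns the configuration list driving [runAllChecks()]: which optional
#' checks are enabled and the metric -> tier thresholds. Shipped defaults
#' live in `inst/extdata/simqc-config.json`; any value can be overridden
#' via the `config` argument or a user JSON file. Tier thresholds are
#' advisory defaults, not published constants — tune them to your
#' instrument and sample types.
#'
#' Threshold entries have the form
#' `list(caution = x, concern = y, direction = "high"|"low")`: with
#' `"high"`, values above `caution`/`concern` earn that tier; with
#' `"low"`, values below do.
#'
#' @param config named list or path to a JSON file of overrides
#' @return the merged configuration list
#' @export
simqcConfig <- function(config = NULL) {
  path <- system.file("extdata", "simqc-config.json", package = "simqc")
  base <- if (nzchar(path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
    else list()
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  if (!is.null(config)) base <- modifyList(base, config)
  base
}

tierFor <- function(value, rule) {
  if (is.null(rule) || !is.finite(value)) return("na")
  hi <- identical(rule$direction, "high")
  if (hi) {
    if (value >= rule$concern) "concern"
    else if (value >= rule$caution) "caution" else "ok"
  } else {
    if (value <= rule$concern) "concern"
    else if (value <= rule$caution) "caution" else "ok"
  }
}

makeReport <- function(checkId, title, metrics, units, guidance, config,
                       artifacts = character()) {
  rules <- config$thresholds
  tiers <- vapply(names(metrics), function(nm)
    tierFor(metrics[[nm]], rules[[nm]]), "")
  new("CheckReport", checkId = checkId, title = title, metrics = metrics,
      units = units[names(metrics)], tiers = tiers, guidance = guidance,
      artifacts = artifacts)
}

setMethod("show", "CheckReport", function(object) {
  cat(sprintf("[%s] %s\n", object@checkId, object@title))
  for (nm in names(object@metrics))
    cat(sprintf("  %-22s %10.4g %-4s [%s]\n", nm,
                object@metrics[[nm]], object@units[[nm]],
                object@tiers[[nm]]))
  if (nzchar(object@guidance)) cat(" ", object@guidance, "\n")
})

renderPng <- function(outDir, name, fun, width = 640, height = 480) {
  if (is.null(outDir)) return(character())
  path <- file.path(outDir, name)
  png(path, width = width, height = height)
  ok <- tryCatch({ fun(); TRUE }, error = function(e) FALSE)
  dev.off()
  if (!ok && file.exists(path)) { unlink(path); return(character()) }
  path
}

writeRgbPng <- function(outDir, name, rgbSlice) {
  if (is.null(outDir)) return(character())
  path <- file.path(outDir, name)
  png::writePNG(clamp(rgbSlice, 0, 1), path)
  path
}

#' Run the SIM quality-control suite
#'
#' Executes the default check set on whatever is provided: channel
#' intensity profile, motion & illumination variation and modulation
#' contrast-to-noise on raw data; intensity histogram, lateral Fourier
#' spectrum and radial profile on reconstructed data; the modulation
#' contrast map when both are given. The raw Fourier projection and the
#' spherical-aberration-mismatch check have specific sample requirements
#' and are off by default (`enable_fpj` / `enable_sam` in the config).
#' Quality tiers come from the configurable thresholds only; the run
#' succeeds regardless of tier — QC is advisory.
#'
#' @param raw a [RawSIMStack], or NULL
#' @param recon a [ReconStack], or NULL
#' @param config overrides for [simqcConfig()]
#' @param outDir if non-NULL, write `summary.csv`, `simqc.log`, metric JSON
#'   and rendered PNGs there
#' @return invisibly, a list with `reports` (list of [CheckReport]) and
#'   `summary` (data.frame: one row per executed check)
#' @export
runAllChecks <- function(raw = NULL, recon = NULL, config = NULL,
                         outDir = NULL) {
  if (is.null(raw) && is.null(recon))
    stop("provide at least one of raw / recon")
  cfg <- simqcConfig(config)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  reports <- list()
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, paste0(...))
  mcnRes <- NULL
  if (!is.null(raw)) {
    cip <- channelIntensityProfile(raw)
    reports <- c(reports, makeReport(
      "cip", "Channel intensity profile",
      list(tiv = max(cip@tiv), decay = max(cip@meanDecay),
           angle_diff = max(cip@maxAngleDiff), flicker = max(cip@flicker)),
      c(tiv = "%", decay = "%", angle_diff = "%", flicker = "%"),
      "Large TIV/angle differences destabilize reconstruction; check focus, bleaching and illumination balance.",
      cfg, renderPng(outDir, "cip.png", function() plotCip(cip))))
    note(sprintf("CIP: TIV %.1f%% (window %d images), decay %.1f%%, angle diff %.1f%%, flicker %.1f%%",
                 max(cip@tiv), cip@nWindowPlanes, max(cip@meanDecay),
                 max(cip@maxAngleDiff), max(cip@flicker)))
    if (isTRUE(cfg$enable_fpj)) {
      fpj <- rawFourierProjection(raw)
      art <- writeRgbPng(outDir, "fpj.png",
                         array(rep(fpj[, , 1], 3),
                               c(dim(fpj)[1], dim(fpj)[2], 3)))
      reports <- c(reports, makeReport(
        "fpj", "Raw Fourier projection",
        list(spot_contrast = max(fpj) - median(fpj)),
        c(spot_contrast = ""),
        "First/second-order spots at each angle indicate a clean illumination pattern (dense samples only).",
        cfg, art))
      note("FPJ: projection rendered; inspect first/second order spots")
    }
    if (nAngles(raw) == 3L) {
      miv <- motionIlluminationVariation(raw)
      zMid <- floor(dim(miv@rgb)[4] / 2) + 1L
      art <- writeRgbPng(outDir, "miv.png", miv@rgb[, , , zMid])
      colourSpread <- mean(apply(miv@rgb, c(1, 2, 4), function(px)
        max(px) - min(px)))
      reports <- c(reports, makeReport(
        "miv", "Motion & illumination variation",
        list(colour_spread = colourSpread), c(colour_spread = ""),
        "Grey/white means stable; coloured regions indicate motion or uneven illumination between angles.",
        cfg, art))
      note(sprintf("MIV: mean CMY colour spread %.3f", colourSpread))
    } else {
      note("MIV skipped: check assumes 3 angles, stack has ", nAngles(raw))
    }
    mcnRes <- mcnr(raw)
    reports <- c(reports, makeReport(
      "mcn", "Modulation contrast-to-noise",
      list(mcnr = mcnRes@featureMeanMcnr[1],
           wiener = mcnRes@wienerSuggestion[1]),
      c(mcnr = "", wiener = ""),
      "Feature-mean MCNR below ~4 gives unreliable reconstructions; consider the suggested Wiener constant.",
      cfg))
    note(sprintf("MCN: feature-mean MCNR %.2f, Wiener suggestion %.4g",
                 mcnRes@featureMeanMcnr[1], mcnRes@wienerSuggestion[1]))
  }
  if (!is.null(recon)) {
    rih <- reconstructedIntensityHistogram(recon)
    reports <- c(reports, makeReport(
      "rih", "Reconstructed intensity histogram",
      list(mmr = rih@mmr, n_min = rih@nMin, n_max = rih@nMax),
      c(mmr = "", n_min = "px", n_max = "px"),
      "MMR near 1 means reconstructed noise/ringing is as strong as features.",
      cfg, renderPng(outDir, "rih.png", function() plotRih(rih))))
    note(sprintf("RIH: mode %.4g, Min* %.4g, Max* %.4g, MMR %.3f",
                 rih@mode, rih@minStar, rih@maxStar, rih@mmr))
    fps <- fourierPlots(recon)
    zMid <- fps@options$centralZ
    art <- writeRgbPng(outDir, "ftl.png",
                       array(rep(rescale01(fps@ftl[, , zMid]), 3),
                             c(dim(fps@ftl)[1], dim(fps@ftl)[2], 3)))
    reports <- c(reports, makeReport(
      "ftl", "Lateral Fourier spectrum",
      list(mode_cutoff = if (is.null(fps@options$cutoff)) NA_real_
           else fps@options$cutoff),
      c(mode_cutoff = ""),
      "Inspect the spectrum for the flower pattern of a clean reconstruction; stripes indicate edge artifacts.",
      cfg, art))
    reports <- c(reports, makeReport(
      "ftr", "Radial Fourier profile",
      list(profile_bins = nrow(fps@ftr)), c(profile_bins = ""),
      "The profile's inflection point approximates the effective resolution.",
      cfg, renderPng(outDir, "ftr.png", function() plotFtr(fps))))
    note("FTL/FTR: spectra computed (cutoff ",
         if (is.null(fps@options$cutoff)) "none"
         else signif(fps@options$cutoff, 4), ")")
    if (isTRUE(cfg$enable_sam)) {
      sam <- sphericalAberrationMismatch(recon)
      reports <- c(reports, makeReport(
        "sam", "Spherical aberration mismatch",
        list(zmv = sam@zmv), c(zmv = ""),
        "Compare ZMV between similar samples: higher values mean deeper axial intensity dips (OTF mismatch).",
        cfg, renderPng(outDir, "sam.png", function() plotSam(sam))))
      note(sprintf("SAM: ZMV %.4g", sam@zmv))
    }
    if (!is.null(raw) && !is.null(mcnRes)) {
      dR <- dim(recon@data); dM <- dim(mcnRes@map)
      if (dR[1] == 2L * dM[1] && dR[2] == 2L * dM[2] && dR[4] == dM[3]) {
        mcm <- modulationContrastMap(recon, mcnRes, raw)
        zMid <- floor(dim(mcm@rgb)[4] / 2) + 1L
        art <- writeRgbPng(outDir, "mcm.png", mcm@rgb[, , , zMid])
        reports <- c(reports, makeReport(
          "mcm", "Modulation contrast map",
          list(saturated_fraction = mean(mcm@saturationMask)),
          c(saturated_fraction = ""),
          "Purple features lack raw stripe contrast; green marks saturated raw voxels.",
          cfg, art))
        note(sprintf("MCM: saturated fraction %.4g", mean(mcm@saturationMask)))
      } else {
        note("MCM skipped: reconstruction is not 2x the raw grid")
      }
    }
  }
  summary <- do.call(rbind, lapply(reports, function(r) {
    worst <- if (length(r@tiers) == 0) "na"
      else c("na", "ok", "caution", "concern")[max(match(
        r@tiers, c("na", "ok", "caution", "concern")))]
    data.frame(check = r@checkId, title = r@title,
               metrics = paste(sprintf("%s=%.4g", names(r@metrics),
                                       unlist(r@metrics)), collapse = "; "),
               tier = worst, stringsAsFactors = FALSE)
  }))
  if (!is.null(outDir)) {
    write.csv(summary, file.path(outDir, "summary.csv"), row.names = FALSE)
    writeLines(logLines, file.path(outDir, "simqc.log"))
    metricList <- lapply(reports, function(r)
      list(title = r@title, metrics = r@metrics,
           tiers = as.list(r@tiers)))
    names(metricList) <- vapply(reports, function(r) r@checkId, "")
    jsonlite::write_json(metricList, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(reports = reports, summary = summary, log = logLines))
}
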