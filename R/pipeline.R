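#' @include AllClasses.R phantom-cohort.R quantify.R roi.R stats.R
NULL

#' Default pipeline configuration
#'
#' Returns the run configuration as a plain named list (YAML-serializable).
#' \code{"default"} is the study-sized cohort (20/15/28 subjects on a
#' 32x32x8 grid); \code{"tiny"} is a 3-subjects-per-group, 8x8x4 cohort
#' sized for fast end-to-end checks. Both share identical schemas.
#'
#' @param scale \code{"default"} or \code{"tiny"}.
#' @param seed base seed recorded in all outputs.
#' @return named list accepted by [runPipeline()].
#' @export
defaultRunConfig <- function(scale = c("default", "tiny"), seed = 20130101) {
  scale <- match.arg(scale)
  tiny <- scale == "tiny"
  list(
    seed = as.integer(seed),
    cohort = list(
      group_sizes = if (tiny) list(control = 3, MCI = 3, AD = 3)
                    else list(control = 20, MCI = 15, AD = 28),
      global_cv = 45, regional_cv = 6, signal_noise_sd = 0.01,
      age_mean = 73, age_sd = 7,
      dim = if (tiny) c(8, 8, 4) else c(32, 32, 8),
      group_effects = list(AD = list(parietal_lh = 0.85, parietal_rh = 0.85,
                                     temporal_medial_rh = 1.12))),
    acquisition = list(tr = 1.439, te = 0.030, n_frames = 40,
                       n_baseline = 6, k = 1),
    quantification = list(reg_threshold = 0.05, n_aif_voxels = 10,
                          fit_threshold = 0.1, gamma_denoise = TRUE),
    normalizations = c("cer", "wm", "cgm"),
    statistics = list(sides = 2, interaction = FALSE))
}

#' Validate a pipeline configuration
#'
#' Checks the configuration before any computation: required sections,
#' known normalization names, positive timing constants.
#'
#' @param config named list as from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return The config, invisibly, or an error.
#' @export
validateRunConfig <- function(config) {
  need <- c("seed", "cohort", "acquisition", "quantification",
            "normalizations")
  miss <- setdiff(need, names(config))
  if (length(miss))
    dscStop(paste("config missing sections:", paste(miss, collapse = ", ")),
            "dscConfigurationError")
  bad <- setdiff(unlist(config$normalizations), c("cer", "wm", "cgm"))
  if (length(bad))
    dscStop(paste("unknown normalization name(s):",
                  paste(bad, collapse = ", ")), "dscConfigurationError")
  with(config$acquisition, {
    if (tr <= 0 || te <= 0 || n_frames <= n_baseline)
      dscStop("invalid acquisition parameters", "dscConfigurationError")
  })
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return [readRunConfig()]: the validated config list.
#' @export
readRunConfig <- function(path) {
  validateRunConfig(yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @param config config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# build the S4 CohortSpec from the plain config list
configCohortSpec <- function(config) {
  co <- config$cohort
  acq <- with(config$acquisition,
              acquisitionParams(tr, te, n_frames, n_baseline, k))
  effects <- lapply(co$group_effects, function(x) unlist(x))
  cohortSpec(groupSizes = unlist(co$group_sizes),
             groupEffects = if (is.null(effects)) list() else effects,
             globalCV = co$global_cv, regionalCV = co$regional_cv,
             signalNoiseSD = co$signal_noise_sd,
             ageMean = co$age_mean, ageSD = co$age_sd,
             dim = unlist(co$dim), acq = acq, seed = config$seed)
}

#' Run the full simulate-quantify-extract-normalize-compare pipeline
#'
#' Executes every stage on one synthetic cohort, writing all artifacts
#' under \code{outDir}: per-subject NIfTI volumes and truth tables
#' (\code{cohort/}), CBF maps and AIF reports (\code{cbf/}), ROI tables per
#' normalization (\code{tables/}), the four report tables plus run
#' metadata (\code{reports/}), and a manifest with per-file MD5 checksums.
#' Identical config and seed reproduce byte-identical outputs.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param outDir output directory.
#' @return Invisibly, a list with the in-memory \code{tables},
#'   \code{report}, cohort \code{manifest} and \code{outDir}.
#' @export
runPipeline <- function(config, outDir) {
  validateRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  spec <- configCohortSpec(config)
  acq <- spec@acq
  qopt <- config$quantification

  stage <- "simulate"
  cohort <- tryCatch(
    generateCohort(spec, dir = file.path(outDir, "cohort"), keep = TRUE),
    error = function(e) dscStop(paste0("stage ", stage, " failed: ",
                                       conditionMessage(e)),
                                "dscPipelineError"))

  stage <- "quantify"
  cbfDir <- file.path(outDir, "cbf")
  dir.create(cbfDir, showWarnings = FALSE)
  maps <- vector("list", length(cohort$subjects))
  names(maps) <- names(cohort$subjects)
  for (id in names(cohort$subjects)) {
    subj <- cohort$subjects[[id]]
    res <- tryCatch(
      computeCBFMap(subj@signal, mask = subj@labels > 0L, acq = acq,
                    regThreshold = qopt$reg_threshold,
                    nAifVoxels = qopt$n_aif_voxels,
                    fitThreshold = qopt$fit_threshold,
                    gammaDenoise = isTRUE(qopt$gamma_denoise)),
      error = function(e)
        dscStop(paste0("stage ", stage, " failed for subject ", id, ": ",
                       conditionMessage(e)), "dscPipelineError"))
    maps[[id]] <- res$map
    RNifti::writeNifti(cbfValues(res$map),
                       file.path(cbfDir, paste0(id, "_cbf.nii.gz")))
    aif <- res$aif
    jsonlite::write_json(
      list(subject_id = id,
           voxels = as.data.frame(aifVoxels(aif)),
           fit = list(amplitude = aif@fit@amplitude, shape = aif@fit@shape,
                      scale = aif@fit@scale, arrival = aif@fit@arrival),
           curve = list(t = timeGrid(aifCurve(aif)),
                        conc = concValues(aifCurve(aif)))),
      file.path(cbfDir, paste0(id, "_aif.json")),
      auto_unbox = TRUE, digits = NA)
  }

  stage <- "extract"
  tabDir <- file.path(outDir, "tables")
  dir.create(tabDir, showWarnings = FALSE)
  absTab <- tryCatch(
    extractROITable(maps, unname(cohort$subjects)),
    error = function(e) dscStop(paste0("stage ", stage, " failed: ",
                                       conditionMessage(e)),
                                "dscPipelineError"))
  writeROITable(absTab, file.path(tabDir, "roitable_absolute.tsv"))

  stage <- "normalize"
  tables <- list(absolute = absTab)
  for (nm in unlist(config$normalizations)) {
    tables[[nm]] <- normalizeTable(absTab, nm)
    writeROITable(tables[[nm]],
                  file.path(tabDir, paste0("roitable_", nm, ".tsv")))
  }

  stage <- "compare"
  sides <- if (is.null(config$statistics$sides)) 2 else
    config$statistics$sides
  report <- tryCatch(
    compareAll(tables, sides = sides,
               interaction = isTRUE(config$statistics$interaction)),
    error = function(e) dscStop(paste0("stage ", stage, " failed: ",
                                       conditionMessage(e)),
                                "dscPipelineError"))
  writeReports(report, file.path(outDir, "reports"),
               metadata = list(seed = config$seed,
                               normalizations = config$normalizations,
                               quantification = qopt,
                               statistics = config$statistics,
                               package_version =
                                 as.character(utils::packageVersion("dscnorm"))))

  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "run_manifest.json"]
  checksums <- tools::md5sum(files)
  names(checksums) <- sub(paste0("^", outDir, "/?"), "", names(checksums))
  jsonlite::write_json(
    list(seed = config$seed, files = as.list(checksums)),
    file.path(outDir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(tables = tables, report = report,
                 manifest = cohort$manifest, outDir = outDir))
}

#' Build fixture configurations
#'
#' \code{"tiny"} (3 subjects per group, 8x8x4 volumes) runs the full
#' pipeline end to end in well under a minute on one CPU and is used by the
#' package's own tests; \code{"default"} is the study-sized cohort. The
#' per-subject seeds appear in the written cohort manifest.
#'
#' @param scale \code{"tiny"} or \code{"default"}.
#' @param seed base seed.
#' @return A validated configuration list.
#' @export
makeFixtures <- function(scale = c("tiny", "default"), seed = 20130101) {
  scale <- match.arg(scale)
  validateRunConfig(defaultRunConfig(
    scale = if (scale == "tiny") "tiny" else "default", seed = seed))
}
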