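#' @include AllClasses.R phantom-curves.R utils.R
NULL

#' Default phantom region table
#'
#' Ten cortical lobe regions (frontal, parietal, lateral temporal, medial
#' temporal, occipital; both hemispheres), whole-brain white matter,
#' cerebellum, and a feeding artery. Ground-truth CBF values sit on the
#' relative scale typical of uncalibrated DSC maps: cortical gray matter
#' near 0.11, cerebellum near 0.30, white matter near 0.07. Tissue bolus
#' arrival is delayed 2 s after the artery.
#'
#' @return data.frame suitable for the \code{regions} slot of
#'   [CohortSpec-class].
#' @export
defaultRegions <- function() {
  lobes <- c("frontal", "parietal", "temporal_lateral", "temporal_medial",
             "occipital")
  cbf <- c(frontal = 0.115, parietal = 0.112, temporal_lateral = 0.110,
           temporal_medial = 0.104, occipital = 0.108)
  cortical <- do.call(rbind, lapply(c("lh", "rh"), function(h) {
    data.frame(name = paste(lobes, h, sep = "_"), lobe = lobes,
               hemisphere = h, tissue_class = "cortical_gm",
               cbf = unname(cbf[lobes]), mtt = 4, residue = "exponential",
               s0 = 100, delay = 2)
  }))
  extra <- data.frame(
    name = c("wm", "cerebellum", "artery"),
    lobe = c("wm", "cerebellum", "artery"),
    hemisphere = "both",
    tissue_class = c("wm", "cerebellum", "artery"),
    cbf = c(0.07, 0.30, 1), mtt = c(6, 4, 1),
    residue = "exponential", s0 = 100, delay = c(2, 2, 0))
  out <- rbind(cortical, extra)
  out <- cbind(label = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Construct a cohort specification
#'
#' Defaults reproduce the study conditions the package's analyses assume: a
#' cohort of 20 controls, 15 MCI and 28 AD subjects; a global inter-subject
#' perfusion factor with 45\% CV; 6\% regional CV; 1\% Gaussian signal
#' noise; AD-specific regional effects of -15\% in both parietal lobes and
#' +12\% in the right medial temporal lobe; ages normal(73, 7) truncated at
#' 60 years.
#'
#' @param groupSizes named integer vector of subjects per group; the first
#'   name is taken as the control group by downstream statistics.
#' @param regions region table as from [defaultRegions()].
#' @param groupEffects named list: group -> named vector of per-region CBF
#'   multipliers.
#' @param aif [GammaVariateParams-class] of the arterial input function.
#' @param globalCV,regionalCV lognormal multiplicative variability, percent.
#' @param signalNoiseSD Gaussian voxel noise SD as fraction of baseline S0.
#' @param ageMean,ageSD age distribution, years (normal truncated at 60).
#' @param dim phantom grid dimensions, voxels.
#' @param acq [AcquisitionParams-class].
#' @param seed base seed; per-subject seeds are derived deterministically.
#' @return A validated [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(groupSizes = c(control = 3, AD = 3), dim = c(8, 8, 4))
#' spec
#' @export
cohortSpec <- function(groupSizes = c(control = 20L, MCI = 15L, AD = 28L),
                       regions = defaultRegions(),
                       groupEffects = list(
                         AD = c(parietal_lh = 0.85, parietal_rh = 0.85,
                                temporal_medial_rh = 1.12)),
                       aif = gammaVariateParams(1.1, 3, 1.5, arrival = 10),
                       globalCV = 45, regionalCV = 6, signalNoiseSD = 0.01,
                       ageMean = 73, ageSD = 7,
                       dim = c(32L, 32L, 8L),
                       acq = acquisitionParams(), seed = 20130101L) {
  gs <- as.integer(groupSizes)
  names(gs) <- names(groupSizes)
  new("CohortSpec", groupSizes = gs, regions = regions,
      groupEffects = groupEffects, aif = aif,
      globalCV = as.numeric(globalCV), regionalCV = as.numeric(regionalCV),
      signalNoiseSD = as.numeric(signalNoiseSD),
      ageMean = as.numeric(ageMean), ageSD = as.numeric(ageSD),
      dim = as.integer(dim), acq = acq, seed = as.integer(seed))
}

#' Block-layout phantom label geometry
#'
#' Lays the regions of a [CohortSpec-class] out as disjoint rectangular
#' blocks on a regular x-y grid spanning the full z extent: the smallest
#' geometry that exercises all ROI logic. A one-voxel background border
#' separates blocks when cells are large enough. Artery regions are
#' restricted to a 2x2 in-plane core of their cell, reflecting that
#' arterial voxels are rare compared to tissue (the automatic AIF
#' selection criteria assume this).
#'
#' @param spec a [CohortSpec-class] object.
#' @return 3D integer array of labels (0 = background).
#' @export
blockGeometry <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  d <- spec@dim
  n <- nrow(spec@regions)
  gx <- ceiling(sqrt(n))
  gy <- ceiling(n / gx)
  cx <- d[1] %/% gx
  cy <- d[2] %/% gy
  if (cx < 2L || cy < 2L)
    dscStop("grid too small for the region count: empty ROI geometry",
            "dscConfigurationError")
  inset <- if (cx >= 4L && cy >= 4L) 1L else 0L
  labels <- array(0L, dim = d)
  for (i in seq_len(n)) {
    ix <- (i - 1L) %% gx
    iy <- (i - 1L) %/% gx
    xs <- (ix * cx + 1L + inset):((ix + 1L) * cx - inset)
    ys <- (iy * cy + 1L + inset):((iy + 1L) * cy - inset)
    if (spec@regions$tissue_class[i] == "artery") {
      xs <- xs[seq_len(min(2L, length(xs))) + (length(xs) - 2L) %/% 2L]
      ys <- ys[seq_len(min(2L, length(ys))) + (length(ys) - 2L) %/% 2L]
    }
    labels[xs, ys, ] <- spec@regions$label[i]
  }
  labels
}

# Per-subject random attributes, in a fixed draw order so that the
# voxel-level generator and the ROI-level fast path agree exactly.
# Assumes the RNG seed has already been set.
drawSubjectAttributes <- function(spec, group) {
  age <- stats::rnorm(1, spec@ageMean, spec@ageSD)
  while (age < 60) age <- stats::rnorm(1, spec@ageMean, spec@ageSD)
  globalFactor <- rLognormFactor(1, spec@globalCV)
  tissue <- spec@regions[spec@regions$tissue_class != "artery", ]
  regionalFactor <- rLognormFactor(nrow(tissue), spec@regionalCV)
  names(regionalFactor) <- tissue$name
  mult <- rep(1, nrow(tissue))
  names(mult) <- tissue$name
  ge <- spec@groupEffects[[group]]
  if (!is.null(ge)) mult[names(ge)] <- ge
  trueCbf <- tissue$cbf * mult * globalFactor * regionalFactor
  list(age = age, globalFactor = globalFactor,
       truth = data.frame(region = tissue$name, true_cbf = unname(trueCbf),
                          global_factor = globalFactor,
                          regional_factor = unname(regionalFactor),
                          group_multiplier = unname(mult)))
}

#' Generate one synthetic DSC-MRI subject
#'
#' Builds the block-layout label volume, draws the subject's global and
#' regional lognormal perfusion factors and age, synthesizes each region's
#' tissue concentration via the gamma-variate AIF and the residue-function
#' forward model, converts to signal, and adds Gaussian voxel noise. Artery
#' voxels carry the (undelayed) AIF concentration itself. All drawn factors
#' are recorded in the \code{truth} table. The same seed always yields a
#' bit-identical dataset.
#'
#' @param spec a [CohortSpec-class] object.
#' @param group group name; must appear in \code{groupSizes}.
#' @param seed integer RNG seed for this subject.
#' @param subjectId identifier stored in the dataset.
#' @return A [SubjectDataset-class] object.
#' @export
generateSubject <- function(spec, group, seed,
                            subjectId = paste0(group, "_", seed)) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  if (!group %in% names(spec@groupSizes))
    dscStop(paste("unknown group:", group), "dscParameterError")
  labels <- blockGeometry(spec)
  set.seed(seed)
  attrs <- drawSubjectAttributes(spec, group)
  acq <- spec@acq
  t <- timeGrid(acq)
  aif <- gammaVariate(t, spec@aif)
  nF <- acq@nFrames
  d <- spec@dim
  signal <- array(0, dim = c(d, nF))
  s0vox <- array(100, dim = d)  # background baseline
  regions <- spec@regions
  truth <- attrs$truth
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$tissue_class == "artery") {
      conc <- aif
    } else {
      cbf <- truth$true_cbf[truth$region == r$name]
      conc <- tissueConcentration(aif, cbf, r$mtt, r$residue, delay = r$delay)
    }
    sig <- concentrationToSignal(conc, r$s0, acq)
    vox <- which(labels == r$label)
    for (f in seq_len(nF)) signal[vox + (f - 1L) * prod(d)] <- sig[f]
    s0vox[vox] <- r$s0
  }
  bg <- which(labels == 0L)
  for (f in seq_len(nF)) signal[bg + (f - 1L) * prod(d)] <- s0vox[bg]
  if (spec@signalNoiseSD > 0) {
    noise <- stats::rnorm(length(signal), 0, spec@signalNoiseSD) *
      as.numeric(s0vox)
    signal <- pmax(signal + noise, 1e-6)
  }
  lookup <- regions[, c("label", "name", "lobe", "hemisphere", "tissue_class")]
  new("SubjectDataset", signal = signal, labels = labels, lookup = lookup,
      truth = truth, group = group, age = attrs$age, subjectId = subjectId)
}

#' Generate a full synthetic cohort
#'
#' Iterates the groups of the specification, deriving one deterministic
#' seed per subject from the cohort seed, and returns the subjects together
#' with a manifest (\code{subject_id}, \code{group}, \code{age},
#' \code{seed}). Optionally writes each subject's 4D signal and label
#' volumes as gzipped NIfTI plus TSV lookup/truth tables and a JSON
#' manifest to \code{dir}.
#'
#' @param spec a [CohortSpec-class] object.
#' @param dir optional output directory.
#' @param keep if \code{FALSE} and \code{dir} is given, subjects are written
#'   and dropped from memory.
#' @return list with elements \code{subjects} (list of
#'   [SubjectDataset-class], possibly empty if not kept) and
#'   \code{manifest} (data.frame).
#' @export
generateCohort <- function(spec, dir = NULL, keep = is.null(dir)) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      spec@regions[, c("label", "name", "lobe", "hemisphere", "tissue_class")],
      file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  subjects <- list()
  rows <- list()
  idx <- 0L
  for (g in names(spec@groupSizes)) {
    for (j in seq_len(spec@groupSizes[[g]])) {
      idx <- idx + 1L
      sd <- deriveSeed(spec@seed, idx)
      id <- sprintf("%s_%02d", g, j)
      subj <- generateSubject(spec, g, sd, subjectId = id)
      rows[[idx]] <- data.frame(subject_id = id, group = g,
                                age = subj@age, seed = sd)
      if (!is.null(dir)) writeSubject(subj, dir)
      if (keep) subjects[[id]] <- subj
    }
  }
  manifest <- if (idx > 0L) do.call(rbind, rows) else
    data.frame(subject_id = character(), group = character(),
               age = numeric(), seed = integer())
  if (!is.null(dir))
    jsonlite::write_json(
      list(seed = spec@seed, n_subjects = idx, subjects = manifest),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  list(subjects = subjects, manifest = manifest)
}

#' Simulate cohort ROI values without voxel data
#'
#' Fast path for statistical studies: draws exactly the same per-subject
#' global/regional factors and ages as [generateCohort()] (identical RNG
#' stream) but skips image synthesis, returning the ground-truth region
#' means directly as an absolute [ROITable-class]. Useful when the question
#' concerns cohort statistics rather than image quantification.
#'
#' @param spec a [CohortSpec-class] object.
#' @return An absolute [ROITable-class] of ground-truth region values.
#' @export
simulateCohortValues <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  tissue <- spec@regions[spec@regions$tissue_class != "artery", ]
  counts <- tabulate(blockGeometry(spec), nbins = max(spec@regions$label))
  rows <- list(); vals <- list(); idx <- 0L
  for (g in names(spec@groupSizes)) {
    for (j in seq_len(spec@groupSizes[[g]])) {
      idx <- idx + 1L
      sd <- deriveSeed(spec@seed, idx)
      set.seed(sd)
      attrs <- drawSubjectAttributes(spec, g)
      rows[[idx]] <- data.frame(subject_id = sprintf("%s_%02d", g, j),
                                group = g, age = attrs$age)
      vals[[idx]] <- attrs$truth$true_cbf
    }
  }
  if (idx == 0L) {
    values <- matrix(numeric(), 0, nrow(tissue),
                     dimnames = list(NULL, tissue$name))
    subjects <- data.frame(subject_id = character(), group = character(),
                           age = numeric())
  } else {
    values <- do.call(rbind, vals)
    colnames(values) <- tissue$name
    subjects <- do.call(rbind, rows)
  }
  ri <- data.frame(region = tissue$name, lobe = tissue$lobe,
                   hemisphere = tissue$hemisphere,
                   tissue_class = tissue$tissue_class,
                   nvoxels = counts[tissue$label])
  new("ROITable", values = values, subjects = subjects, regionInfo = ri,
      normalization = "absolute")
}

#' Write one subject's volumes and tables
#'
#' Writes \code{<id>_pwi.nii.gz} (4D signal), \code{<id>_labels.nii.gz} and
#' \code{<id>_truth.tsv} into \code{dir}.
#'
#' @param subject a [SubjectDataset-class] object.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
writeSubject <- function(subject, dir) {
  stopifnot(is(subject, "SubjectDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(subject@subjectId,
                                 c("_pwi.nii.gz", "_labels.nii.gz",
                                   "_truth.tsv")))
  RNifti::writeNifti(subject@signal, paths[1])
  RNifti::writeNifti(subject@labels, paths[2])
  utils::write.table(subject@truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
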