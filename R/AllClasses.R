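#' @import methods
NULL

#' Acquisition parameters for a DSC-MRI perfusion series
#'
#' Scanner and timing constants governing the conversion between the measured
#' echo-planar signal and tracer concentration. Defaults follow a typical
#' 1.5T bolus-tracking protocol: TR = 1.439 s, TE = 0.030 s, 40 dynamic
#' frames of which the first 6 precede bolus arrival. The proportionality
#' constant \code{k} of the concentration relation
#' \eqn{C(t) = -(k/TE)\,\ln(S(t)/S_0)} is fixed to 1 by default, so all CBF
#' values are in relative (arbitrary) flow units.
#'
#' @slot tr repetition time between frames, seconds.
#' @slot te echo time, seconds.
#' @slot nFrames number of dynamic frames.
#' @slot nBaseline number of pre-bolus baseline frames.
#' @slot k concentration proportionality constant (arbitrary units).
#'
#' @seealso [acquisitionParams()], [signalToConcentration()]
#' @export
setClass("AcquisitionParams",
  slots = c(tr = "numeric", te = "numeric", nFrames = "integer",
            nBaseline = "integer", k = "numeric"))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (!is.finite(object@tr) || object@tr <= 0) msg <- c(msg, "tr must be > 0")
  if (!is.finite(object@te) || object@te <= 0) msg <- c(msg, "te must be > 0")
  if (object@nBaseline < 1L) msg <- c(msg, "nBaseline must be >= 1")
  if (object@nFrames <= object@nBaseline)
    msg <- c(msg, "nFrames must exceed nBaseline")
  if (!is.finite(object@k) || object@k <= 0) msg <- c(msg, "k must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#'
#' @param tr repetition time, seconds.
#' @param te echo time, seconds.
#' @param nFrames number of dynamic frames.
#' @param nBaseline number of pre-bolus frames used for the S0 baseline.
#' @param k proportionality constant of the concentration conversion.
#' @return An [AcquisitionParams-class] object.
#' @examples
#' acq <- acquisitionParams()
#' timeGrid(acq)[1:5]
#' @export
acquisitionParams <- function(tr = 1.439, te = 0.030, nFrames = 40L,
                              nBaseline = 6L, k = 1) {
  new("AcquisitionParams", tr = as.numeric(tr), te = as.numeric(te),
      nFrames = as.integer(nFrames), nBaseline = as.integer(nBaseline),
      k = as.numeric(k))
}

#' Gamma-variate bolus parameters
#'
#' Parameters of the standard first-pass bolus model
#' \eqn{C(t) = K (t-t_0)^{\alpha} e^{-(t-t_0)/\beta}} for \eqn{t > t_0}
#' and 0 otherwise. The curve peaks at \eqn{t_0 + \alpha\beta}.
#'
#' @slot amplitude scale factor K, concentration units.
#' @slot shape dimensionless shape \eqn{\alpha}.
#' @slot scale time scale \eqn{\beta}, seconds.
#' @slot arrival bolus arrival time \eqn{t_0}, seconds.
#'
#' @seealso [gammaVariate()], [fitGammaVariate()]
#' @export
setClass("GammaVariateParams",
  slots = c(amplitude = "numeric", shape = "numeric", scale = "numeric",
            arrival = "numeric"))

setValidity("GammaVariateParams", function(object) {
  v <- c(object@amplitude, object@shape, object@scale, object@arrival)
  if (any(!is.finite(v))) return("all parameters must be finite")
  msg <- character()
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
  if (object@shape <= 0) msg <- c(msg, "shape must be > 0")
  if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
  if (object@arrival < 0) msg <- c(msg, "arrival must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct gamma-variate parameters
#'
#' @param amplitude K, concentration units; must be positive.
#' @param shape alpha, dimensionless; must be positive.
#' @param scale beta, seconds; must be positive.
#' @param arrival t0, seconds; must be nonnegative.
#' @return A [GammaVariateParams-class] object.
#' @export
gammaVariateParams <- function(amplitude, shape, scale, arrival = 0) {
  new("GammaVariateParams", amplitude = as.numeric(amplitude),
      shape = as.numeric(shape), scale = as.numeric(scale),
      arrival = as.numeric(arrival))
}

#' Tracer concentration-time curve
#'
#' A concentration series sampled on the uniform frame grid of the
#' acquisition (time step = TR).
#'
#' @slot t time grid, seconds; uniform spacing.
#' @slot conc concentration values, arbitrary units.
#' @export
setClass("ConcentrationCurve", slots = c(t = "numeric", conc = "numeric"))

setValidity("ConcentrationCurve", function(object) {
  if (length(object@t) != length(object@conc))
    return("t and conc must have equal length")
  if (length(object@t) >= 3) {
    dt <- diff(object@t)
    if (max(abs(dt - dt[1])) > 1e-8 * dt[1])
      return("time grid must be uniform")
  }
  TRUE
})

#' @rdname ConcentrationCurve-class
#' @param t time grid, seconds.
#' @param conc concentration values.
#' @export
concentrationCurve <- function(t, conc)
  new("ConcentrationCurve", t = as.numeric(t), conc = as.numeric(conc))

#' Cohort specification for the synthetic phantom generator
#'
#' Defines the study conditions under which synthetic DSC-MRI cohorts are
#' generated: group sizes, the per-region ground-truth perfusion table,
#' group-specific regional effects (multipliers), the arterial input
#' function, and the inter-subject variability model. Subject-level
#' variability is multiplicative and lognormal: one global perfusion factor
#' per subject (coefficient of variation \code{globalCV} percent) times
#' independent per-region factors (\code{regionalCV} percent), matching the
#' "ratio" logic of reference-region normalization.
#'
#' @slot groupSizes named integer vector, subjects per diagnostic group.
#' @slot regions data.frame with one row per region: \code{label},
#'   \code{name}, \code{lobe}, \code{hemisphere}, \code{tissue_class}
#'   (one of cortical_gm, wm, cerebellum, artery), \code{cbf} (ground-truth
#'   relative flow), \code{mtt} (s), \code{residue} (exponential or boxcar),
#'   \code{s0} (baseline signal), \code{delay} (bolus arrival delay after
#'   the artery, s).
#' @slot groupEffects named list: group -> named numeric vector of per-region
#'   CBF multipliers (regions not named keep multiplier 1).
#' @slot aif [GammaVariateParams-class] of the arterial input function.
#' @slot globalCV inter-subject global perfusion CV, percent.
#' @slot regionalCV per-region perfusion CV, percent.
#' @slot signalNoiseSD Gaussian voxel noise SD as a fraction of baseline S0.
#' @slot ageMean,ageSD age distribution (normal, truncated at 60), years.
#' @slot dim 3D phantom grid dimensions, voxels.
#' @slot acq [AcquisitionParams-class].
#' @slot seed base RNG seed; per-subject seeds are derived from it.
#' @seealso [cohortSpec()], [generateCohort()], [simulateCohortValues()]
#' @export
setClass("CohortSpec",
  slots = c(groupSizes = "integer", regions = "data.frame",
            groupEffects = "list", aif = "GammaVariateParams",
            globalCV = "numeric", regionalCV = "numeric",
            signalNoiseSD = "numeric", ageMean = "numeric", ageSD = "numeric",
            dim = "integer", acq = "AcquisitionParams", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  need <- c("label", "name", "lobe", "hemisphere", "tissue_class",
            "cbf", "mtt", "residue", "s0", "delay")
  if (!all(need %in% names(object@regions)))
    msg <- c(msg, paste("regions must have columns:",
                        paste(need, collapse = ", ")))
  if (any(object@groupSizes < 0L)) msg <- c(msg, "group sizes must be >= 0")
  if (is.null(names(object@groupSizes)) || any(names(object@groupSizes) == ""))
    msg <- c(msg, "groupSizes must be named")
  if (object@globalCV < 0 || object@regionalCV < 0)
    msg <- c(msg, "CVs must be >= 0")
  if (object@signalNoiseSD < 0) msg <- c(msg, "signalNoiseSD must be >= 0")
  if (all(need %in% names(object@regions))) {
    if (any(object@regions$cbf < 0)) msg <- c(msg, "region cbf must be >= 0")
    if (any(object@regions$mtt <= 0)) msg <- c(msg, "region mtt must be > 0")
    if (any(object@regions$s0 <= 0)) msg <- c(msg, "region s0 must be > 0")
    if (!any(object@regions$tissue_class == "artery"))
      msg <- c(msg, "regions must include an artery")
    if (anyDuplicated(object@regions$name))
      msg <- c(msg, "region names must be unique")
    bad <- setdiff(unlist(lapply(object@groupEffects, names)),
                   object@regions$name)
    if (length(bad))
      msg <- c(msg, paste("groupEffects name unknown regions:",
                          paste(bad, collapse = ", ")))
  }
  if (length(object@dim) != 3L || any(object@dim < 2L))
    msg <- c(msg, "dim must be three values >= 2")
  if (length(msg)) msg else TRUE
})

#' One synthetic subject's DSC-MRI dataset
#'
#' @slot signal 4D array (x, y, z, frame) of MR signal values.
#' @slot labels 3D integer array of region labels; 0 is background.
#' @slot lookup data.frame mapping labels to region names, lobes,
#'   hemispheres and tissue classes.
#' @slot truth data.frame with one row per non-artery region: the realized
#'   ground-truth CBF (\code{true_cbf}) and the drawn \code{global_factor}
#'   and \code{regional_factor}.
#' @slot group diagnostic group name.
#' @slot age subject age, years.
#' @slot subjectId subject identifier.
#' @export
setClass("SubjectDataset",
  slots = c(signal = "array", labels = "array", lookup = "data.frame",
            truth = "data.frame", group = "character", age = "numeric",
            subjectId = "character"))

setValidity("SubjectDataset", function(object) {
  msg <- character()
  ds <- dim(object@signal); dl <- dim(object@labels)
  if (length(ds) != 4L) msg <- c(msg, "signal must be 4D")
  if (length(dl) != 3L) msg <- c(msg, "labels must be 3D")
  if (length(ds) == 4L && length(dl) == 3L && !all(ds[1:3] == dl))
    msg <- c(msg, "signal and labels must share spatial dimensions")
  if (any(object@signal <= 0)) msg <- c(msg, "signal values must be > 0")
  labs <- setdiff(unique(as.integer(object@labels)), 0L)
  if (!all(labs %in% object@lookup$label))
    msg <- c(msg, "every nonzero label must appear in lookup")
  if (length(msg)) msg else TRUE
})

#' CBF parametric map
#'
#' A 3D volume of cerebral-blood-flow estimates (relative flow units) with a
#' mask of voxels where quantification succeeded. Voxels outside the mask
#' (background, nonpositive baselines, failed gamma fits) carry \code{NA}.
#'
#' @slot values 3D numeric array of CBF estimates.
#' @slot mask 3D logical array of valid voxels.
#' @export
setClass("CBFMap", slots = c(values = "array", mask = "array"))

setValidity("CBFMap", function(object) {
  if (!all(dim(object@values) == dim(object@mask)))
    return("values and mask must have identical dimensions")
  v <- object@values[object@mask]
  if (any(!is.finite(v)) || any(v < 0))
    return("masked values must be finite and >= 0")
  TRUE
})

#' @rdname CBFMap-class
#' @param values 3D numeric array of CBF estimates.
#' @param mask 3D logical array; defaults to the finite voxels of
#'   \code{values}.
#' @export
cbfMap <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- array(is.finite(values), dim = dim(values))
  new("CBFMap", values = values, mask = mask)
}

#' Automatic AIF detection result
#'
#' @slot curve [ConcentrationCurve-class]: the mean of the selected voxels'
#'   fitted gamma-variate curves.
#' @slot voxels integer matrix (n x 3) of selected voxel coordinates.
#' @slot fit [GammaVariateParams-class] of the strongest selected voxel.
#' @slot diagnostics list with the quantile thresholds used and per-voxel
#'   candidate features.
#' @export
setClass("AIFResult",
  slots = c(curve = "ConcentrationCurve", voxels = "matrix",
            fit = "GammaVariateParams", diagnostics = "list"))

setValidity("AIFResult", function(object) {
  if (nrow(object@voxels) < 1L) return("at least one voxel must be selected")
  if (ncol(object@voxels) != 3L) return("voxels must be an n x 3 matrix")
  TRUE
})

#' Deconvolved residue-function estimate
#'
#' Samples of the flow-scaled residue function \eqn{CBF \cdot R(t)}
#' recovered by regularized deconvolution, with the CBF estimate taken as
#' its maximum (clamped at 0).
#'
#' @slot rScaled numeric vector of \eqn{CBF \cdot R(t)} samples.
#' @slot cbf the CBF estimate, \code{max(rScaled)}, never negative.
#' @seealso [deconvolve()]
#' @export
setClass("ResidueEstimate", slots = c(rScaled = "numeric", cbf = "numeric"))

setValidity("ResidueEstimate", function(object) {
  if (length(object@cbf) != 1L || !is.finite(object@cbf))
    return("cbf must be a single finite value")
  if (object@cbf < 0) return("cbf must be >= 0")
  if (abs(object@cbf - max(max(object@rScaled), 0)) > 1e-12 * (1 + object@cbf))
    return("cbf must equal max(rScaled) clamped at 0")
  TRUE
})

#' Subjects-by-regions table of mean CBF values
#'
#' The central tabular container: one row per subject, one column per
#' region (per-hemisphere lobes plus cerebellum and whole-brain white
#' matter), holding mean CBF in relative flow units, either absolute or
#' normalized by a reference region. Missing values are \code{NA}, never 0.
#'
#' @slot values numeric matrix, subjects x regions.
#' @slot subjects data.frame: \code{subject_id}, \code{group}, \code{age}.
#' @slot regionInfo data.frame: \code{region}, \code{lobe},
#'   \code{hemisphere}, \code{tissue_class}, \code{nvoxels}.
#' @slot normalization one of \code{"absolute"}, \code{"cer"}, \code{"wm"},
#'   \code{"cgm"}.
#' @seealso [extractROITable()], [normalizeTable()], [referenceValue()]
#' @export
setClass("ROITable",
  slots = c(values = "matrix", subjects = "data.frame",
            regionInfo = "data.frame", normalization = "character"))

setValidity("ROITable", function(object) {
  msg <- character()
  if (!object@normalization %in% c("absolute", "cer", "wm", "cgm"))
    msg <- c(msg, "normalization must be absolute, cer, wm or cgm")
  if (nrow(object@values) != nrow(object@subjects))
    msg <- c(msg, "one subjects row per values row required")
  if (ncol(object@values) != nrow(object@regionInfo))
    msg <- c(msg, "one regionInfo row per values column required")
  if (!identical(colnames(object@values), object@regionInfo$region))
    msg <- c(msg, "values columns must match regionInfo$region")
  v <- object@values[is.finite(object@values)]
  if (any(v < 0)) msg <- c(msg, "CBF values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Variance-components decomposition
#'
#' Method-of-moments estimates from the two-way random-effects ANOVA of the
#' normalized CBF values, attributing variance to the diagnosis group, the
#' normalization method, and residual (intra-group) variation. Negative
#' moment estimates are truncated to zero before proportions are formed.
#'
#' @slot variances named numeric: \code{diagnosis}, \code{normalization},
#'   optionally \code{interaction}, and \code{residual}.
#' @slot proportions same names; nonnegative, summing to 1.
#' @seealso [varianceComponents()]
#' @export
setClass("VarianceComponents",
  slots = c(variances = "numeric", proportions = "numeric"))

setValidity("VarianceComponents", function(object) {
  if (any(object@variances < 0)) return("variance components must be >= 0")
  s <- sum(object@proportions)
  # all-zero proportions mark the degenerate constant-data case
  if (abs(s - 1) > 1e-9 && s != 0)
    return("proportions must sum to 1 (or all be 0 for constant data)")
  TRUE
})
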