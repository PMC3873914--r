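#' @include AllClasses.R
NULL

#' Accessors for dscnorm objects
#'
#' Small accessor generics exposing slots of the package's S4 classes
#' without touching \code{@} directly.
#'
#' @param object a dscnorm S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))
#' @rdname accessors
#' @export
setGeneric("concValues", function(object) standardGeneric("concValues"))
#' @rdname accessors
#' @export
setGeneric("cbfValues", function(object) standardGeneric("cbfValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("roiValues", function(object) standardGeneric("roiValues"))
#' @rdname accessors
#' @export
setGeneric("subjectInfo", function(object) standardGeneric("subjectInfo"))
#' @rdname accessors
#' @export
setGeneric("regionInfo", function(object) standardGeneric("regionInfo"))
#' @rdname accessors
#' @export
setGeneric("normalization", function(object) standardGeneric("normalization"))
#' @rdname accessors
#' @export
setGeneric("aifCurve", function(object) standardGeneric("aifCurve"))
#' @rdname accessors
#' @export
setGeneric("aifVoxels", function(object) standardGeneric("aifVoxels"))

#' @rdname accessors
#' @export
setMethod("timeGrid", "AcquisitionParams", function(object)
  (seq_len(object@nFrames) - 1) * object@tr)
#' @rdname accessors
#' @export
setMethod("timeGrid", "ConcentrationCurve", function(object) object@t)
#' @rdname accessors
#' @export
setMethod("concValues", "ConcentrationCurve", function(object) object@conc)
#' @rdname accessors
#' @export
setMethod("cbfValues", "CBFMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("validMask", "CBFMap", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("roiValues", "ROITable", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("subjectInfo", "ROITable", function(object) object@subjects)
#' @rdname accessors
#' @export
setMethod("regionInfo", "ROITable", function(object) object@regionInfo)
#' @rdname accessors
#' @export
setMethod("normalization", "ROITable", function(object) object@normalization)
#' @rdname accessors
#' @export
setMethod("aifCurve", "AIFResult", function(object) object@curve)
#' @rdname accessors
#' @export
setMethod("aifVoxels", "AIFResult", function(object) object@voxels)

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams: TR=%.3f s, TE=%.3f s, %d frames (%d baseline), k=%g\n",
    object@tr, object@te, object@nFrames, object@nBaseline, object@k))
})

setMethod("show", "GammaVariateParams", function(object) {
  cat(sprintf(
    "GammaVariateParams: K=%.4g, alpha=%.4g, beta=%.4g s, t0=%.4g s (peak at %.4g s)\n",
    object@amplitude, object@shape, object@scale, object@arrival,
    object@arrival + object@shape * object@scale))
})

setMethod("show", "ConcentrationCurve", function(object) {
  cat(sprintf("ConcentrationCurve: %d samples, t in [%.3g, %.3g] s, peak %.4g\n",
              length(object@t), min(object@t), max(object@t),
              if (length(object@conc)) max(object@conc) else NA))
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(object@groupSizes),
                                  object@groupSizes), collapse = ", "), "\n")
  cat(sprintf("  %d regions on a %s grid\n", nrow(object@regions),
              paste(object@dim, collapse = "x")))
  cat(sprintf("  global CV %.1f%%, regional CV %.1f%%, signal noise %.1f%% of S0\n",
              object@globalCV, object@regionalCV, 100 * object@signalNoiseSD))
  cat(sprintf("  seed %d\n", object@seed))
})

setMethod("show", "SubjectDataset", function(object) {
  d <- dim(object@signal)
  cat(sprintf("SubjectDataset %s (%s, age %.1f): %dx%dx%d voxels, %d frames, %d regions\n",
              object@subjectId, object@group, object@age,
              d[1], d[2], d[3], d[4], nrow(object@lookup)))
})

setMethod("show", "CBFMap", function(object) {
  cat(sprintf("CBFMap: %s, %d valid voxels, CBF range [%.3g, %.3g]\n",
              paste(dim(object@values), collapse = "x"), sum(object@mask),
              suppressWarnings(min(object@values[object@mask])),
              suppressWarnings(max(object@values[object@mask]))))
})

setMethod("show", "AIFResult", function(object) {
  cat(sprintf("AIFResult: %d voxels selected, peak %.4g at %.3g s\n",
              nrow(object@voxels), max(object@curve@conc),
              object@curve@t[which.max(object@curve@conc)]))
})

setMethod("show", "ROITable", function(object) {
  cat(sprintf("ROITable (%s): %d subjects x %d regions\n",
              object@normalization, nrow(object@values), ncol(object@values)))
  cat("  groups:", paste(sprintf("%s=%d", names(table(object@subjects$group)),
                                 table(object@subjects$group)), collapse = ", "), "\n")
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents\n")
  for (nm in names(object@variances))
    cat(sprintf("  %-13s %10.4g  (%.1f%%)\n", nm, object@variances[nm],
                100 * object@proportions[nm]))
})

#' @rdname accessors
#' @export
setGeneric("varProportions", function(object) standardGeneric("varProportions"))
#' @rdname accessors
#' @export
setMethod("varProportions", "VarianceComponents",
          function(object) object@proportions)
#' @rdname accessors
#' @export
setGeneric("varEstimates", function(object) standardGeneric("varEstimates"))
#' @rdname accessors
#' @export
setMethod("varEstimates", "VarianceComponents",
          function(object) object@variances)
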