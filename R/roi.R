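#' @include AllClasses.R utils.R
NULL

#' Mean CBF over one labelled region
#'
#' Averages the valid (masked) CBF voxels carrying the given label.
#' Invalid voxels are excluded from the mean, not zero-filled; a region
#' that is absent or contains no valid voxel yields \code{NA} with a
#' warning.
#'
#' @param map a [CBFMap-class] object.
#' @param labels 3D integer label array matching the map's dimensions.
#' @param label the label to average.
#' @return list with \code{mean} (flow units or \code{NA}) and \code{n}
#'   (number of valid voxels used).
#' @export
roiMean <- function(map, labels, label) {
  stopifnot(is(map, "CBFMap"))
  if (!all(dim(labels) == dim(cbfValues(map))))
    dscStop("labels must match the map's dimensions", "dscParameterError")
  inRegion <- labels == label
  if (!any(inRegion)) {
    warning(sprintf("label %s absent from the volume: missing value", label))
    return(list(mean = NA_real_, n = 0L))
  }
  use <- inRegion & validMask(map)
  if (!any(use)) {
    warning(sprintf("label %s has no valid voxel: missing value", label))
    return(list(mean = NA_real_, n = 0L))
  }
  list(mean = mean(cbfValues(map)[use]), n = sum(use))
}

#' Aggregate gyrus-level means to lobes
#'
#' Combines per-gyrus ROI means into per-hemisphere lobe means using
#' voxel-count weighting, which makes the lobe mean identical to a direct
#' mean over all lobe voxels.
#'
#' @param roiMeans named numeric vector of per-region means (names = region
#'   names).
#' @param roiCounts named integer vector of valid voxel counts, same names.
#' @param mapping data.frame with columns \code{name}, \code{lobe},
#'   \code{hemisphere} covering every entry of \code{roiMeans}.
#' @return list with \code{means} and \code{counts}, named
#'   \code{<lobe>_<hemisphere>}.
#' @export
aggregateLobes <- function(roiMeans, roiCounts, mapping) {
  miss <- setdiff(names(roiMeans), mapping$name)
  if (length(miss))
    dscStop(paste("unmapped cortical labels:", paste(miss, collapse = ", ")),
            "dscConfigurationError")
  m <- mapping[match(names(roiMeans), mapping$name), ]
  key <- paste(m$lobe, m$hemisphere, sep = "_")
  means <- counts <- numeric(0)
  for (k in unique(key)) {
    i <- which(key == k)
    ok <- i[is.finite(roiMeans[i]) & roiCounts[i] > 0]
    if (length(ok)) {
      means[k] <- sum(roiMeans[ok] * roiCounts[ok]) / sum(roiCounts[ok])
      counts[k] <- sum(roiCounts[ok])
    } else {
      means[k] <- NA_real_
      counts[k] <- 0
    }
  }
  list(means = means, counts = as.integer(counts))
}

#' Per-subject reference value for normalization
#'
#' Computes the denominator of the intensity normalization for each
#' subject: the cerebellum mean (\code{"cer"}), the whole-brain white
#' matter mean (\code{"wm"}), or whole-brain cortical gray matter
#' (\code{"cgm"}) as the unweighted average of the lobe means (hemispheres
#' averaged within each lobe first; set \code{cgmWeighting = "voxel"} for a
#' voxel-count-weighted average instead).
#'
#' @param table an absolute [ROITable-class].
#' @param which \code{"cer"}, \code{"wm"} or \code{"cgm"}.
#' @param cgmWeighting \code{"unweighted"} (default) or \code{"voxel"}.
#' @return numeric vector, one reference value per subject (\code{NA} where
#'   a required region is missing).
#' @export
referenceValue <- function(table, which = c("cer", "wm", "cgm"),
                           cgmWeighting = c("unweighted", "voxel")) {
  stopifnot(is(table, "ROITable"))
  which <- match.arg(which)
  cgmWeighting <- match.arg(cgmWeighting)
  ri <- regionInfo(table)
  v <- roiValues(table)
  classMean <- function(cls) {
    cols <- which(ri$tissue_class == cls)
    if (!length(cols)) {
      warning(sprintf("no %s region in table: missing reference", cls))
      return(rep(NA_real_, nrow(v)))
    }
    if (length(cols) == 1L) return(unname(v[, cols]))
    w <- ri$nvoxels[cols]
    as.numeric(v[, cols, drop = FALSE] %*% (w / sum(w)))
  }
  if (which == "cer") return(classMean("cerebellum"))
  if (which == "wm") return(classMean("wm"))
  cols <- which(ri$tissue_class == "cortical_gm")
  if (!length(cols)) {
    warning("no cortical region in table: missing reference")
    return(rep(NA_real_, nrow(v)))
  }
  if (cgmWeighting == "voxel") {
    w <- ri$nvoxels[cols]
    return(as.numeric(v[, cols, drop = FALSE] %*% (w / sum(w))))
  }
  lobes <- unique(ri$lobe[cols])
  lobeMeans <- vapply(lobes, function(lb) {
    cc <- cols[ri$lobe[cols] == lb]
    rowMeans(v[, cc, drop = FALSE])
  }, numeric(nrow(v)))
  if (nrow(v) == 1L) lobeMeans <- matrix(lobeMeans, nrow = 1L)
  unname(rowMeans(lobeMeans))
}

#' Normalize an ROI table by a reference region
#'
#' Divides every region value by the subject's reference value, cancelling
#' the subject-level global perfusion scale. Subjects whose reference is
#' missing or nonpositive are dropped with a message.
#'
#' @param table an absolute [ROITable-class].
#' @param which reference region: \code{"cer"}, \code{"wm"} or \code{"cgm"}.
#' @param cgmWeighting passed to [referenceValue()].
#' @return A normalized [ROITable-class].
#' @examples
#' spec <- cohortSpec(groupSizes = c(control = 4, AD = 4))
#' tab <- simulateCohortValues(spec)
#' roiValues(normalizeTable(tab, "cgm"))[1:2, 1:3]
#' @export
normalizeTable <- function(table, which = c("cer", "wm", "cgm"),
                           cgmWeighting = c("unweighted", "voxel")) {
  stopifnot(is(table, "ROITable"))
  which <- match.arg(which)
  if (normalization(table) != "absolute")
    dscStop("can only normalize an absolute table", "dscParameterError")
  ref <- referenceValue(table, which, cgmWeighting)
  keep <- is.finite(ref) & ref > 0
  if (!all(keep))
    message(sprintf("dropping %d subject(s) with missing/zero %s reference: %s",
                    sum(!keep), which,
                    paste(subjectInfo(table)$subject_id[!keep],
                          collapse = ", ")))
  new("ROITable", values = roiValues(table)[keep, , drop = FALSE] / ref[keep],
      subjects = subjectInfo(table)[keep, , drop = FALSE],
      regionInfo = regionInfo(table), normalization = which)
}

#' Build an ROI table from CBF maps and label volumes
#'
#' For each subject, computes per-label means on the CBF map, aggregates
#' cortical gyri to per-hemisphere lobes (voxel-weighted), and pools white
#' matter and cerebellum labels into single regions. Artery labels are
#' excluded.
#'
#' @param maps list of [CBFMap-class], one per subject.
#' @param subjects list of [SubjectDataset-class] in the same order (the
#'   label volume, lookup, group and age come from here).
#' @return An absolute [ROITable-class].
#' @export
extractROITable <- function(maps, subjects) {
  stopifnot(length(maps) == length(subjects), length(maps) >= 1L)
  rows <- vector("list", length(maps))
  riOut <- NULL
  for (s in seq_along(maps)) {
    subj <- subjects[[s]]
    lk <- subj@lookup
    perLabel <- lapply(lk$label, function(lb)
      suppressWarnings(roiMean(maps[[s]], subj@labels, lb)))
    means <- vapply(perLabel, `[[`, numeric(1), "mean")
    counts <- vapply(perLabel, function(x) as.integer(x$n), integer(1))
    names(means) <- names(counts) <- lk$name
    cortical <- lk$tissue_class == "cortical_gm"
    agg <- aggregateLobes(means[cortical], counts[cortical], lk[cortical, ])
    vals <- agg$means
    nvox <- agg$counts
    info <- data.frame(
      region = names(vals),
      lobe = lk$lobe[cortical][match(names(vals),
        paste(lk$lobe[cortical], lk$hemisphere[cortical], sep = "_"))],
      hemisphere = sub(".*_", "", names(vals)),
      tissue_class = "cortical_gm")
    for (cls in c("wm", "cerebellum")) {
      sel <- lk$tissue_class == cls
      if (any(sel)) {
        ok <- sel & is.finite(means) & counts > 0
        vals[cls] <- if (any(ok))
          sum(means[ok] * counts[ok]) / sum(counts[ok]) else NA_real_
        nvox[cls] <- sum(counts[ok])
        info <- rbind(info, data.frame(region = cls, lobe = cls,
                                       hemisphere = "both",
                                       tissue_class = cls))
      }
    }
    info$nvoxels <- as.integer(nvox)
    if (is.null(riOut)) riOut <- info
    rows[[s]] <- list(id = subj@subjectId, group = subj@group,
                      age = subj@age, vals = vals)
  }
  values <- do.call(rbind, lapply(rows, `[[`, "vals"))
  colnames(values) <- riOut$region
  subjectsDf <- data.frame(
    subject_id = vapply(rows, `[[`, character(1), "id"),
    group = vapply(rows, `[[`, character(1), "group"),
    age = vapply(rows, `[[`, numeric(1), "age"))
  rownames(riOut) <- NULL
  new("ROITable", values = values, subjects = subjectsDf,
      regionInfo = riOut, normalization = "absolute")
}

#' Write / read an ROI table as TSV
#'
#' The on-disk format is one row per subject with columns
#' \code{subject_id}, \code{group}, \code{age}, \code{normalization},
#' followed by one column per region. Region metadata are stored alongside
#' in \code{<stem>_regions.tsv}.
#'
#' @param table an [ROITable-class].
#' @param path TSV output path.
#' @return Invisibly, \code{path}.
#' @export
writeROITable <- function(table, path) {
  stopifnot(is(table, "ROITable"))
  df <- cbind(subjectInfo(table), normalization = normalization(table),
              as.data.frame(roiValues(table)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(regionInfo(table),
                     sub("\\.tsv$", "_regions.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeROITable
#' @param path TSV path previously written by [writeROITable()].
#' @export
readROITable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ri <- utils::read.delim(sub("\\.tsv$", "_regions.tsv", path))
  meta <- c("subject_id", "group", "age", "normalization")
  values <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  new("ROITable", values = values,
      subjects = df[, c("subject_id", "group", "age")],
      regionInfo = ri, normalization = unique(df$normalization))
}
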