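test_that("roiMean averages valid voxels and flags missing regions", {
  vals <- array(NA_real_, dim = c(2, 2, 1))
  vals[1, 1, 1] <- 2; vals[2, 1, 1] <- 4; vals[1, 2, 1] <- 9
  mask <- array(!is.na(vals), dim = dim(vals))
  labels <- array(0L, dim = dim(vals))
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 1L; labels[2, 2, 1] <- 1L
  map <- cbfMap(vals, mask)
  r <- roiMean(map, labels, 1L)
  expect_equal(r$mean, 3)   # the invalid voxel is excluded
  expect_equal(r$n, 2L)
  expect_warning(r2 <- roiMean(map, labels, 99L), "absent")
  expect_true(is.na(r2$mean))
  labels2 <- labels; labels2[2, 2, 1] <- 2L
  map2 <- cbfMap(vals, array(FALSE, dim = dim(vals)))
  expect_warning(r3 <- roiMean(map2, labels2, 2L), "no valid voxel")
  expect_true(is.na(r3$mean))
})

test_that("lobe aggregation equals the voxel-weighted mean and the merged-label oracle", {
  mapping <- data.frame(name = c("gyrusA", "gyrusB"), lobe = "frontal",
                        hemisphere = "lh")
  agg <- aggregateLobes(c(gyrusA = 1, gyrusB = 3), c(gyrusA = 10L, gyrusB = 30L),
                        mapping)
  expect_equal(unname(agg$means["frontal_lh"]), 2.5)
  single <- aggregateLobes(c(gyrusA = 1.7), c(gyrusA = 10L), mapping)
  expect_equal(unname(single$means["frontal_lh"]), 1.7)
  expect_error(aggregateLobes(c(other = 1), c(other = 2L), mapping),
               class = "dscConfigurationError")

  # oracle: aggregation equals roiMean over the merged label set
  set.seed(9)
  vals <- array(runif(64, 0.05, 0.3), dim = c(4, 4, 4))
  labels <- array(sample(1:3, 64, replace = TRUE), dim = c(4, 4, 4))
  map <- cbfMap(vals)
  per <- lapply(1:3, function(l) roiMean(map, labels, l))
  means <- vapply(per, `[[`, numeric(1), "mean")
  counts <- vapply(per, function(x) as.integer(x$n), integer(1))
  names(means) <- names(counts) <- paste0("g", 1:3)
  mapping3 <- data.frame(name = paste0("g", 1:3), lobe = "parietal",
                         hemisphere = "rh")
  agg3 <- aggregateLobes(means, counts, mapping3)
  merged <- roiMean(map, array(1L, dim = dim(labels)), 1L)
  expect_equal(unname(agg3$means["parietal_rh"]), merged$mean,
               tolerance = 1e-12)
})

makeTable <- function(values, lobes, hemis, classes) {
  n <- nrow(values)
  regions <- ifelse(hemis == "both", lobes, paste(lobes, hemis, sep = "_"))
  colnames(values) <- regions
  new("ROITable", values = values,
      subjects = data.frame(subject_id = paste0("s", seq_len(n)),
                            group = rep("control", n), age = rep(70, n)),
      regionInfo = data.frame(region = regions, lobe = lobes,
                              hemisphere = hemis, tissue_class = classes,
                              nvoxels = 10L),
      normalization = "absolute")
}

test_that("reference values follow their definitions and are permutation-invariant", {
  lobes <- c("frontal", "parietal", "temporal_lateral", "temporal_medial",
             "occipital", "cerebellum", "wm")
  hemis <- c(rep("lh", 5), "both", "both")
  classes <- c(rep("cortical_gm", 5), "cerebellum", "wm")
  v <- matrix(c(1, 2, 3, 4, 5, 0.30, 0.07), nrow = 1)
  tab <- makeTable(v, lobes, hemis, classes)
  expect_equal(referenceValue(tab, "cgm"), 3)   # mean of the lobe means
  expect_equal(referenceValue(tab, "cer"), 0.30)
  expect_equal(referenceValue(tab, "wm"), 0.07)
  # permuting lobes leaves cgm unchanged
  perm <- c(5, 3, 1, 2, 4, 6, 7)
  tabp <- makeTable(v[, perm, drop = FALSE], lobes[perm], hemis[perm],
                    classes[perm])
  expect_equal(referenceValue(tabp, "cgm"), 3)
  # hemispheres are averaged within a lobe before lobes are averaged
  tab2 <- makeTable(matrix(c(1, 3, 5, 0.3, 0.07), nrow = 1),
                    c("frontal", "frontal", "parietal", "cerebellum", "wm"),
                    c("lh", "rh", "lh", "both", "both"),
                    c(rep("cortical_gm", 3), "cerebellum", "wm"))
  expect_equal(referenceValue(tab2, "cgm"), mean(c(mean(c(1, 3)), 5)))
})

test_that("normalization divides by the subject reference and is scale-invariant", {
  spec <- tinySpec()
  tab <- simulateCohortValues(spec)
  cgm <- normalizeTable(tab, "cgm")
  ref <- referenceValue(tab, "cgm")
  expect_equal(roiValues(cgm)[3, "parietal_lh"],
               roiValues(tab)[3, "parietal_lh"] / ref[3], tolerance = 1e-14)
  # the reference region normalized by itself is exactly 1
  cer <- normalizeTable(tab, "cer")
  expect_identical(unname(roiValues(cer)[, "cerebellum"]),
                   rep(1, nrow(roiValues(cer))))
  # global rescaling of one subject's absolute values cancels exactly
  v2 <- roiValues(tab); v2[4, ] <- v2[4, ] * 7
  tab2 <- new("ROITable", values = v2, subjects = subjectInfo(tab),
              regionInfo = regionInfo(tab), normalization = "absolute")
  cgm2 <- normalizeTable(tab2, "cgm")
  expect_equal(roiValues(cgm2)[4, ], roiValues(cgm)[4, ], tolerance = 1e-12)
  # a simple ratio: ROI 0.22 over reference 0.11 is 2
  expect_equal(0.22 / 0.11, 2)
})

test_that("subjects with a missing or zero reference are dropped with a message", {
  spec <- tinySpec()
  tab <- simulateCohortValues(spec)
  v <- roiValues(tab); v[2, "cerebellum"] <- 0
  tab0 <- new("ROITable", values = v, subjects = subjectInfo(tab),
              regionInfo = regionInfo(tab), normalization = "absolute")
  expect_message(cer <- normalizeTable(tab0, "cer"), "dropping 1")
  expect_equal(nrow(roiValues(cer)), nrow(v) - 1)
})

test_that("extraction + lobe aggregation equals direct means over lobe voxels", {
  # split one lobe into two gyrus labels and check the aggregate
  regions <- data.frame(
    label = 1:4,
    name = c("sup_parietal", "precuneus", "cerebellum", "artery"),
    lobe = c("parietal", "parietal", "cerebellum", "artery"),
    hemisphere = c("rh", "rh", "both", "both"),
    tissue_class = c("cortical_gm", "cortical_gm", "cerebellum", "artery"),
    cbf = c(0.12, 0.10, 0.30, 1), mtt = 4, residue = "exponential",
    s0 = 100, delay = c(2, 2, 2, 0))
  spec <- cohortSpec(groupSizes = c(control = 1L), regions = regions,
                     groupEffects = list(), globalCV = 0, regionalCV = 0,
                     signalNoiseSD = 0, dim = c(12, 12, 2))
  subj <- generateSubject(spec, "control", 6)
  res <- computeCBFMap(subj@signal, subj@labels > 0L, acquisitionParams())
  tab <- extractROITable(list(res$map), list(subj))
  expect_setequal(regionInfo(tab)$region,
                  c("parietal_rh", "cerebellum"))
  merged <- ifelse(subj@labels %in% c(1L, 2L), 1L, 0L)
  direct <- roiMean(res$map, array(merged, dim = dim(subj@labels)), 1L)
  expect_equal(unname(roiValues(tab)[1, "parietal_rh"]), direct$mean,
               tolerance = 1e-12)
})

test_that("ROI tables round-trip through TSV", {
  spec <- tinySpec()
  tab <- simulateCohortValues(spec)
  path <- file.path(tempdir(), "roitable_test.tsv")
  writeROITable(tab, path)
  back <- readROITable(path)
  expect_equal(roiValues(back), roiValues(tab), tolerance = 1e-12)
  expect_equal(subjectInfo(back)$group, subjectInfo(tab)$group)
  expect_identical(normalization(back), "absolute")
})
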