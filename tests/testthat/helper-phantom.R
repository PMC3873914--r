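# shared fixture builders (all fixtures are generated in code)

# two tissue ROIs with identical kinetics plus an artery; CBF ratio 2:1
twoRoiRegions <- function(cbfA = 0.2, cbfB = 0.1, mtt = 4) {
  data.frame(
    label = 1:3, name = c("roiA", "roiB", "artery"),
    lobe = c("frontal", "parietal", "artery"),
    hemisphere = c("lh", "lh", "both"),
    tissue_class = c("cortical_gm", "cortical_gm", "artery"),
    cbf = c(cbfA, cbfB, 1), mtt = mtt, residue = "exponential",
    s0 = 100, delay = c(2, 2, 0))
}

twoRoiSpec <- function(signalNoiseSD = 0, seed = 1L, dim = c(12, 12, 4)) {
  cohortSpec(groupSizes = c(control = 1L), regions = twoRoiRegions(),
             groupEffects = list(), globalCV = 0, regionalCV = 0,
             signalNoiseSD = signalNoiseSD, dim = dim, seed = seed)
}

# full default region set but tiny grid and controllable noise
tinySpec <- function(groupSizes = c(control = 3L, MCI = 3L, AD = 3L),
                     globalCV = 45, regionalCV = 6, signalNoiseSD = 0.01,
                     groupEffects = list(AD = c(parietal_lh = 0.85,
                                                parietal_rh = 0.85,
                                                temporal_medial_rh = 1.12)),
                     seed = 1L) {
  cohortSpec(groupSizes = groupSizes, groupEffects = groupEffects,
             globalCV = globalCV, regionalCV = regionalCV,
             signalNoiseSD = signalNoiseSD, dim = c(8L, 8L, 4L), seed = seed)
}

# absolute + all three normalized tables from the ROI-level fast path
normalizedTables <- function(spec) {
  tab <- simulateCohortValues(spec)
  list(absolute = tab,
       cer = normalizeTable(tab, "cer"),
       wm = normalizeTable(tab, "wm"),
       cgm = normalizeTable(tab, "cgm"))
}

# brute-force discrete convolution oracle: tr * sum_j aif[j] * r[i-j+1]
bruteConvolve <- function(aifValues, rValues, tr) {
  n <- length(aifValues)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(i)) acc <- acc + aifValues[j] * rValues[i - j + 1]
    out[i] <- tr * acc
  }
  out
}
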