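acq <- acquisitionParams()

test_that("gamma-variate curve has the closed form, boundary and peak location", {
  gv <- gammaVariateParams(1, 3, 1.5, arrival = 5)
  # zero at and before arrival
  expect_identical(concValues(gammaVariate(c(0, 2.5, 5), gv)), c(0, 0, 0))
  # peak at t0 + alpha*beta on a dense grid
  tt <- seq(0, 30, by = 0.001)
  cc <- concValues(gammaVariate(tt, gv))
  expect_equal(tt[which.max(cc)], 5 + 3 * 1.5, tolerance = 1e-3)
  # direct evaluation of the closed form at t = 3, t0 = 0
  gv0 <- gammaVariateParams(1, 3, 1.5, arrival = 0)
  expect_equal(concValues(gammaVariate(3, gv0)), 27 * exp(-2),
               tolerance = 1e-12)
  # unimodal and continuous: single sign change of the finite difference
  d <- diff(cc[tt > 5])
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
  expect_error(gammaVariateParams(NaN, 3, 1.5), "finite")
  expect_error(gammaVariate(c(3, 1, 2), gv), class = "dscParameterError")
})

test_that("tissue forward model matches impulse response and brute-force convolution", {
  t <- timeGrid(acq)
  tr <- 1.439
  aif <- gammaVariate(t, gammaVariateParams(1.1, 3, 1.5, arrival = 10))
  # cbf = 0 gives the all-zero curve
  expect_identical(concValues(tissueConcentration(aif, 0, 4)),
                   rep(0, length(t)))
  # unit-area impulse AIF: output is cbf * exp(-t/mtt)
  imp <- concentrationCurve(t, c(1 / tr, rep(0, length(t) - 1)))
  out <- tissueConcentration(imp, 0.7, 4, "exponential")
  expect_equal(concValues(out), 0.7 * exp(-t / 4), tolerance = 1e-12)
  # boxcar residue with mtt = 2*tr against a constant AIF: hand convolution
  const <- concentrationCurve(t, rep(2, length(t)))
  out2 <- tissueConcentration(const, 0.5, 2 * tr, "boxcar")
  r <- as.numeric(t - t[1] < 2 * tr)
  expect_equal(concValues(out2), 0.5 * bruteConvolve(rep(2, length(t)), r, tr),
               tolerance = 1e-12)
  # exponential residue against the same oracle
  out3 <- tissueConcentration(aif, 0.3, 4, "exponential")
  expect_equal(concValues(out3),
               0.3 * bruteConvolve(concValues(aif), exp(-(t - t[1]) / 4), tr),
               tolerance = 1e-12)
  expect_error(tissueConcentration(aif, 0.5, -1), class = "dscParameterError")
})

test_that("signal conversion is exact at baseline and round-trips to machine precision", {
  expect_equal(concentrationToSignal(0, 100, acq), 100)
  expect_equal(concentrationToSignal(10, 100, acq), 100 * exp(-0.3),
               tolerance = 1e-14)
  set.seed(1)
  conc <- concentrationCurve(timeGrid(acq), abs(rnorm(40, 2, 1)))
  s <- concentrationToSignal(conc, 120, acq)
  back <- signalToConcentration(s, 120, acq)
  expect_lt(max(abs(concValues(back) - concValues(conc))), 1e-12)
  expect_error(concentrationToSignal(1, -5, acq), class = "dscParameterError")
})

test_that("subject generation is seed-deterministic and exact without noise", {
  spec <- tinySpec()
  s1 <- generateSubject(spec, "AD", 77)
  s2 <- generateSubject(spec, "AD", 77)
  expect_identical(s1@signal, s2@signal)
  expect_identical(s1@truth, s2@truth)
  s3 <- generateSubject(spec, "AD", 78)
  expect_false(identical(s1@signal, s3@signal))
  # all noise off: realized truth equals the spec CBF times the group effect
  spec0 <- tinySpec(globalCV = 0, regionalCV = 0, signalNoiseSD = 0)
  sAD <- generateSubject(spec0, "AD", 5)
  base <- spec0@regions$cbf[match(sAD@truth$region, spec0@regions$name)]
  mult <- ifelse(sAD@truth$region %in%
                   c("parietal_lh", "parietal_rh"), 0.85,
                 ifelse(sAD@truth$region == "temporal_medial_rh", 1.12, 1))
  expect_identical(sAD@truth$true_cbf, unname(base * mult))
})

test_that("global lognormal factor reproduces the requested CV", {
  # 500 subjects, regional noise off: region value / base CBF = global factor
  spec <- cohortSpec(groupSizes = c(control = 500L), groupEffects = list(),
                     globalCV = 45, regionalCV = 0, seed = 31L)
  tab <- simulateCohortValues(spec)
  gf <- roiValues(tab)[, "cerebellum"] / 0.30
  expect_equal(mean(gf), 1, tolerance = 0.1)
  cv <- coefficientOfVariation(gf)
  expect_gt(cv, 40); expect_lt(cv, 50)
})

test_that("combined ROI variability approaches sqrt(globalCV^2 + regionalCV^2)", {
  spec <- cohortSpec(groupSizes = c(control = 1000L), groupEffects = list(),
                     globalCV = 45, regionalCV = 6, seed = 17L)
  tab <- simulateCohortValues(spec)
  cv <- coefficientOfVariation(roiValues(tab)[, "frontal_lh"])
  expect_equal(cv, sqrt(45^2 + 6^2), tolerance = 0.1)
})

test_that("group-effect multipliers touch only the targeted regions", {
  spec <- tinySpec(globalCV = 0, regionalCV = 0, signalNoiseSD = 0,
                   groupEffects = list(AD = c(parietal_rh = 0.8)))
  tab <- simulateCohortValues(spec)
  v <- roiValues(tab); g <- subjectInfo(tab)$group
  for (rg in colnames(v)) {
    ratio <- mean(v[g == "AD", rg]) / mean(v[g == "control", rg])
    expect_equal(ratio, if (rg == "parietal_rh") 0.8 else 1,
                 tolerance = 1e-12)
  }
})

test_that("cohort generation fans out seeds deterministically", {
  spec <- tinySpec()
  co1 <- generateCohort(spec)
  co2 <- generateCohort(spec)
  expect_identical(co1$manifest, co2$manifest)
  expect_equal(nrow(co1$manifest), 9)
  expect_false(anyDuplicated(co1$manifest$seed) > 0)
  # a different cohort seed yields disjoint subject seeds
  spec2 <- tinySpec(seed = 2L)
  co3 <- generateCohort(spec2)
  expect_length(intersect(co1$manifest$seed, co3$manifest$seed), 0)
  # empty cohort is valid
  spec0 <- tinySpec(groupSizes = c(control = 0L, AD = 0L))
  co0 <- generateCohort(spec0)
  expect_equal(nrow(co0$manifest), 0)
})

test_that("the ROI-level fast path reproduces the voxel generator's truth", {
  spec <- tinySpec()
  tab <- simulateCohortValues(spec)
  co <- generateCohort(spec)
  i <- which(subjectInfo(tab)$subject_id == "AD_02")
  subj <- co$subjects[["AD_02"]]
  expect_identical(as.numeric(roiValues(tab)[i, subj@truth$region]),
                   subj@truth$true_cbf)
  expect_identical(subjectInfo(tab)$age[i], subj@age)
})

test_that("degenerate geometry is rejected as a configuration error", {
  expect_error(blockGeometry(cohortSpec(dim = c(4, 4, 2))),
               class = "dscConfigurationError")
})
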