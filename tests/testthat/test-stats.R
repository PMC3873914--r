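test_that("one-way ANOVA matches the sums-of-squares definition", {
  # identical groups: zero between-group sum of squares
  y <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  expect_equal(oneWayAnova(y, g)$F, 0)
  # well-separated groups with tiny jitter
  set.seed(2)
  y2 <- rep(0:2, each = 5) + rnorm(15, 0, 1e-4)
  expect_lt(oneWayAnova(y2, rep(c("a", "b", "c"), each = 5))$p, 1e-6)
  # brute-force oracle on random data
  set.seed(7)
  y3 <- rnorm(40); g3 <- sample(c("a", "b", "c"), 40, replace = TRUE)
  res <- oneWayAnova(y3, g3)
  gm <- mean(y3)
  ssb <- sum(tapply(y3, g3, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(y3, g3, function(x) sum((x - mean(x))^2)))
  k <- length(unique(g3)); n <- length(y3)
  Fref <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$F, Fref, tolerance = 1e-10)
  expect_equal(res$p, stats::pf(Fref, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(oneWayAnova(c(1, 2, 3), c("a", "a", "b")),
               regexp = "b", class = "dscParameterError")
})

test_that("Dunnett comparisons reduce to the pooled t-test at k = 1", {
  set.seed(11)
  y <- c(rnorm(20), rnorm(25, 0.4))
  g <- rep(c("control", "AD"), c(20, 25))
  dn <- dunnettTest(y, g, "control")
  tt <- stats::t.test(y[g == "AD"], y[g == "control"], var.equal = TRUE)
  expect_equal(dn$comparisons$p, tt$p.value, tolerance = 1e-6)
  expect_equal(dn$comparisons$t, unname(tt$statistic), tolerance = 1e-10)
})

test_that("Dunnett adjustment agrees with the multcomp reference and is conservative", {
  set.seed(3)
  y <- c(rnorm(20), rnorm(15, 0.3), rnorm(28, -0.4))
  g <- factor(rep(c("control", "MCI", "AD"), c(20, 15, 28)),
              levels = c("control", "MCI", "AD"))
  dn <- dunnettTest(y, as.character(g), "control")
  fit <- stats::aov(y ~ g)
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(dn$comparisons$p[dn$comparisons$group == "MCI"],
               unname(mc$test$pvalues[1]), tolerance = 2e-3)
  expect_equal(dn$comparisons$p[dn$comparisons$group == "AD"],
               unname(mc$test$pvalues[2]), tolerance = 2e-3)
  # adjusted p is never smaller than the unadjusted pooled t p
  for (grp in c("MCI", "AD")) {
    padj <- dn$comparisons$p[dn$comparisons$group == grp]
    tPooled <- dn$comparisons$t[dn$comparisons$group == grp]
    punadj <- 2 * stats::pt(-abs(tPooled), dn$df)
    expect_gte(padj, punadj - 1e-6)
  }
  # a treatment identical to the control gives adjusted p of 1
  y0 <- rnorm(10)
  yy <- c(y0, y0)
  gg <- rep(c("control", "tx"), each = 10)
  expect_gte(dunnettTest(yy, gg, "control")$comparisons$p, 0.99)
  expect_error(dunnettTest(y0, rep("control", 10), "control"),
               class = "dscParameterError")
})

test_that("ANOVA F is shift-invariant and CV is scale-invariant", {
  set.seed(5)
  y <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  expect_equal(oneWayAnova(y + 100, g)$F, oneWayAnova(y, g)$F,
               tolerance = 1e-9)
  x <- c(8, 10, 12)
  expect_equal(coefficientOfVariation(x), 20)
  expect_equal(coefficientOfVariation(rep(4, 10)), 0)
  expect_equal(coefficientOfVariation(3.7 * x), coefficientOfVariation(x),
               tolerance = 1e-12)
  expect_warning(expect_true(is.na(coefficientOfVariation(c(-1, 1)))),
                 "zero mean")
})

test_that("Cohen's d follows the pooled-SD definition and sign convention", {
  patient <- c(0.5, 1.5, 1, 1, 1)   # mean 1
  control <- c(-0.5, 0.5, 0, 0, 0)  # mean 0, same spread
  sp <- sqrt((4 * var(patient) + 4 * var(control)) / 8)
  expect_equal(cohensD(patient, control), 1 / sp)
  expect_equal(cohensD(control, patient), -cohensD(patient, control))
  # hypoperfusion (patient below control) gives negative d
  expect_lt(cohensD(control, patient + 1), 0)
  expect_warning(expect_true(is.na(cohensD(rep(1, 5), rep(1, 5)))),
                 "zero pooled SD")
})

test_that("variance components recover known generating variances", {
  set.seed(42)
  n <- 1000; b <- 3
  normEff <- rnorm(b, 0, 3)          # variance 9 between normalizations
  subjGroup <- rep(c("g1", "g2", "g3"), length.out = n)  # no diagnosis effect
  y <- c(); dg <- c(); nf <- c()
  for (j in seq_len(b)) {
    y <- c(y, normEff[j] + rnorm(n))  # residual variance 1
    dg <- c(dg, subjGroup)
    nf <- c(nf, rep(paste0("n", j), n))
  }
  vc <- varianceComponents(y, dg, nf)
  expect_equal(unname(varProportions(vc)["normalization"]), 0.9,
               tolerance = 0.05)
  expect_lt(varProportions(vc)["diagnosis"], 0.05)
  expect_equal(unname(varEstimates(vc)["residual"]), 1, tolerance = 0.1)
  expect_equal(sum(varProportions(vc)), 1, tolerance = 1e-9)
  # constant data: everything is zero
  vc0 <- varianceComponents(rep(2, 12), rep(c("a", "b"), 6),
                            rep(c("x", "y"), each = 6))
  expect_identical(unname(varEstimates(vc0)), c(0, 0, 0))
  # single-level factor: its component is zero with a warning
  expect_warning(vc1 <- varianceComponents(rnorm(20), rep("a", 20),
                                           rep(c("x", "y"), 10)),
                 "single diagnosis")
  expect_identical(unname(varEstimates(vc1)["diagnosis"]), 0)
})

test_that("ANCOVA group test matches the extra-sum-of-squares oracle", {
  set.seed(13)
  n <- c(20, 15, 28)
  g <- rep(c("control", "MCI", "AD"), n)
  age <- rnorm(sum(n), 73, 7)
  vol <- 150 - 0.8 * age + rep(c(0, -2, -10), n) + rnorm(sum(n), 0, 8)
  res <- ancovaVolume(vol, g, age, "control")
  gf <- factor(g, levels = c("control", "MCI", "AD"))
  rss1 <- sum(resid(lm(vol ~ gf + age))^2)
  rss0 <- sum(resid(lm(vol ~ age))^2)
  df1 <- sum(n) - 4
  Fref <- ((rss0 - rss1) / 2) / (rss1 / df1)
  expect_equal(res$F, Fref, tolerance = 1e-10)
  expect_equal(res$p, stats::pf(Fref, 2, df1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(res$ancova)
  # near-perfect separation of adjusted means
  vol2 <- 150 - 0.8 * age + rep(c(0, 40, 80), n) + rnorm(sum(n), 0, 0.5)
  expect_lt(ancovaVolume(vol2, g, age, "control")$p, 1e-6)
  # constant age falls back to plain one-way ANOVA
  expect_warning(fb <- ancovaVolume(vol, g, rep(70, sum(n)), "control"),
                 "constant age")
  expect_false(fb$ancova)
  expect_equal(fb$F, oneWayAnova(vol, g)$F, tolerance = 1e-10)
})

test_that("ANCOVA keeps its nominal type-I error under a pure age trend", {
  set.seed(99)
  n <- c(20, 15, 28)
  g <- rep(c("control", "MCI", "AD"), n)
  rej <- replicate(2000, {
    age <- rnorm(sum(n), 73, 7)
    vol <- 200 - 1.5 * age + rnorm(sum(n), 0, 5)  # no group effect
    gf <- factor(g, levels = c("control", "MCI", "AD"))
    a <- anova(lm(vol ~ age), lm(vol ~ gf + age))
    a$`Pr(>F)`[2] < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("compareAll produces complete, schema-stable report tables", {
  spec <- tinySpec(groupSizes = c(control = 6L, MCI = 5L, AD = 6L))
  tabs <- normalizedTables(spec)
  rep <- compareAll(tabs)
  gc <- rep$group_comparisons
  nCortical <- sum(regionInfo(tabs$absolute)$tissue_class == "cortical_gm")
  expect_equal(nrow(gc), nCortical * length(tabs))
  expect_true(all(c("normalization", "region", "anova_F", "anova_p",
                    "dunnett_p_MCI", "dunnett_p_AD", "cohens_d_MCI",
                    "cohens_d_AD") %in% names(gc)))
  expect_false(anyNA(gc$dunnett_p_AD))
  expect_true(all(gc$anova_p >= 0 & gc$anova_p <= 1, na.rm = TRUE))
  expect_equal(nrow(rep$bias_check), 9)  # 3 references x 3 groups
  expect_equal(nrow(rep$cv_table), 5)    # five bilateral lobes
  expect_equal(nrow(rep$variance_components), nCortical)
  # cohort mismatch is an error
  tabs2 <- tabs
  v <- roiValues(tabs2$cgm)[-1, , drop = FALSE]
  tabs2$cgm <- new("ROITable", values = v,
                   subjects = subjectInfo(tabs2$cgm)[-1, , drop = FALSE],
                   regionInfo = regionInfo(tabs2$cgm), normalization = "cgm")
  expect_error(compareAll(tabs2), class = "dscParameterError")
})
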