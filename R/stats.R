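#' @include AllClasses.R utils.R
NULL

#' One-way analysis of variance
#'
#' Classical between/within mean-square F test that mean CBF does not
#' differ across diagnostic groups.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @return list with \code{F}, \code{p}, \code{df1}, \code{df2}, and the
#'   pooled within-group \code{mse}.
#' @export
oneWayAnova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L)
    dscStop("at least two groups required", "dscParameterError")
  small <- names(which(table(g) < 2L))
  if (length(small))
    dscStop(paste("group(s) with fewer than 2 observations:",
                  paste(small, collapse = ", ")), "dscParameterError")
  a <- stats::anova(stats::lm(values ~ g))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       df1 = a$Df[1], df2 = a$Df[2], mse = a$`Mean Sq`[2])
}

# P(max_i |T_i| <= q) (sides = 2) or P(max_i T_i <= q) (sides = 1) for the
# k-variate t distribution; deterministic via a fixed local RNG state for
# the randomized Genz-Bretz quadrature.
pMaxT <- function(q, corr, df, sides = 2) {
  k <- nrow(corr)
  lower <- if (sides == 2) rep(-q, k) else rep(-Inf, k)
  withLocalSeed(271828L, as.numeric(mvtnorm::pmvt(
    lower = lower, upper = rep(q, k), df = as.integer(df), corr = corr,
    algorithm = mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 100000L))))
}

# family-wise adjusted p values for a vector of t statistics with the
# given correlation structure (shared by dunnettTest and ancovaVolume)
dunnettAdjustedP <- function(tstats, corr, df, sides = 2) {
  vapply(tstats, function(ti) {
    q <- if (sides == 2) abs(ti) else ti
    p <- 1 - pMaxT(q, corr, df, sides)
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Dunnett's many-to-one comparisons against a control group
#'
#' For each treatment group \eqn{i}, computes
#' \eqn{t_i = (\bar y_i - \bar y_0)/\sqrt{MSE\,(1/n_i + 1/n_0)}} with the
#' MSE pooled over all groups, and adjusts for the family of \eqn{k}
#' comparisons using the k-variate t distribution with correlations
#' \eqn{\rho_{ij} = \sqrt{n_i n_j/((n_i+n_0)(n_j+n_0))}}, evaluated by
#' deterministic (seeded) quadrature.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @param control name of the control group (default: first encountered).
#' @param sides 2 (default) for two-sided p values, 1 for one-sided
#'   (greater).
#' @return list with \code{comparisons} (data.frame: group, n, estimate, t,
#'   p), \code{df}, \code{mse}, \code{control}.
#' @examples
#' set.seed(1)
#' y <- c(rnorm(10), rnorm(10, 1), rnorm(10, 2))
#' g <- rep(c("control", "MCI", "AD"), each = 10)
#' dunnettTest(y, g)$comparisons
#' @export
dunnettTest <- function(values, groups, control = NULL, sides = 2) {
  groups <- as.character(groups)
  if (is.null(control)) control <- groups[1]
  if (!control %in% groups)
    dscStop(paste("control group not found:", control), "dscParameterError")
  lev <- c(control, setdiff(unique(groups), control))
  k <- length(lev) - 1L
  if (k < 1L) dscStop("no treatment group to compare", "dscParameterError")
  g <- factor(groups, levels = lev)
  small <- names(which(table(g) < 2L))
  if (length(small))
    dscStop(paste("group(s) with fewer than 2 observations:",
                  paste(small, collapse = ", ")), "dscParameterError")
  n <- as.numeric(table(g))
  means <- tapply(values, g, mean)
  sse <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  df <- length(values) - length(lev)
  mse <- sse / df
  est <- means[-1] - means[1]
  se <- sqrt(mse * (1 / n[-1] + 1 / n[1]))
  tstat <- as.numeric(est / se)
  corr <- diag(1, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    corr[i, j] <- sqrt(n[i + 1] * n[j + 1] /
                         ((n[i + 1] + n[1]) * (n[j + 1] + n[1])))
  p <- dunnettAdjustedP(tstat, corr, df, sides)
  list(comparisons = data.frame(group = lev[-1], n = n[-1],
                                estimate = as.numeric(est), t = tstat, p = p),
       df = df, mse = mse, control = control)
}

#' Cohen's d effect size
#'
#' Standardized mean difference \eqn{(\bar y_p - \bar y_c)/s_{pooled}}
#' between a patient group and the control group, with
#' \eqn{s_{pooled}^2 = ((n_p-1)s_p^2 + (n_c-1)s_c^2)/(n_p+n_c-2)}.
#' Negative d means the patient group is lower than controls.
#'
#' @param patient,control numeric vectors with at least two observations
#'   each.
#' @return d, or \code{NA} with a warning when the pooled SD is zero.
#' @export
cohensD <- function(patient, control) {
  np <- length(patient); nc <- length(control)
  if (np < 2L || nc < 2L)
    dscStop("both groups need at least 2 observations", "dscParameterError")
  sp <- sqrt(((np - 1) * stats::var(patient) + (nc - 1) * stats::var(control)) /
               (np + nc - 2))
  if (sp == 0) {
    warning("zero pooled SD: effect size undefined")
    return(NA_real_)
  }
  (mean(patient) - mean(control)) / sp
}

#' Coefficient of variation
#'
#' \eqn{100 \cdot s / \bar y} in percent, the study's measure of
#' inter-subject intensity variability; invariant to positive rescaling.
#'
#' @param values numeric vector.
#' @return CV in percent, or \code{NA} with a warning when the mean is 0.
#' @export
coefficientOfVariation <- function(values) {
  m <- mean(values)
  if (m == 0) {
    warning("zero mean: CV undefined")
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

#' Two-way random-effects variance components
#'
#' Method-of-moments estimates of the variance attributable to the
#' diagnosis group, the normalization method, and residual (intra-group)
#' variation, from the expected mean squares of the two-way random-effects
#' ANOVA. The layout is crossed (every subject is observed under every
#' normalization) and may be unbalanced in the diagnosis factor; EMS
#' coefficients use the standard unbalanced one-way form
#' \eqn{c = (M - \sum m_i^2/M)/(a-1)} over observation counts \eqn{m_i}.
#' Negative moment estimates are truncated to 0.
#'
#' @param values numeric response (stacked over normalizations).
#' @param diagnosis diagnosis-group factor, same length.
#' @param normalization normalization-method factor, same length.
#' @param interaction include a diagnosis-by-normalization interaction
#'   component (default \code{FALSE}).
#' @return A [VarianceComponents-class] object.
#' @export
varianceComponents <- function(values, diagnosis, normalization,
                               interaction = FALSE) {
  A <- factor(diagnosis); B <- factor(normalization)
  if (stats::var(values) == 0) {
    # constant data: every component is exactly zero
    z <- c(diagnosis = 0, normalization = 0, residual = 0)
    if (interaction) z <- c(z[1:2], interaction = 0, residual = 0)
    return(new("VarianceComponents", variances = z, proportions = z))
  }
  emsCoef <- function(f) {
    m <- as.numeric(table(f)); M <- sum(m)
    (M - sum(m^2) / M) / (length(m) - 1)
  }
  singleA <- nlevels(A) < 2L; singleB <- nlevels(B) < 2L
  if (singleA) warning("single diagnosis level: its component set to 0")
  if (singleB) warning("single normalization level: its component set to 0")
  if (singleA && singleB) {
    v <- c(diagnosis = 0, normalization = 0,
           residual = max(stats::var(values), 0))
  } else if (singleA || singleB) {
    f <- if (singleA) B else A
    a <- stats::anova(stats::lm(values ~ f))
    comp <- max((a$`Mean Sq`[1] - a$`Mean Sq`[2]) / emsCoef(f), 0)
    res <- a$`Mean Sq`[2]
    v <- if (singleA) c(diagnosis = 0, normalization = comp, residual = res)
         else c(diagnosis = comp, normalization = 0, residual = res)
  } else if (!interaction) {
    a <- stats::anova(stats::lm(values ~ A + B))
    mse <- a$`Mean Sq`[3]
    v <- c(diagnosis = max((a$`Mean Sq`[1] - mse) / emsCoef(A), 0),
           normalization = max((a$`Mean Sq`[2] - mse) / emsCoef(B), 0),
           residual = mse)
  } else {
    a <- stats::anova(stats::lm(values ~ A * B))
    mse <- a$`Mean Sq`[4]
    msab <- a$`Mean Sq`[3]
    cells <- as.numeric(table(A, B))
    nh <- length(cells) / sum(1 / cells)  # harmonic mean cell count
    vab <- max((msab - mse) / nh, 0)
    v <- c(diagnosis = max((a$`Mean Sq`[1] - msab) / emsCoef(A), 0),
           normalization = max((a$`Mean Sq`[2] - msab) / emsCoef(B), 0),
           interaction = vab, residual = mse)
  }
  v[!is.finite(v)] <- 0
  tot <- sum(v)
  p <- if (tot > 0) v / tot else v * 0
  new("VarianceComponents", variances = v, proportions = p)
}

#' ANCOVA of regional volumes with age as covariate
#'
#' Fits \code{volume ~ group + age}, tests the group effect by the
#' extra-sum-of-squares F against the age-only model, and compares the
#' age-adjusted group means against the control with Dunnett-type
#' family-wise adjustment using the model's residual MSE and coefficient
#' covariance. If age is constant (or collinear), falls back to a plain
#' one-way ANOVA with a warning.
#'
#' @param volumes numeric response vector.
#' @param groups group labels, same length.
#' @param ages numeric covariate, same length.
#' @param control control group name (default: first encountered).
#' @param sides 1 or 2 (default 2).
#' @return list with \code{F}, \code{p}, \code{df}, \code{comparisons}
#'   (data.frame: group, estimate, t, p), and \code{ancova} (logical:
#'   \code{FALSE} when the fallback was used).
#' @export
ancovaVolume <- function(volumes, groups, ages, control = NULL, sides = 2) {
  groups <- as.character(groups)
  if (is.null(control)) control <- groups[1]
  stopifnot(length(volumes) == length(groups),
            length(volumes) == length(ages))
  if (stats::sd(ages) == 0) {
    warning("constant age covariate: falling back to one-way ANOVA")
    aov1 <- oneWayAnova(volumes, groups)
    dn <- dunnettTest(volumes, groups, control, sides)
    return(list(F = aov1$F, p = aov1$p, df = aov1$df2,
                comparisons = dn$comparisons[, c("group", "estimate", "t", "p")],
                ancova = FALSE))
  }
  g <- factor(groups, levels = c(control, setdiff(unique(groups), control)))
  fit1 <- stats::lm(volumes ~ g + ages)
  fit0 <- stats::lm(volumes ~ ages)
  cmp <- stats::anova(fit0, fit1)
  Fg <- cmp$F[2]; pg <- cmp$`Pr(>F)`[2]
  ix <- grep("^g", names(stats::coef(fit1)))
  est <- stats::coef(fit1)[ix]
  V <- stats::vcov(fit1)[ix, ix, drop = FALSE]
  tstat <- as.numeric(est / sqrt(diag(V)))
  corr <- stats::cov2cor(V)
  df <- stats::df.residual(fit1)
  p <- dunnettAdjustedP(tstat, corr, df, sides)
  list(F = Fg, p = pg, df = df,
       comparisons = data.frame(group = levels(g)[-1],
                                estimate = as.numeric(est), t = tstat, p = p),
       ancova = TRUE)
}

# per-subject bilateral lobe values: hemispheres averaged within each lobe
bilateralLobeValues <- function(table) {
  ri <- regionInfo(table)
  v <- roiValues(table)
  cols <- which(ri$tissue_class == "cortical_gm")
  lobes <- unique(ri$lobe[cols])
  out <- vapply(lobes, function(lb)
    rowMeans(v[, cols[ri$lobe[cols] == lb], drop = FALSE]),
    numeric(nrow(v)))
  if (nrow(v) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, lobes))
  out
}

#' Full group-level comparison across normalizations
#'
#' Runs the study's statistical framework on one cohort: (a) the
#' reference-region bias check (per-group mean/SD/CV of each candidate
#' reference value, with one-way ANOVA across groups); (b) per-region group
#' comparisons (ANOVA, Dunnett p vs control, Cohen's d) for the absolute
#' values and each normalization; (c) the pooled coefficient-of-variation
#' table (bilateral lobes x normalization, all groups pooled); and (d) the
#' per-region variance-components decomposition over the normalized tables.
#' Dunnett p values and effect sizes are reported for every region;
#' following the source framework, no correction is applied across regions
#' beyond Dunnett's within-region family.
#'
#' @param tables named list of [ROITable-class] objects; must contain
#'   \code{absolute} plus any of \code{cer}, \code{wm}, \code{cgm}, all on
#'   the identical cohort.
#' @param control control group name (default: first group of the absolute
#'   table).
#' @param sides sidedness of the Dunnett comparisons (default 2).
#' @param interaction passed to [varianceComponents()].
#' @return list of data.frames: \code{bias_check},
#'   \code{group_comparisons}, \code{cv_table}, \code{variance_components}.
#' @export
compareAll <- function(tables, control = NULL, sides = 2,
                       interaction = FALSE) {
  if (!"absolute" %in% names(tables))
    dscStop("tables must include an 'absolute' entry", "dscParameterError")
  absTab <- tables$absolute
  ids <- subjectInfo(absTab)$subject_id
  for (nm in names(tables)) {
    if (!identical(sort(subjectInfo(tables[[nm]])$subject_id), sort(ids)))
      dscStop(paste("cohort mismatch between tables: ", nm),
              "dscParameterError")
  }
  groups <- subjectInfo(absTab)$group
  if (is.null(control)) control <- groups[1]
  patientGroups <- setdiff(unique(groups), control)

  # (a) reference-region bias check on the absolute table
  bias <- list()
  for (ref in c("cgm", "cer", "wm")) {
    rv <- referenceValue(absTab, ref)
    av <- oneWayAnova(rv, groups)
    for (g in unique(groups)) {
      x <- rv[groups == g]
      bias[[length(bias) + 1L]] <- data.frame(
        reference = ref, group = g, n = length(x), mean = mean(x),
        sd = stats::sd(x), cv = coefficientOfVariation(x),
        anova_F = av$F, anova_p = av$p)
    }
  }
  biasDf <- do.call(rbind, bias)

  # (b) per-region comparisons, one row per (normalization, region)
  comp <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    ri <- regionInfo(tab)
    v <- roiValues(tab)
    gv <- subjectInfo(tab)$group
    for (rg in ri$region[ri$tissue_class == "cortical_gm"]) {
      y <- v[, rg]
      av <- oneWayAnova(y, gv)
      dn <- dunnettTest(y, gv, control, sides)
      row <- data.frame(normalization = nm, region = rg,
                        anova_F = av$F, anova_p = av$p,
                        mean_control = mean(y[gv == control]),
                        sd_control = stats::sd(y[gv == control]))
      for (pg in patientGroups) {
        row[[paste0("mean_", pg)]] <- mean(y[gv == pg])
        row[[paste0("sd_", pg)]] <- stats::sd(y[gv == pg])
        row[[paste0("dunnett_p_", pg)]] <-
          dn$comparisons$p[dn$comparisons$group == pg]
        row[[paste0("cohens_d_", pg)]] <-
          cohensD(y[gv == pg], y[gv == control])
      }
      comp[[length(comp) + 1L]] <- row
    }
  }
  compDf <- do.call(rbind, comp)

  # (c) pooled CV per bilateral lobe x normalization
  lobeList <- lapply(tables, bilateralLobeValues)
  lobes <- colnames(lobeList[[1]])
  cvDf <- data.frame(lobe = lobes)
  for (nm in names(tables))
    cvDf[[paste0("cv_", nm)]] <- apply(lobeList[[nm]], 2,
                                       coefficientOfVariation)

  # (d) variance components over the normalized tables
  normNames <- intersect(c("cer", "wm", "cgm"), names(tables))
  vcList <- list()
  if (length(normNames) >= 1L) {
    ri <- regionInfo(absTab)
    for (rg in ri$region[ri$tissue_class == "cortical_gm"]) {
      y <- unlist(lapply(normNames, function(nm)
        roiValues(tables[[nm]])[, rg]), use.names = FALSE)
      dg <- rep(subjectInfo(absTab)$group, length(normNames))
      nf <- rep(normNames, each = length(ids))
      vc <- suppressWarnings(
        varianceComponents(y, dg, nf, interaction = interaction))
    pr <- varProportions(vc); va <- varEstimates(vc)
      vcList[[length(vcList) + 1L]] <- data.frame(
        region = rg, var_diagnosis = va[["diagnosis"]],
        var_normalization = va[["normalization"]],
        var_residual = va[["residual"]],
        prop_diagnosis = pr[["diagnosis"]],
        prop_normalization = pr[["normalization"]],
        prop_residual = pr[["residual"]])
    }
  }
  vcDf <- if (length(vcList)) do.call(rbind, vcList) else
    data.frame(region = character())

  list(bias_check = biasDf, group_comparisons = compDf, cv_table = cvDf,
       variance_components = vcDf)
}

#' Write the comparison report tables
#'
#' Writes \code{bias_check.tsv}, \code{group_comparisons.tsv},
#' \code{cv_table.tsv}, \code{variance_components.tsv} and a JSON run
#' metadata file into \code{dir}.
#'
#' @param report result of [compareAll()].
#' @param dir output directory.
#' @param metadata named list written as \code{run_metadata.json}.
#' @return Invisibly, the paths written.
#' @export
writeReports <- function(report, dir, metadata = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("bias_check", "group_comparisons", "cv_table",
               "variance_components")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(report[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(metadata, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}
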