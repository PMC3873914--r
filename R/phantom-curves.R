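#' @include AllClasses.R
NULL

#' Evaluate a gamma-variate bolus curve
#'
#' Computes \eqn{C(t) = K (t-t_0)^{\alpha} e^{-(t-t_0)/\beta}} for
#' \eqn{t > t_0}, 0 otherwise: the standard parametric model of a
#' first-pass contrast bolus. The curve is continuous, unimodal, and peaks
#' at \eqn{t_0 + \alpha\beta}.
#'
#' @param t sorted, nonnegative time grid, seconds.
#' @param params a [GammaVariateParams-class] object.
#' @return A [ConcentrationCurve-class] sampled on \code{t}.
#' @examples
#' acq <- acquisitionParams()
#' gv <- gammaVariateParams(1.1, 3, 1.5, arrival = 10)
#' aif <- gammaVariate(timeGrid(acq), gv)
#' @export
gammaVariate <- function(t, params) {
  stopifnot(is(params, "GammaVariateParams"))
  validObject(params)
  t <- as.numeric(t)
  if (any(!is.finite(t)) || is.unsorted(t) || any(t < 0))
    dscStop("t must be a sorted, nonnegative, finite time grid",
            "dscParameterError")
  dt <- t - params@arrival
  conc <- numeric(length(t))
  up <- dt > 0
  conc[up] <- params@amplitude * dt[up]^params@shape * exp(-dt[up] / params@scale)
  concentrationCurve(t, conc)
}

# peak height of the gamma-variate curve, K*(alpha*beta)^alpha*exp(-alpha)
gammaVariatePeak <- function(params) {
  params@amplitude * (params@shape * params@scale)^params@shape *
    exp(-params@shape)
}

# full width at half maximum of the fitted curve, found on a dense grid
gammaVariateFWHM <- function(params, tmax = NULL) {
  if (is.null(tmax))
    tmax <- params@arrival + params@shape * params@scale * 8
  tt <- seq(params@arrival, tmax, length.out = 2048)
  cc <- concValues(gammaVariate(tt, params))
  half <- max(cc) / 2
  above <- which(cc >= half)
  tt[above[length(above)]] - tt[above[1]]
}

# residue function R(t): R(0) = 1, nonincreasing
residueFunction <- function(t, mtt, model = c("exponential", "boxcar")) {
  model <- match.arg(model)
  if (!is.finite(mtt) || mtt <= 0)
    dscStop("mtt must be > 0", "dscParameterError")
  switch(model,
         exponential = exp(-t / mtt),
         boxcar = as.numeric(t < mtt))
}

# Lower-triangular Toeplitz convolution matrix: A[i, j] = tr * aif[i - j + 1]
# for i >= j. Shared by the forward model and the SVD deconvolution.
convolutionMatrix <- function(aifValues, tr) {
  n <- length(aifValues)
  A <- matrix(0, n, n)
  for (j in seq_len(n))
    A[j:n, j] <- tr * aifValues[seq_len(n - j + 1)]
  A
}

#' Forward model: tissue concentration from an AIF
#'
#' Generates the measurable tissue concentration
#' \eqn{C_m(t) = \mathrm{CBF}\,(AIF \circledast R)(t)} by discrete
#' convolution on the frame grid (step TR) with a residue function
#' \eqn{R(t)} satisfying \eqn{R(0) = 1} and nonincreasing: exponential
#' \eqn{e^{-t/\mathrm{MTT}}} or boxcar (1 for \eqn{t < \mathrm{MTT}}).
#' An optional arrival delay shifts the input by a whole number of frames,
#' modelling tissue bolus arrival after the feeding artery.
#'
#' @param aif arterial input as a [ConcentrationCurve-class] on a uniform
#'   grid.
#' @param cbf cerebral blood flow, relative units; nonnegative.
#' @param mtt mean transit time, seconds; positive.
#' @param residueModel \code{"exponential"} or \code{"boxcar"}.
#' @param delay arrival delay, seconds; rounded to the nearest whole frame.
#' @return A [ConcentrationCurve-class] on the same grid.
#' @export
tissueConcentration <- function(aif, cbf, mtt,
                                residueModel = c("exponential", "boxcar"),
                                delay = 0) {
  stopifnot(is(aif, "ConcentrationCurve"))
  residueModel <- match.arg(residueModel)
  if (!is.finite(mtt) || mtt <= 0)
    dscStop("mtt must be > 0", "dscParameterError")
  if (!is.finite(cbf) || cbf < 0)
    dscStop("cbf must be >= 0", "dscParameterError")
  t <- timeGrid(aif)
  n <- length(t)
  tr <- if (n > 1) t[2] - t[1] else 1
  av <- concValues(aif)
  if (delay > 0) {
    shift <- as.integer(round(delay / tr))
    if (shift > 0)
      av <- c(numeric(min(shift, n)), av)[seq_len(n)]
  }
  R <- residueFunction(t - t[1], mtt, residueModel)
  conc <- cbf * as.numeric(convolutionMatrix(av, tr) %*% R)
  concentrationCurve(t, conc)
}

#' Convert tracer concentration to MR signal
#'
#' Inverse of the DSC concentration relation:
#' \eqn{S(t) = S_0\, e^{-TE\, C(t) / k}}. With \eqn{C = 0} the signal is the
#' baseline \eqn{S_0}; the signal decreases monotonically in concentration.
#' Round-trips with [signalToConcentration()] to machine precision.
#'
#' @param conc a [ConcentrationCurve-class] or numeric vector of
#'   concentrations.
#' @param s0 baseline signal; positive.
#' @param acq an [AcquisitionParams-class] object.
#' @return Numeric vector of signal values.
#' @export
concentrationToSignal <- function(conc, s0, acq) {
  stopifnot(is(acq, "AcquisitionParams"))
  if (!is.finite(s0) || s0 <= 0)
    dscStop("s0 must be > 0", "dscParameterError")
  c <- if (is(conc, "ConcentrationCurve")) concValues(conc) else as.numeric(conc)
  s0 * exp(-acq@te * c / acq@k)
}
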