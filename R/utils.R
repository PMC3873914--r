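# internal helpers shared across modules

# Deterministic per-subject / per-stage seed fan-out. Large odd multiplier
# spreads consecutive indices; result kept strictly below 2^31.
deriveSeed <- function(seed, index) {
  s <- (as.double(seed) + 1000003 * as.double(index)) %% 2147483629
  as.integer(s)
}

# sigma of a mean-1 lognormal with the given coefficient of variation (%)
lognormSigma <- function(cvPercent) {
  sqrt(log(1 + (cvPercent / 100)^2))
}

# draw n mean-1 lognormal multipliers with the given CV (%)
rLognormFactor <- function(n, cvPercent) {
  if (cvPercent == 0) return(rep(1, n))
  s <- lognormSigma(cvPercent)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# Evaluate an expression under a fixed RNG state without disturbing the
# caller's stream (used to make quadrature-based p values deterministic).
withLocalSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# stop() with a class so callers/tests can target specific failure modes
dscStop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
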