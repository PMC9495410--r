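# Fixture builders used across the suite.

# Single gene with a constant activation level: alpha identical for both
# promoter states, so f == level for every abundance.
constantGene <- function(level = 0.6, m = 1e-3, delta = 2e-4, s = 0.05,
                         gamma = 5e-3, x0 = 5, y0 = 50) {
  tfParams(1, m = m, delta = delta, s = s, gamma = gamma, x0 = x0, y0 = y0,
           k = 500, h = 2, alpha = level, r = numeric(0))
}

# Closed-form solution of the constant-f single-gene linear system
# (per-day rates), x' = M c - D x, y' = S x - G y.
constantGeneClosedForm <- function(params, level, t) {
  M <- params@m[1] * 86400; D <- params@delta[1] * 86400
  S <- params@s[1] * 86400; G <- params@gamma[1] * 86400
  xs <- M * level / D
  x <- xs + (params@x0[1] - xs) * exp(-D * t)
  ys <- S * xs / G
  # particular + homogeneous response of y to the exponential x transient
  A <- S * (params@x0[1] - xs) / (G - D)
  y <- ys + A * exp(-D * t) + (params@y0[1] - ys - A) * exp(-G * t)
  list(x = x, y = y)
}

# A trajectory object built directly from closed-form curves.
makeTrajectory <- function(times, y, x = NULL, n = 1) {
  ym <- if (is.matrix(y)) y else matrix(y, ncol = n)
  xm <- if (is.null(x)) ym * 0 else if (is.matrix(x)) x else matrix(x, ncol = n)
  new("Trajectory", times = times, x = xm, y = ym,
      light = rep(0, length(times)))
}

# Random in-bounds parameter draws for property tests.
randomInBounds <- function(n, seed) initParams(n, seed = seed, perturbSd = 0.3)
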