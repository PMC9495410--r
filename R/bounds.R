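#' @include AllClasses.R
NULL

PARAM_FAMILIES <- c("m", "delta", "s", "gamma", "k", "h", "alpha", "r", "x0", "y0")

#' Biological parameter bounds
#'
#' Default lower/upper bounds per parameter family, chosen to be roughly
#' compatible with realistic single-cell value ranges: rates per second,
#' abundances in molecules per cell, `h`, `alpha`, `r` dimensionless. The
#' rate bounds imply mRNA abundances of order (0, 1e2) and TF protein
#' abundances of order (0, 1e3), which are used as the initial-condition
#' bounds.
#'
#' @return A 10 x 2 numeric matrix with rownames `m, delta, s, gamma, k, h,
#'   alpha, r, x0, y0` and columns `lower`, `upper`.
#' @examples
#' defaultBounds()
#' @export
defaultBounds <- function() {
  b <- rbind(m     = c(1e-4, 1e-2),
             delta = c(1e-4, 1e-2),
             s     = c(1e-3, 1),
             gamma = c(1e-3, 1),
             k     = c(1e2, 1e4),
             h     = c(0, 5),
             alpha = c(0, 1),
             r     = c(0, 10),
             x0    = c(0, 1e2),
             y0    = c(0, 1e3))
  colnames(b) <- c("lower", "upper")
  b
}

checkBoundsMatrix <- function(bounds) {
  if (!is.matrix(bounds) || ncol(bounds) != 2 ||
      !all(PARAM_FAMILIES %in% rownames(bounds)))
    stop("bounds must be a matrix with rows ", paste(PARAM_FAMILIES, collapse = ", "),
         " and columns lower, upper")
  if (any(bounds[, 1] >= bounds[, 2]))
    stop("every lower bound must be strictly below its upper bound")
  invisible(bounds)
}

#' Sigmoid squash specification
#'
#' The bounded-parameter transform maps an unbounded optimization value p to
#' (0, 1): it is the identity on the interior `[d, 1 - d]` and bends into
#' logistic tails outside, with constants `k1 = d (1 + exp(-10 d))` and
#' `k2 = 10 (1 - d) + log(d / (1 - d))` chosen so the pieces join continuously
#' at `d` and `1 - d`.
#'
#' @param d boundary-layer width, `0 < d < 0.5` (default 0.01).
#' @return List with elements `d`, `k1`, `k2`.
#' @seealso [squash()], [unsquash()]
#' @export
squashSpec <- function(d = 0.01) {
  if (!is.numeric(d) || length(d) != 1 || d <= 0 || d >= 0.5)
    stop("d must lie strictly between 0 and 0.5")
  list(d = d,
       k1 = d * (1 + exp(-10 * d)),
       k2 = 10 * (1 - d) + log(d / (1 - d)))
}

#' Squash an unbounded value into (0, 1)
#'
#' Piecewise sigmoid: `k1 / (1 + exp(-10 p))` for `p < d`,
#' `1 / (1 + exp(-10 p + k2))` for `p > 1 - d`, and `p` itself in between.
#' Monotone, continuous, and the identity on `[d, 1 - d]`, so that optimizer
#' values well inside the range pass through untouched while values outside
#' saturate smoothly.
#'
#' @param p numeric vector of unbounded values.
#' @param spec a [squashSpec()].
#' @return Values strictly in (0, 1).
#' @examples
#' squash(c(-5, 0.5, 5))
#' @export
squash <- function(p, spec = squashSpec()) {
  lo <- p < spec$d
  hi <- p > 1 - spec$d
  out <- p
  out[lo] <- spec$k1 * stats::plogis(10 * p[lo])
  out[hi] <- stats::plogis(10 * p[hi] - spec$k2)
  # keep the output inside the open interval even for extreme arguments
  pmin(pmax(out, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Derivative of the squash transform
#' @inheritParams squash
#' @return d squash / d p, elementwise.
#' @export
squashDeriv <- function(p, spec = squashSpec()) {
  lo <- p < spec$d
  hi <- p > 1 - spec$d
  out <- rep_len(1, length(p))
  q <- stats::plogis(10 * p[lo])
  out[lo] <- spec$k1 * 10 * q * (1 - q)
  q <- stats::plogis(10 * p[hi] - spec$k2)
  out[hi] <- 10 * q * (1 - q)
  out
}

#' Invert the squash transform
#'
#' Maps theta in (0, 1) back to the unbounded optimization scale, so that
#' parameters chosen inside their biological range can be stored for
#' unconstrained optimization.
#'
#' @param theta numeric vector strictly inside (0, 1).
#' @inheritParams squash
#' @return Unbounded values p with `squash(p) == theta`.
#' @export
unsquash <- function(theta, spec = squashSpec()) {
  if (any(theta <= 0 | theta >= 1)) stop("theta must lie strictly inside (0, 1)")
  lo <- theta < spec$d
  hi <- theta > 1 - spec$d
  out <- theta
  out[lo] <- -log(spec$k1 / theta[lo] - 1) / 10
  out[hi] <- (spec$k2 - log(1 / theta[hi] - 1)) / 10
  out
}
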