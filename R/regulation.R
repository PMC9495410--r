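#' @include params.R
NULL

#' TF binding intensity
#'
#' `v = (y / k)^h`: activation intensity of a TF at abundance y relative to
#' its promoter dissociation constant k, reshaped by the Hill coefficient h.
#' `v = 1` at `y = k`; `h = 0` gives a constant intensity of 1.
#'
#' @param y protein abundance (molecules/cell), nonnegative.
#' @param k dissociation constant (molecules/cell), positive.
#' @param h Hill coefficient, nonnegative.
#' @return Nonnegative intensity.
#' @export
intensity <- function(y, k, h) {
  if (any(y < 0)) stop("protein abundance y must be nonnegative")
  if (any(k <= 0)) stop("dissociation constant k must be positive")
  if (any(h < 0)) stop("Hill coefficient h must be nonnegative")
  ifelse(h == 0, 1, (y / k)^h)
}

#' Single-TF activation
#'
#' Thermodynamic occupancy form `f = (alpha0 + alpha1 v) / (1 + v)`:
#' a weighted average of the unbound (`alpha0`) and bound (`alpha1`)
#' expression levels.
#'
#' @param alpha0,alpha1 expression weights in `[0, 1]` for the unbound and
#'   bound promoter states.
#' @param v nonnegative binding intensity, see [intensity()].
#' @return f in `[min(alpha0, alpha1), max(alpha0, alpha1)]`.
#' @export
activationSingle <- function(alpha0, alpha1, v) {
  (alpha0 + alpha1 * v) / (1 + v)
}

#' Two-TF activation
#'
#' `f = (a0 + a1 v1 + a2 v2 + a3 r v1 v2) / (1 + v1 + v2 + r v1 v2)`, where
#' `r` weights the doubly bound promoter state (synergy between the TFs).
#'
#' @param alpha length-4 expression weights in bitmask order: none, TF1, TF2,
#'   both.
#' @param r synergy weight (> 0).
#' @param v1,v2 nonnegative binding intensities.
#' @return f in `[min(alpha), max(alpha)]`.
#' @export
activationPair <- function(alpha, r, v1, v2) {
  (alpha[1] + alpha[2] * v1 + alpha[3] * v2 + alpha[4] * r * v1 * v2) /
    (1 + v1 + v2 + r * v1 * v2)
}

# 2^n x n subset incidence matrix (row mask+1 marks the TFs in mask)
maskIncidence <- function(n) {
  masks <- 0:(2L^n - 1L)
  sapply(seq_len(n), function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L)
}

#' General n-TF activation for one gene
#'
#' Expands the thermodynamic occupancy model over all 2^n bound-TF subsets S:
#' `f = sum_S alpha_S w_S / sum_S w_S` with `w_S = r_S prod_{j in S} v_j`,
#' `v_j = (y_j / k_j)^{h_j}`, and `r_S = 1` for subsets of size <= 1. Weights
#' are evaluated in log space and rescaled by the maximum weight, so extreme
#' intensities (`v` up to 1e15 per TF) cannot overflow.
#'
#' @param y length-n protein abundances.
#' @param k,h length-n dissociation constants / Hill coefficients for this
#'   gene's promoter (one entry per input TF).
#' @param alpha length-2^n expression weights, ascending bitmask order.
#' @param r length-(2^n - n - 1) synergy weights for subsets of size >= 2,
#'   ascending bitmask order.
#' @return Scalar f in `[min(alpha), max(alpha)]`.
#' @examples
#' activationGeneral(y = c(500, 800), k = c(500, 500), h = c(2, 2),
#'                   alpha = c(0, 0, 0, 1), r = 2)
#' @export
activationGeneral <- function(y, k, h, alpha, r = numeric(0)) {
  n <- length(y)
  if (any(y < 0)) stop("protein abundances must be nonnegative")
  nm <- 2L^n
  stopifnot(length(k) == n, length(h) == n, length(alpha) == nm,
            length(r) == nm - n - 1L)
  lv <- ifelse(h == 0, 0, ifelse(y <= 0, -Inf, h * (log(y) - log(k))))
  inc <- maskIncidence(n)
  lw <- as.vector(inc %*% ifelse(is.finite(lv), lv, 0))
  # subsets containing a zero-intensity TF have weight zero
  dead <- as.vector(inc %*% as.numeric(!is.finite(lv))) > 0
  lw[dead] <- -Inf
  rc <- rColIndex(n)
  lw[rc >= 0] <- lw[rc >= 0] + log(r[rc[rc >= 0] + 1L])
  w <- exp(lw - max(lw))
  sum(alpha * w) / sum(w)
}

# activation of every gene for a circuit parameter set
activationAll <- function(params, y) {
  n <- params@n
  vapply(seq_len(n), function(i)
    activationGeneral(y, params@k[i, ], params@h[i, ],
                      params@alpha[i, ], params@r[i, ]),
    numeric(1))
}

#' TF input-output logic surface
#'
#' Evaluates the activation function of one gene over a grid of TF abundance
#' combinations, producing the mRNA generation-rate multiplier surface
#' (0 = complete repression, 1 = maximum production).
#'
#' @param params a [TFParams-class].
#' @param outputGene gene index whose promoter logic is evaluated.
#' @param grids list of length n of abundance vectors (molecules/cell), one
#'   per input TF; the full outer grid is evaluated.
#' @return data.frame with abundance columns `p1 ... pn` and the activation
#'   `f`, one row per grid point (long format, suitable for CSV export).
#' @export
logicSurface <- function(params, outputGene = 1L, grids) {
  n <- params@n
  if (outputGene < 1 || outputGene > n) stop("outputGene out of range")
  if (!is.list(grids) || length(grids) != n)
    stop("grids must be a list with one abundance vector per TF")
  gd <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(gd) <- paste0("p", seq_len(n))
  Y <- as.matrix(gd)
  f <- cpp_activation_grid(n, Y, params@k[outputGene, ], params@h[outputGene, ],
                           params@alpha[outputGene, ], params@r[outputGene, ],
                           rColIndex(n))
  gd$f <- f
  gd
}
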