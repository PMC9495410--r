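#' @include tfcircuit-package.R
NULL

#' TF circuit parameter set
#'
#' Structured, bounds-aware parameter set for an n-TF circuit. Rates are
#' stored per second (the units the biological bounds are quoted in) and are
#' converted to per-day inside the simulators. Slot conventions:
#'
#' * `m`, `delta`: maximum mRNA production and mRNA decay rates (per second).
#' * `s`, `gamma`: protein production (per mRNA) and protein decay rates.
#' * `x0`, `y0`: initial mRNA and protein abundances (molecules/cell).
#' * `k`, `h`: n x n dissociation constants and Hill coefficients; entry
#'   `[i, j]` describes binding of TF j to the promoter of gene i.
#' * `alpha`: n x 2^n expression weights in `[0, 1]`; column `mask + 1` is the
#'   weight of the promoter state in which exactly the TFs in bitmask `mask`
#'   are bound (bit j-1 = TF j); column 1 (empty mask) is the basal weight.
#' * `r`: n x (2^n - n - 1) synergy weights, one per bound-TF subset of size
#'   >= 2, columns in ascending bitmask order; subsets of size <= 1 have an
#'   implied weight of 1.
#'
#' @slot n integer, number of TFs.
#' @slot m,delta,s,gamma numeric length-n per-second rates.
#' @slot x0,y0 numeric length-n initial abundances.
#' @slot k,h numeric n x n matrices.
#' @slot alpha numeric n x 2^n matrix.
#' @slot r numeric n x (2^n - n - 1) matrix.
#' @seealso [tfParams()], [initParams()], [decodeParams()], [encodeParams()]
#' @export
setClass("TFParams",
  representation(n = "integer",
                 m = "numeric", delta = "numeric",
                 s = "numeric", gamma = "numeric",
                 x0 = "numeric", y0 = "numeric",
                 k = "matrix", h = "matrix",
                 alpha = "matrix", r = "matrix"))

setValidity("TFParams", function(object) {
  n <- object@n
  if (length(n) != 1L || is.na(n) || n < 1L) return("n must be a positive integer")
  nm <- 2L^n
  msg <- character(0)
  for (f in c("m", "delta", "s", "gamma", "x0", "y0"))
    if (length(slot(object, f)) != n) msg <- c(msg, sprintf("%s must have length n", f))
  for (f in c("k", "h"))
    if (!all(dim(slot(object, f)) == c(n, n))) msg <- c(msg, sprintf("%s must be n x n", f))
  if (!all(dim(object@alpha) == c(n, nm))) msg <- c(msg, "alpha must be n x 2^n")
  if (!all(dim(object@r) == c(n, nm - n - 1L))) msg <- c(msg, "r must be n x (2^n - n - 1)")
  if (length(msg)) return(msg)
  vals <- unlist(lapply(c("m", "delta", "s", "gamma", "x0", "y0", "k", "h", "alpha", "r"),
                        function(f) slot(object, f)))
  if (any(!is.finite(vals))) msg <- c(msg, "all parameter values must be finite")
  if (any(object@k <= 0)) msg <- c(msg, "k must be strictly positive")
  if (any(object@h < 0)) msg <- c(msg, "h must be nonnegative")
  if (any(object@alpha < 0 | object@alpha > 1)) msg <- c(msg, "alpha must lie in [0, 1]")
  if (any(object@r < 0)) msg <- c(msg, "r must be nonnegative")
  if (any(c(object@m, object@delta, object@s, object@gamma) < 0))
    msg <- c(msg, "rates must be nonnegative")
  if (any(c(object@x0, object@y0) < 0)) msg <- c(msg, "initial abundances must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a TFParams object
#'
#' @param n number of TFs.
#' @param m,delta,s,gamma length-n per-second rates (scalars are recycled).
#' @param x0,y0 length-n initial abundances (molecules/cell).
#' @param k,h n x n dissociation constants / Hill coefficients (scalars recycled).
#' @param alpha n x 2^n expression weights (scalar recycled).
#' @param r n x (2^n - n - 1) synergy weights (scalar recycled).
#' @return A validated [TFParams-class] object.
#' @examples
#' p <- tfParams(2, m = 1e-3, delta = 1e-4, s = 0.1, gamma = 1e-3,
#'               x0 = 10, y0 = 100, k = 500, h = 2, alpha = 0.5, r = 1)
#' nTF(p)
#' @export
tfParams <- function(n, m, delta, s, gamma, x0, y0, k, h, alpha, r) {
  n <- as.integer(n)
  nm <- 2L^n
  vec <- function(v) rep_len(as.numeric(v), n)
  mat <- function(v, nc) {
    if (is.matrix(v)) return(matrix(as.numeric(v), n, nc))
    matrix(rep_len(as.numeric(v), n * nc), n, nc)
  }
  new("TFParams", n = n,
      m = vec(m), delta = vec(delta), s = vec(s), gamma = vec(gamma),
      x0 = vec(x0), y0 = vec(y0),
      k = mat(k, n), h = mat(h, n),
      alpha = mat(alpha, nm), r = mat(r, nm - n - 1L))
}

#' Number of TFs in a circuit object
#' @param object a [TFParams-class] (or other circuit) object.
#' @return Integer TF count.
#' @export
setGeneric("nTF", function(object) standardGeneric("nTF"))

#' @rdname nTF
#' @export
setMethod("nTF", "TFParams", function(object) object@n)

setMethod("show", "TFParams", function(object) {
  n <- object@n
  cat(sprintf("TFParams: %d-TF circuit, %d parameters\n", n, countParameters(n)))
  cat(sprintf("  m     [/s]: %s\n", paste(signif(object@m, 3), collapse = " ")))
  cat(sprintf("  delta [/s]: %s\n", paste(signif(object@delta, 3), collapse = " ")))
  cat(sprintf("  s     [/s]: %s\n", paste(signif(object@s, 3), collapse = " ")))
  cat(sprintf("  gamma [/s]: %s\n", paste(signif(object@gamma, 3), collapse = " ")))
  cat(sprintf("  x0: %s | y0: %s\n",
              paste(signif(object@x0, 3), collapse = " "),
              paste(signif(object@y0, 3), collapse = " ")))
  cat(sprintf("  k in [%.3g, %.3g], h in [%.3g, %.3g]\n",
              min(object@k), max(object@k), min(object@h), max(object@h)))
  cat(sprintf("  alpha in [%.3g, %.3g], r in [%.3g, %.3g]\n",
              min(object@alpha), max(object@alpha),
              if (ncol(object@r)) min(object@r) else NA,
              if (ncol(object@r)) max(object@r) else NA))
  invisible(object)
})

#' Telegraph light schedule
#'
#' On/off external light availability switching at exponentially distributed
#' waiting times with mean `meanWait` (days). The signal starts off; its state
#' at time t is the parity of the number of switch times at or before t.
#'
#' @slot switchTimes strictly ascending switch times (days) within `[0, tEnd]`.
#' @slot tEnd end of the covered horizon (days).
#' @slot meanWait mean waiting time w (days) used to sample the schedule.
#' @seealso [sampleLightSchedule()], [lightState()]
#' @export
setClass("LightSchedule",
  representation(switchTimes = "numeric", tEnd = "numeric", meanWait = "numeric"))

setValidity("LightSchedule", function(object) {
  st <- object@switchTimes
  if (length(st) && any(diff(st) <= 0)) return("switchTimes must be strictly ascending")
  if (length(st) && (any(st < 0) | any(st > object@tEnd)))
    return("switchTimes must lie in [0, tEnd]")
  if (object@tEnd <= 0) return("tEnd must be positive")
  TRUE
})

setMethod("show", "LightSchedule", function(object) {
  cat(sprintf("LightSchedule: %d switches over %.3g days (mean wait w = %.3g days, initially off)\n",
              length(object@switchTimes), object@tEnd, object@meanWait))
  invisible(object)
})

#' Simulated circuit trajectory
#'
#' Time grid with per-gene mRNA and protein abundances and the light state.
#'
#' @slot times save times (days), ascending.
#' @slot x,y length(times) x n matrices of mRNA / protein abundances.
#' @slot light 0/1 light state at each save time.
#' @seealso [simulateODE()], [simulateSDE()], [as.data.frame,Trajectory-method]
#' @export
setClass("Trajectory",
  representation(times = "numeric", x = "matrix", y = "matrix", light = "numeric"))

setValidity("Trajectory", function(object) {
  nt <- length(object@times)
  if (nt > 1 && any(diff(object@times) <= 0)) return("times must be strictly ascending")
  if (nrow(object@x) != nt || nrow(object@y) != nt) return("x/y rows must match times")
  if (ncol(object@x) != ncol(object@y)) return("x and y must have the same gene count")
  if (length(object@light) != nt) return("light must match times")
  TRUE
})

#' @rdname nTF
#' @export
setMethod("nTF", "Trajectory", function(object) ncol(object@x))

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d genes, %d time points over [%.3g, %.3g] days\n",
              ncol(object@x), length(object@times),
              min(object@times), max(object@times)))
  invisible(object)
})

#' Tidy view of a trajectory
#'
#' @param x a [Trajectory-class].
#' @param row.names,optional,... ignored (S3/S4 compatibility).
#' @return Long data.frame with columns `time`, `gene`, `mRNA`, `protein`,
#'   `light_state`.
#' @export
setMethod("as.data.frame", "Trajectory", function(x, row.names = NULL, optional = FALSE, ...) {
  n <- ncol(x@x)
  nt <- length(x@times)
  data.frame(time = rep(x@times, n),
             gene = rep(seq_len(n), each = nt),
             mRNA = as.vector(x@x),
             protein = as.vector(x@y),
             light_state = rep(x@light, n))
})

#' Trajectory accessors
#'
#' `trajTimes`, `trajMRNA`, `trajProtein`, `trajLight` extract the save times,
#' abundance matrices, and light state of a [Trajectory-class].
#' @param object a [Trajectory-class].
#' @return Numeric vector or matrix.
#' @export
trajTimes <- function(object) object@times
#' @rdname trajTimes
#' @export
trajMRNA <- function(object) object@x
#' @rdname trajTimes
#' @export
trajProtein <- function(object) object@y
#' @rdname trajTimes
#' @export
trajLight <- function(object) object@light

#' Result of a circuit fit
#'
#' @slot par final unbounded parameter vector (best checkpoint).
#' @slot params decoded [TFParams-class] for `par`.
#' @slot lossHistory data.frame with columns `stage`, `window`, `iter`,
#'   `loss`, `best` (best-so-far within the stage).
#' @slot finalLoss loss of the returned checkpoint on its final stage window.
#' @slot config list echoing the optimizer configuration.
#' @slot seed integer seed the run was started from (NA if none).
#' @seealso [fitCircuit()]
#' @export
setClass("CircuitFit",
  representation(par = "numeric", params = "TFParams",
                 lossHistory = "data.frame", finalLoss = "numeric",
                 config = "list", seed = "integer"))

setMethod("show", "CircuitFit", function(object) {
  nstage <- length(unique(object@lossHistory$stage))
  cat(sprintf("CircuitFit: n = %d, %d stages, %d recorded iterations\n",
              object@params@n, nstage, nrow(object@lossHistory)))
  cat(sprintf("  final (best-checkpoint) loss: %.6g\n", object@finalLoss))
  if (!is.na(object@seed)) cat(sprintf("  seed: %d\n", object@seed))
  invisible(object)
})

#' @rdname nTF
#' @export
setMethod("nTF", "CircuitFit", function(object) object@params@n)
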