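#' @include bounds.R
NULL

#' Number of optimizable parameters for an n-TF circuit
#'
#' Counts 4n rate constants, 2n initial conditions, n^2 dissociation constants
#' k, n^2 Hill coefficients h, n 2^n expression weights alpha (one per
#' bound-TF subset and gene) and n (2^n - n - 1) synergy weights r (subsets of
#' size >= 2), i.e. n (5 + n + 2^(n+1)) in closed form.
#'
#' @param n positive integer TF count.
#' @return Integer-valued count (numeric, since the count overflows integers
#'   for large n).
#' @examples
#' countParameters(4)  # 164
#' @export
countParameters <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n))
    stop("n must be a positive integer")
  n * (5 + n + 2^(n + 1))
}

# popcount of nonnegative integer masks
maskPopcount <- function(mask) {
  vapply(mask, function(m) {
    c <- 0L
    while (m > 0) { c <- c + (m %% 2L); m <- m %/% 2L }
    c
  }, integer(1))
}

# mask -> 0-based column in the r matrix (-1 for subsets of size < 2)
rColIndex <- function(n) {
  masks <- 0:(2L^n - 1L)
  pc <- maskPopcount(masks)
  idx <- rep(-1L, length(masks))
  idx[pc >= 2L] <- seq_len(sum(pc >= 2L)) - 1L
  idx
}

#' Layout of the flat unbounded parameter vector
#'
#' The fixed serialization order is: `m`, `delta`, `s`, `gamma` (each gene
#' 1..n), `x0`, `y0`, then `k` and `h` gene-major (gene 1's row first), then
#' `alpha` gene-major in ascending bitmask order (mask 0 = basal state), then
#' `r` gene-major over ascending bitmasks of popcount >= 2.
#'
#' @param n TF count.
#' @return data.frame with columns `slot`, `family`, `gene`, `j` (bound TF for
#'   k/h, bitmask for alpha/r, NA otherwise).
#' @export
paramLayout <- function(n) {
  nm <- 2L^n
  masks <- 0:(nm - 1L)
  rmasks <- masks[maskPopcount(masks) >= 2L]
  fam <- c(rep(c("m", "delta", "s", "gamma", "x0", "y0"), each = n),
           rep("k", n * n), rep("h", n * n),
           rep("alpha", n * nm), rep("r", n * length(rmasks)))
  gene <- c(rep(rep(seq_len(n), 6)),
            rep(seq_len(n), each = n), rep(seq_len(n), each = n),
            rep(seq_len(n), each = nm), rep(seq_len(n), each = length(rmasks)))
  j <- c(rep(NA_integer_, 6L * n),
         rep(seq_len(n), n), rep(seq_len(n), n),
         rep(masks, n), rep(rmasks, n))
  data.frame(slot = seq_along(fam), family = fam, gene = gene, j = j)
}

# family bound (a, b-a) and per-day unit scale for each vector slot, in layout order
layoutScale <- function(n, bounds) {
  lay <- paramLayout(n)
  lower <- bounds[lay$family, "lower"]
  width <- bounds[lay$family, "upper"] - lower
  list(layout = lay, lower = lower, width = width)
}

#' Decode an unbounded vector into a TFParams object
#'
#' Applies the squash transform slot-wise and the affine map onto each
#' family's biological range `(a, a + b)`. The resulting rates are in
#' per-second units.
#'
#' @param v numeric vector of length `countParameters(n)` in [paramLayout()]
#'   order.
#' @param n TF count.
#' @param bounds bounds matrix, see [defaultBounds()].
#' @param spec a [squashSpec()].
#' @return A [TFParams-class].
#' @seealso [encodeParams()]
#' @export
decodeParams <- function(v, n, bounds = defaultBounds(), spec = squashSpec()) {
  checkBoundsMatrix(bounds)
  n <- as.integer(n)
  np <- countParameters(n)
  if (length(v) != np)
    stop(sprintf("v has length %d but countParameters(%d) = %d", length(v), n, np))
  sc <- layoutScale(n, bounds)
  vals <- unname(sc$lower + sc$width * squash(v, spec))
  sliceParams(vals, n)
}

# split a layout-ordered value vector into a TFParams
sliceParams <- function(vals, n) {
  vals <- unname(vals)
  nm <- 2L^n
  nr <- nm - n - 1L
  at <- 0L
  take <- function(k) { out <- vals[at + seq_len(k)]; at <<- at + k; out }
  m <- take(n); delta <- take(n); s <- take(n); gamma <- take(n)
  x0 <- take(n); y0 <- take(n)
  k <- matrix(take(n * n), n, n, byrow = TRUE)
  h <- matrix(take(n * n), n, n, byrow = TRUE)
  alpha <- matrix(take(n * nm), n, nm, byrow = TRUE)
  r <- matrix(take(n * nr), n, nr, byrow = TRUE)
  new("TFParams", n = n, m = m, delta = delta, s = s, gamma = gamma,
      x0 = x0, y0 = y0, k = k, h = h, alpha = alpha, r = r)
}

# flatten a TFParams into layout order (natural units)
flattenParams <- function(params) {
  c(params@m, params@delta, params@s, params@gamma, params@x0, params@y0,
    as.vector(t(params@k)), as.vector(t(params@h)),
    as.vector(t(params@alpha)), as.vector(t(params@r)))
}

#' Encode a TFParams object as an unbounded vector
#'
#' Inverse of [decodeParams()]: maps each in-bounds value to (0, 1) by the
#' affine map and then to the unbounded scale with [unsquash()]. Values lying
#' exactly on a bound are nudged into the open interval by a machine-epsilon
#' margin (the inverse sigmoid is undefined at 0 and 1); values outside their
#' family's bounds raise an error naming the family.
#'
#' @param params a [TFParams-class].
#' @inheritParams decodeParams
#' @return Numeric vector of length `countParameters(n)`.
#' @export
encodeParams <- function(params, bounds = defaultBounds(), spec = squashSpec()) {
  checkBoundsMatrix(bounds)
  n <- params@n
  sc <- layoutScale(n, bounds)
  vals <- flattenParams(params)
  theta <- (vals - sc$lower) / sc$width
  bad <- theta < -1e-9 | theta > 1 + 1e-9
  if (any(bad)) {
    fams <- unique(sc$layout$family[bad])
    stop("parameter value(s) out of bounds for family: ", paste(fams, collapse = ", "))
  }
  eps <- .Machine$double.eps
  theta <- pmin(pmax(theta, eps), 1 - eps)
  unname(unsquash(theta, spec))
}

#' Check a parameter set against its bounds
#'
#' @inheritParams encodeParams
#' @return data.frame of violations (`slot`, `family`, `value`, `lower`,
#'   `upper`); zero rows when everything is in bounds.
#' @export
checkBounds <- function(params, bounds = defaultBounds()) {
  checkBoundsMatrix(bounds)
  sc <- layoutScale(params@n, bounds)
  vals <- flattenParams(params)
  bad <- vals < sc$lower | vals > sc$lower + sc$width
  data.frame(slot = which(bad), family = sc$layout$family[bad],
             value = vals[bad], lower = sc$lower[bad],
             upper = (sc$lower + sc$width)[bad])
}

#' Random initial parameter set
#'
#' Draws the base values used to seed optimization runs: `m` uniform on
#' (1e-4, 1e-2) per second, `delta = 1.01e-4`, `s = 1.01e-1`,
#' `gamma = 1.01e-3` (decay rates pinned near their minimum, which keeps
#' abundances from collapsing early in the search), `k = 5e2`, `h = 2`,
#' `alpha` uniform on (0, 1), `r = 1`, plus `x0 = 10` mRNA and `y0 = 100`
#' protein molecules. Every scalar is then multiplied by `1 + z` with
#' `z ~ Normal(0, perturbSd)` and clipped just inside its bounds.
#'
#' @param n TF count.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param perturbSd standard deviation of the relative perturbation, in
#'   `[0, 1)`; 0 returns the exact base values.
#' @param bounds bounds matrix, see [defaultBounds()].
#' @return A [TFParams-class] within bounds.
#' @examples
#' p <- initParams(2, seed = 1)
#' @export
initParams <- function(n, seed = NULL, perturbSd = 0.25, bounds = defaultBounds()) {
  if (perturbSd < 0 || perturbSd >= 1) stop("perturbSd must lie in [0, 1)")
  checkBoundsMatrix(bounds)
  n <- as.integer(n)
  nm <- 2L^n
  nr <- nm - n - 1L
  withSeed(seed, {
    base <- c(runif(n, 1e-4, 1e-2),            # m
              rep(1.01e-4, n),                 # delta
              rep(1.01e-1, n),                 # s
              rep(1.01e-3, n),                 # gamma
              rep(10, n),                      # x0
              rep(100, n),                     # y0
              rep(5e2, n * n),                 # k
              rep(2, n * n),                   # h
              runif(n * nm),                   # alpha
              rep(1, n * nr))                  # r
    z <- rnorm(length(base), 0, perturbSd)
    vals <- base * (1 + z)
    sc <- layoutScale(n, bounds)
    margin <- 1e-9 * sc$width
    vals <- pmin(pmax(vals, sc$lower + margin), sc$lower + sc$width - margin)
    sliceParams(vals, n)
  })
}

LAYOUT_VERSION <- "tfcircuit-params-1"

#' Serialize / deserialize a parameter set as JSON
#'
#' Round-trip lossless at full double precision; the file carries the layout
#' version tag, n, and explicit field names.
#'
#' @param params a [TFParams-class].
#' @param path file path.
#' @return `writeParams` returns `path` invisibly; `readParams` returns the
#'   [TFParams-class].
#' @export
writeParams <- function(params, path) {
  obj <- list(layout = LAYOUT_VERSION, n = params@n,
              m = params@m, delta = params@delta, s = params@s,
              gamma = params@gamma, x0 = params@x0, y0 = params@y0,
              k = params@k, h = params@h, alpha = params@alpha, r = params@r)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$layout, LAYOUT_VERSION))
    stop("unrecognized parameter layout tag: ", obj$layout)
  n <- as.integer(obj$n)
  asMat <- function(x, nc) matrix(as.numeric(x), n, nc)
  new("TFParams", n = n,
      m = as.numeric(obj$m), delta = as.numeric(obj$delta),
      s = as.numeric(obj$s), gamma = as.numeric(obj$gamma),
      x0 = as.numeric(obj$x0), y0 = as.numeric(obj$y0),
      k = asMat(obj$k, n), h = asMat(obj$h, n),
      alpha = asMat(obj$alpha, 2L^n), r = asMat(obj$r, 2L^n - n - 1L))
}
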