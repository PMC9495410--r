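#' @include dynamics.R
NULL

#' Daily circadian target rhythm
#'
#' `z_t = (sin(2 pi t + pi) + 1) / 2` with t in days: period exactly one day,
#' range `[0, 1]`, value 0.5 at integer and half-integer days. Upward
#' crossings of 0.5 (day onsets) fall at half-integer days; downward
#' crossings (night onsets) at integer days.
#'
#' @param t time (days), any real.
#' @return z in `[0, 1]`.
#' @examples
#' targetRhythm(c(0, 0.25, 0.5, 0.75))  # 0.5 0 0.5 1
#' @export
targetRhythm <- function(t) (sin(2 * pi * t + pi) + 1) / 2

#' Hill normalization of a protein abundance
#'
#' `y~ = y^2 / (half^2 + y^2)`, mapping molecule counts onto `[0, 1)` with
#' half-saturation at the daytime threshold (1000 molecules/cell by default),
#' so that abundance and target rhythm become comparable.
#'
#' @param y abundance (molecules/cell), nonnegative.
#' @param half half-saturation abundance (default 1000).
#' @return Normalized value in `[0, 1)`.
#' @export
transformAbundance <- function(y, half = 1000) y^2 / (half^2 + y^2)

#' Hill normalization of the target rhythm
#'
#' `z~ = z^2 / (half^2 + z^2)` with half-saturation at the day/night
#' threshold z = 0.5, mirroring [transformAbundance()] on the rhythm scale.
#'
#' @param z rhythm value in `[0, 1]`.
#' @param half half-saturation (default 0.5).
#' @return Normalized value in `[0, 1)`.
#' @export
transformTarget <- function(z, half = 0.5) z^2 / (half^2 + z^2)

#' Loss specification
#'
#' @param gridDt loss grid spacing (days; default 0.02, i.e. 50 points/day).
#' @param yHalf abundance half-saturation (molecules/cell).
#' @param zHalf rhythm half-saturation.
#' @param outputGene gene whose protein must track the rhythm (default TF 1).
#' @return List of the four settings.
#' @export
lossSpec <- function(gridDt = 0.02, yHalf = 1000, zHalf = 0.5, outputGene = 1L) {
  if (gridDt <= 0 || yHalf <= 0 || zHalf <= 0) stop("gridDt and half-saturations must be positive")
  list(gridDt = gridDt, yHalf = yHalf, zHalf = zHalf,
       outputGene = as.integer(outputGene))
}

# half-open loss grid: 0, gridDt, ..., < tEnd (50 points/day by default)
lossGrid <- function(tEnd, gridDt = 0.02) {
  npt <- as.integer(floor(tEnd / gridDt + 1e-9))
  (seq_len(npt) - 1L) * gridDt
}

#' Circadian trajectory loss
#'
#' Sum of squared deviations between the Hill-normalized output-TF abundance
#' and the Hill-normalized target rhythm on the half-open grid t = 0,
#' `gridDt`, ..., `tEnd - gridDt` (50 equally spaced points per day at the
#' default spacing): `L = sum_t (y~_t - z~_t)^2`. Trajectory values between
#' grid points do not enter.
#'
#' @param traj a [Trajectory-class] covering `[0, tEnd]`; values at grid
#'   points are linearly interpolated if the save grid differs.
#' @param tEnd end of the scored window (days); default: the trajectory span.
#' @param spec a [lossSpec()].
#' @param target target rhythm function of t (default [targetRhythm()]), or a
#'   numeric vector of *already normalized* target values on the loss grid.
#' @return Nonnegative loss.
#' @export
circadianLoss <- function(traj, tEnd = NULL, spec = lossSpec(),
                          target = targetRhythm) {
  if (is.null(tEnd)) tEnd <- max(traj@times)
  grid <- lossGrid(tEnd, spec$gridDt)
  if (min(traj@times) > grid[1] + 1e-12 || max(traj@times) < grid[length(grid)] - 1e-12)
    stop("trajectory does not cover the loss grid")
  yg <- approx(traj@times, traj@y[, spec$outputGene], xout = grid)$y
  zt <- if (is.function(target)) transformTarget(target(grid), spec$zHalf)
        else {
          if (length(target) != length(grid))
            stop("numeric target must have one value per grid point")
          target
        }
  sum((transformAbundance(yg, spec$yHalf) - zt)^2)
}

#' Day/night state of a protein abundance
#'
#' The cell is in its daytime ("on") state when the output TF abundance is
#' strictly above the threshold (1000 molecules/cell).
#'
#' @param y abundance (molecules/cell), nonnegative.
#' @param threshold daytime threshold (default 1000).
#' @return Logical, same shape as `y`.
#' @export
isDaytime <- function(y, threshold = 1000) {
  if (any(y < 0)) stop("abundance must be nonnegative")
  y > threshold
}
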