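#' @include regulation.R
NULL

#' Light drive specification
#'
#' When external light is available (telegraph state "on"), the production
#' rate of one TF is boosted by `gain * z_t^exponent` molecules per day, with
#' `z_t` the daily rhythm of [targetRhythm()]. With the default exponent the
#' boost is sharply peaked around midday and essentially zero at night, so
#' the drive carries the phase information the circuit entrains to.
#'
#' @param gene index of the light-driven TF (default 2).
#' @param gain drive amplitude (molecules/day, default 1e6).
#' @param exponent sharpening exponent on the rhythm (default 4).
#' @return List with elements `gene`, `gain`, `exponent`.
#' @export
driveSpec <- function(gene = 2L, gain = 1e6, exponent = 4) {
  if (gain < 0 || exponent < 0) stop("gain and exponent must be nonnegative")
  list(gene = as.integer(gene), gain = gain, exponent = exponent)
}

#' Sample a telegraph light schedule
#'
#' The light signal starts off and switches state at i.i.d. exponential
#' waiting times with mean `w` days, truncated at `tEnd`.
#'
#' @param w mean waiting time between switches (days), > 0.
#' @param tEnd horizon (days).
#' @param seed optional integer seed.
#' @return A [LightSchedule-class].
#' @examples
#' sched <- sampleLightSchedule(w = 2, tEnd = 20, seed = 1)
#' lightState(sched, c(0, 5, 10))
#' @export
sampleLightSchedule <- function(w, tEnd, seed = NULL) {
  if (w <= 0) stop("mean waiting time w must be positive")
  withSeed(seed, {
    times <- numeric(0)
    t <- 0
    repeat {
      t <- t + rexp(1, rate = 1 / w)
      if (t > tEnd) break
      times <- c(times, t)
    }
    new("LightSchedule", switchTimes = times, tEnd = tEnd, meanWait = w)
  })
}

#' A schedule that never switches on
#' @param tEnd horizon (days).
#' @return A [LightSchedule-class] with no switches (`meanWait = Inf`).
#' @export
darkSchedule <- function(tEnd) {
  new("LightSchedule", switchTimes = numeric(0), tEnd = tEnd, meanWait = Inf)
}

#' Light state of a schedule at given times
#'
#' @param schedule a [LightSchedule-class] (or NULL, treated as always off).
#' @param t numeric times (days).
#' @return Integer 0/1 vector: parity of the number of switches at or before
#'   each time, starting off.
#' @export
lightState <- function(schedule, t) {
  if (is.null(schedule) || length(schedule@switchTimes) == 0)
    return(rep(0L, length(t)))
  as.integer(findInterval(t, schedule@switchTimes) %% 2L)
}

# per-day light boost to the driven TF at times t
driveAddAt <- function(t, schedule, drive) {
  if (is.null(drive) || drive$gain == 0) return(rep(0, length(t)))
  lightState(schedule, t) * drive$gain * targetRhythm(t)^drive$exponent
}

#' Chemical noise amplitude
#'
#' `sqrt(z)` for abundance z > 16 and `z / 4` for z <= 16 (continuous at 16):
#' square-root "chemical Langevin" scaling, with the small-abundance
#' replacement preventing fluctuations from overwhelming the mean and driving
#' abundances negative.
#'
#' @param z nonnegative abundance (molecules/cell).
#' @return Noise amplitude, same shape as `z`.
#' @export
noiseAmplitude <- function(z) {
  if (any(z < 0)) stop("abundance must be nonnegative")
  ifelse(z > 16, sqrt(z), z / 4)
}

# per-day rates of a TFParams
ratesPerDay <- function(params) {
  list(m = params@m * SECONDS_PER_DAY, delta = params@delta * SECONDS_PER_DAY,
       s = params@s * SECONDS_PER_DAY, gamma = params@gamma * SECONDS_PER_DAY)
}

#' Deterministic right-hand side of the circuit ODE
#'
#' `dx_i/dt = m_i f_i(y) - delta_i x_i`, `dy_i/dt = s_i x_i - gamma_i y_i`,
#' plus the light boost on the driven TF when the schedule is on. Rates are
#' converted from per-second storage to per-day; time is in days.
#'
#' @param state numeric vector `c(x, y)` of length 2n.
#' @param t time (days).
#' @param params a [TFParams-class].
#' @param schedule optional [LightSchedule-class] (NULL = always off).
#' @param drive a [driveSpec()] (NULL = no drive).
#' @return Numeric derivative vector `c(dx, dy)` (per day).
#' @export
odeRHS <- function(state, t, params, schedule = NULL, drive = NULL) {
  n <- params@n
  x <- state[seq_len(n)]
  y <- state[n + seq_len(n)]
  rd <- ratesPerDay(params)
  f <- activationAll(params, pmax(y, 0))
  dx <- rd$m * f - rd$delta * x
  dy <- rd$s * x - rd$gamma * y
  if (!is.null(drive) && drive$gain > 0)
    dy[drive$gene] <- dy[drive$gene] + driveAddAt(t, schedule, drive)
  c(dx, dy)
}

#' Simulate the deterministic circuit ODE
#'
#' Integrates the circuit dynamics from `(x0, y0)`. The default method is
#' deSolve's adaptive `lsoda`; `method = "euler"` uses the same fixed-step
#' stepper the gradient-based optimizer differentiates through (step `dt`).
#'
#' @param params a [TFParams-class].
#' @param tEnd horizon (days), > 0.
#' @param saveDt spacing of the saved grid (days, default 0.02).
#' @param schedule optional [LightSchedule-class].
#' @param drive a [driveSpec()] or NULL for no light drive.
#' @param method `"lsoda"` (adaptive, default) or `"euler"` (fixed-step).
#' @param dt fixed step for `method = "euler"` (days); must divide `saveDt`.
#' @param rtol,atol tolerances for `lsoda`.
#' @return A [Trajectory-class].
#' @examples
#' p <- initParams(2, seed = 1, perturbSd = 0)
#' tr <- simulateODE(p, tEnd = 1)
#' @export
simulateODE <- function(params, tEnd, saveDt = 0.02, schedule = NULL,
                        drive = NULL, method = c("lsoda", "euler"),
                        dt = 1e-3, rtol = 1e-8, atol = 1e-8) {
  method <- match.arg(method)
  if (tEnd <= 0) stop("tEnd must be positive")
  times <- seq(0, tEnd, by = saveDt)
  if (method == "euler") {
    sim <- eulerCore(params, tEnd = tEnd, dt = dt, saveDt = saveDt,
                     schedule = schedule, drive = drive, noiseScale = 0)
    return(newTrajectory(sim$times, sim$x, sim$y, schedule))
  }
  n <- params@n
  fn <- function(t, state, parms) list(odeRHS(state, t, params, schedule, drive))
  hasSwitches <- !is.null(schedule) && length(schedule@switchTimes) > 0
  out <- deSolve::lsoda(y = c(params@x0, params@y0), times = times, func = fn,
                        parms = NULL, rtol = rtol, atol = atol,
                        hmax = if (hasSwitches) saveDt else NULL)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("ODE solver failed near t = %.4g days", max(out[, 1])))
  newTrajectory(out[, 1], out[, 1 + seq_len(n), drop = FALSE],
                out[, 1 + n + seq_len(n), drop = FALSE], schedule)
}

newTrajectory <- function(times, x, y, schedule = NULL) {
  new("Trajectory", times = as.numeric(times),
      x = as.matrix(x), y = as.matrix(y),
      light = as.numeric(lightState(schedule, times)))
}

# shared fixed-step core: builds the per-step drive vector and calls the C++
# stepper; W (2n x nsteps) is drawn here from the ambient RNG when noisy
eulerCore <- function(params, tEnd, dt, saveDt, schedule, drive, noiseScale,
                      W = NULL, lossGene = 1L, lossSteps = integer(0),
                      lossTarget = numeric(0), yHalf = 1000, wantGrad = FALSE) {
  n <- params@n
  saveEvery <- as.integer(round(saveDt / dt))
  if (abs(saveEvery * dt - saveDt) > 1e-9 * saveDt)
    stop("dt must divide saveDt")
  nsteps <- as.integer(round(tEnd / dt))
  if (nsteps %% saveEvery != 0) stop("saveDt must divide tEnd")
  tsteps <- (seq_len(nsteps) - 1L) * dt
  hasDrive <- !is.null(drive) && drive$gain > 0 &&
    !is.null(schedule) && length(schedule@switchTimes) > 0
  driveAdd <- if (hasDrive) driveAddAt(tsteps, schedule, drive) else numeric(nsteps)
  driveGene <- if (hasDrive) drive$gene - 1L else -1L
  if (noiseScale != 0 && is.null(W))
    W <- matrix(rnorm(2 * n * nsteps), 2 * n, nsteps)
  if (noiseScale == 0) W <- matrix(0, 0, 0)
  rd <- ratesPerDay(params)
  res <- cpp_simulate(n, rd$m, rd$delta, rd$s, rd$gamma,
                      params@x0, params@y0, params@k, params@h,
                      params@alpha, params@r, rColIndex(n),
                      dt, nsteps, saveEvery, driveAdd, driveGene,
                      noiseScale, W,
                      lossGene - 1L, as.integer(lossSteps), lossTarget,
                      yHalf, wantGrad)
  res$times <- seq(0, tEnd, by = saveDt)
  res
}

#' Simulate the stochastic circuit dynamics
#'
#' Fixed-step Euler-Maruyama: each abundance is updated by its deterministic
#' drift times `dt` plus `noiseScale * noiseAmplitude(z) * sqrt(dt) * W` with
#' independent standard-normal `W` per component and step, then floored at
#' zero. `noiseScale = 0` reproduces the fixed-step deterministic solution
#' exactly. Results are bit-reproducible for a fixed `seed`.
#'
#' @inheritParams simulateODE
#' @param dt Euler-Maruyama step (days); must divide `saveDt`.
#' @param seed optional integer seed for the noise draws.
#' @param noiseScale multiplier on the chemical noise amplitude (default 1).
#' @return A [Trajectory-class].
#' @examples
#' p <- initParams(2, seed = 1, perturbSd = 0)
#' tr <- simulateSDE(p, tEnd = 1, seed = 7)
#' @export
simulateSDE <- function(params, tEnd, dt = 1e-3, seed = NULL, schedule = NULL,
                        drive = NULL, noiseScale = 1, saveDt = 0.02) {
  if (dt <= 0) stop("dt must be positive")
  if (dt > saveDt) stop("dt must not exceed the save interval")
  withSeed(seed, {
    sim <- eulerCore(params, tEnd = tEnd, dt = dt, saveDt = saveDt,
                     schedule = schedule, drive = drive, noiseScale = noiseScale)
    newTrajectory(sim$times, sim$x, sim$y, schedule)
  })
}
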