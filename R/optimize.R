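#' @include objective.R
NULL

#' Define a circuit fitting problem
#'
#' Bundles everything the optimizer needs: network size, fitting horizon,
#' solver step, loss settings, light drive, and the target.
#'
#' @param n TF count.
#' @param tEnd full fitting horizon (days).
#' @param dt fixed solver step for the differentiable simulator (days).
#' @param spec a [lossSpec()].
#' @param drive a [driveSpec()]; used only when light schedules are sampled
#'   (stochastic mode).
#' @param target target rhythm function of time (default [targetRhythm()]).
#' @param targetTilde optional numeric vector of already-normalized target
#'   values on the full loss grid (overrides `target`; used e.g. for fitting
#'   to a reference trajectory).
#' @param bounds bounds matrix, see [defaultBounds()].
#' @param squash a [squashSpec()].
#' @return A list of class `"circuitProblem"`.
#' @export
circuitProblem <- function(n, tEnd, dt = 1e-3, spec = lossSpec(),
                           drive = driveSpec(), target = targetRhythm,
                           targetTilde = NULL, bounds = defaultBounds(),
                           squash = squashSpec()) {
  checkBoundsMatrix(bounds)
  if (tEnd <= 0 || dt <= 0) stop("tEnd and dt must be positive")
  structure(list(n = as.integer(n), tEnd = tEnd, dt = dt, spec = spec,
                 drive = drive, target = target, targetTilde = targetTilde,
                 bounds = bounds, squash = squash),
            class = "circuitProblem")
}

# normalized target values on the loss grid of a window
windowTarget <- function(problem, window) {
  grid <- lossGrid(window, problem$spec$gridDt)
  if (!is.null(problem$targetTilde)) {
    tt <- problem$targetTilde
    if (length(tt) < length(grid))
      stop("targetTilde does not cover the fitting window")
    tt[seq_along(grid)]
  } else {
    transformTarget(problem$target(grid), problem$spec$zHalf)
  }
}

# loss (and gradient on the unbounded scale) of one simulated window.
# schedule/W come from the caller so that stochastic mode can use
# common random numbers across the gradient and any re-evaluation.
lossAndGrad <- function(v, problem, window = problem$tEnd, schedule = NULL,
                        W = NULL, noiseScale = 0, wantGrad = TRUE) {
  params <- decodeParams(v, problem$n, problem$bounds, problem$squash)
  grid <- lossGrid(window, problem$spec$gridDt)
  lossSteps <- as.integer(round(grid / problem$dt))
  sim <- eulerCore(params, tEnd = window, dt = problem$dt, saveDt = problem$dt,
                   schedule = schedule, drive = problem$drive,
                   noiseScale = noiseScale, W = W,
                   lossGene = problem$spec$outputGene,
                   lossSteps = lossSteps,
                   lossTarget = windowTarget(problem, window),
                   yHalf = problem$spec$yHalf, wantGrad = wantGrad)
  out <- list(loss = sim$loss)
  if (wantGrad) {
    g <- sim$grad
    gvals <- c(g$m, g$delta, g$s, g$gamma, g$x0, g$y0,
               as.vector(t(g$k)), as.vector(t(g$h)),
               as.vector(t(g$alpha)), as.vector(t(g$r)))
    sc <- layoutScale(problem$n, problem$bounds)
    unit <- ifelse(sc$layout$family %in% c("m", "delta", "s", "gamma"),
                   SECONDS_PER_DAY, 1)
    out$grad <- gvals * unit * sc$width * squashDeriv(v, problem$squash)
  }
  out
}

#' Loss of an unbounded parameter vector
#'
#' Decodes `v`, simulates the problem's window with the same fixed-step
#' solver the optimizer differentiates through, and returns the circadian
#' loss. Deterministic (`noiseScale = 0`, no light) unless a schedule and
#' noise are supplied.
#'
#' @param v unbounded parameter vector.
#' @param problem a [circuitProblem()].
#' @param window fitting window (days), defaults to the full horizon.
#' @param schedule optional [LightSchedule-class].
#' @param noiseScale chemical noise multiplier (default 0).
#' @return Numeric loss.
#' @export
circuitLoss <- function(v, problem, window = problem$tEnd, schedule = NULL,
                        noiseScale = 0) {
  lossAndGrad(v, problem, window, schedule = schedule,
              noiseScale = noiseScale, wantGrad = FALSE)$loss
}

#' Gradient of the fitting loss
#'
#' Backpropagates the trajectory loss through every step of the unrolled
#' fixed-step solver. In `"stochastic"` mode the gradient is the average over
#' `nRealizations` noisy trajectories, each with its own pre-drawn Gaussian
#' noise (held fixed through the backward pass) and a freshly sampled light
#' schedule of mean waiting time `w`.
#'
#' @inheritParams circuitLoss
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed optional integer seed for the stochastic draws.
#' @param nRealizations trajectories averaged per gradient (stochastic mode).
#' @param w mean light switch waiting time (days) for sampled schedules;
#'   `Inf` keeps the light off.
#' @param noiseScale chemical noise multiplier in stochastic mode.
#' @return Gradient vector (same length as `v`) with the loss attached as
#'   attribute `"loss"`.
#' @export
evaluateGradient <- function(v, problem, mode = c("deterministic", "stochastic"),
                             window = problem$tEnd, seed = NULL,
                             nRealizations = 4, w = 2, noiseScale = 1) {
  mode <- match.arg(mode)
  if (any(!is.finite(v))) stop("parameter vector must be finite")
  if (mode == "deterministic") {
    res <- lossAndGrad(v, problem, window)
    return(structure(res$grad, loss = res$loss))
  }
  withSeed(seed, {
    n <- problem$n
    nsteps <- as.integer(round(window / problem$dt))
    acc <- NULL
    lacc <- 0
    for (rr in seq_len(nRealizations)) {
      schedule <- if (is.finite(w)) sampleLightSchedule(w, window) else NULL
      W <- matrix(rnorm(2 * n * nsteps), 2 * n, nsteps)
      res <- lossAndGrad(v, problem, window, schedule = schedule, W = W,
                         noiseScale = noiseScale)
      acc <- if (is.null(acc)) res$grad else acc + res$grad
      lacc <- lacc + res$loss
    }
    structure(acc / nRealizations, loss = lacc / nRealizations)
  })
}

#' Curriculum fitting windows
#'
#' Ascending windows ending at the full horizon; by default geometric
#' doubling: `tEnd / 2^(nStages - 1), ..., tEnd / 2, tEnd`. Starting against
#' a short initial stretch of the target and slowly lengthening the fitted
#' period keeps early gradients informative.
#'
#' @param tEnd full horizon (days).
#' @param nStages number of stages (>= 1).
#' @return Ascending numeric vector of window lengths, last equal to `tEnd`.
#' @examples
#' curriculumWindows(4, 3)  # 1 2 4
#' @export
curriculumWindows <- function(tEnd, nStages) {
  if (nStages < 1) stop("nStages must be at least 1")
  tEnd / 2^((nStages - 1):0)
}

#' Fit a circuit to its target by Adam through the solver
#'
#' Runs curriculum stages of Adam on the unbounded parameter vector. Each
#' gradient is obtained by backpropagating the loss through the unrolled
#' fixed-step solver ([evaluateGradient()]). In stochastic mode each step
#' averages `nRealizations` noisy trajectories with freshly sampled light
#' schedules (common random numbers within a step). Non-finite losses or
#' gradients trigger a checkpoint restore with halved learning rate;
#' persistent failure aborts with diagnostics. The returned checkpoint is the
#' best-loss iterate of the final stage.
#'
#' @param init a [TFParams-class] or an unbounded numeric vector to start
#'   from.
#' @param problem a [circuitProblem()].
#' @param iters iterations per stage (scalar recycled, or one per stage).
#'   `0` returns the initial vector with its loss.
#' @param learningRate Adam step size (default 0.002).
#' @param curriculum ascending window vector; default
#'   `curriculumWindows(problem$tEnd, nStages)`.
#' @param nStages stage count used when `curriculum` is NULL.
#' @param mode `"deterministic"` (noise-free, light off) or `"stochastic"`.
#' @param nRealizations,w,noiseScale stochastic-mode settings, see
#'   [evaluateGradient()].
#' @param beta1,beta2,epsilon Adam moment hyperparameters.
#' @param seed optional integer master seed (reproducible histories).
#' @param maxFailures consecutive non-finite evaluations tolerated before
#'   aborting.
#' @return A [CircuitFit-class].
#' @export
fitCircuit <- function(init, problem, iters = 1000, learningRate = 0.002,
                       curriculum = NULL, nStages = 3,
                       mode = c("deterministic", "stochastic"),
                       nRealizations = 4, w = 2, noiseScale = 1,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       seed = NULL, maxFailures = 20) {
  mode <- match.arg(mode)
  v <- if (is(init, "TFParams")) encodeParams(init, problem$bounds, problem$squash)
       else as.numeric(init)
  np <- countParameters(problem$n)
  if (length(v) != np) stop("init has the wrong length for n = ", problem$n)
  if (is.null(curriculum)) curriculum <- curriculumWindows(problem$tEnd, nStages)
  if (any(diff(curriculum) <= 0)) stop("curriculum windows must be ascending")
  iters <- rep_len(as.integer(iters), length(curriculum))

  cfg <- list(iters = iters, learningRate = learningRate,
              curriculum = curriculum, mode = mode,
              nRealizations = nRealizations, w = w, noiseScale = noiseScale,
              beta1 = beta1, beta2 = beta2, epsilon = epsilon)

  runOne <- function() {
    mAdam <- numeric(np); vAdam <- numeric(np); tAdam <- 0
    hist <- vector("list", sum(iters) + length(iters))
    hi <- 0
    bestPar <- v; bestLoss <- Inf
    for (stage in seq_along(curriculum)) {
      window <- curriculum[stage]
      lr <- learningRate
      bestPar <- v; bestLoss <- Inf   # best within the stage
      failures <- 0
      it <- 0
      while (it < iters[stage]) {
        g <- evaluateGradient(v, problem, mode = mode, window = window,
                              nRealizations = nRealizations, w = w,
                              noiseScale = noiseScale)
        loss <- attr(g, "loss")
        if (!is.finite(loss) || any(!is.finite(g))) {
          failures <- failures + 1
          if (failures > maxFailures)
            stop(sprintf(paste0("optimization aborted: %d consecutive non-finite ",
                                "evaluations in stage %d (window %.3g days, ",
                                "best loss %.4g)"),
                         failures, stage, window, bestLoss))
          v <- bestPar
          lr <- lr / 2
          next
        }
        failures <- 0
        it <- it + 1
        if (loss < bestLoss) { bestLoss <- loss; bestPar <- v }
        hi <- hi + 1
        hist[[hi]] <- data.frame(stage = stage, window = window, iter = it,
                                 loss = loss, best = bestLoss)
        tAdam <- tAdam + 1
        mAdam <- beta1 * mAdam + (1 - beta1) * g
        vAdam <- beta2 * vAdam + (1 - beta2) * g^2
        mhat <- mAdam / (1 - beta1^tAdam)
        vhat <- vAdam / (1 - beta2^tAdam)
        v <- v - lr * mhat / (sqrt(vhat) + epsilon)
      }
      if (iters[stage] > 0) v <- bestPar   # carry the stage's best forward
    }
    if (all(iters == 0)) {
      bestPar <- v
      bestLoss <- circuitLoss(v, problem, window = curriculum[length(curriculum)])
      hi <- hi + 1
      hist[[hi]] <- data.frame(stage = length(curriculum),
                               window = curriculum[length(curriculum)],
                               iter = 0L, loss = bestLoss, best = bestLoss)
    }
    list(par = bestPar, loss = bestLoss, hist = do.call(rbind, hist[seq_len(hi)]))
  }

  res <- withSeed(seed, runOne())
  new("CircuitFit", par = res$par,
      params = decodeParams(res$par, problem$n, problem$bounds, problem$squash),
      lossHistory = res$hist, finalLoss = res$loss, config = cfg,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
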