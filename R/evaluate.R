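#' @include optimize.R
NULL

#' Simulate an ensemble of stochastic trajectories
#'
#' Runs `nTraj` independent Euler-Maruyama trajectories, each with its own
#' noise stream and an independently sampled telegraph light schedule of mean
#' waiting time `w`. Per-trajectory seeds are derived from the master seed,
#' so the ensemble is reproducible and trajectory i does not change when
#' `nTraj` grows.
#'
#' @param params a [TFParams-class].
#' @param nTraj number of trajectories.
#' @param tEnd horizon (days).
#' @param w mean light switch waiting time (days); `Inf` keeps light off.
#' @param seed master integer seed.
#' @param drive a [driveSpec()].
#' @param dt Euler-Maruyama step (days).
#' @param noiseScale chemical noise multiplier.
#' @param saveDt save grid spacing (days).
#' @return List of [Trajectory-class] objects, with the schedules attached as
#'   attribute `"schedules"`.
#' @export
simulateEnsemble <- function(params, nTraj, tEnd, w, seed = NULL,
                             drive = driveSpec(), dt = 1e-3, noiseScale = 1,
                             saveDt = 0.02) {
  if (nTraj < 1) stop("nTraj must be at least 1")
  seeds <- if (is.null(seed)) rep(list(NULL), nTraj)
           else as.list(subSeeds(seed, 2L * nTraj))
  trajs <- vector("list", nTraj)
  scheds <- vector("list", nTraj)
  for (i in seq_len(nTraj)) {
    sSeed <- if (is.null(seed)) NULL else seeds[[2L * i - 1L]]
    nSeed <- if (is.null(seed)) NULL else seeds[[2L * i]]
    sched <- if (is.finite(w)) sampleLightSchedule(w, tEnd, seed = sSeed)
             else darkSchedule(tEnd)
    trajs[[i]] <- simulateSDE(params, tEnd = tEnd, dt = dt, seed = nSeed,
                              schedule = sched, drive = drive,
                              noiseScale = noiseScale, saveDt = saveDt)
    scheds[[i]] <- sched
  }
  attr(trajs, "schedules") <- scheds
  trajs
}

#' Fold a deviation into (-12, +12] hours
#'
#' Entry-time deviations are defined modulo the 24 h period; each deviation
#' is attributed to the nearest target onset.
#'
#' @param hours numeric deviations in hours.
#' @return Deviations folded into `(-12, 12]`.
#' @export
foldDeviation <- function(hours) hours - 24 * ceiling((hours - 12) / 24)

#' Daytime entry times of a trajectory
#'
#' Times at which the output TF abundance crosses the daytime threshold
#' (1000 molecules/cell) upwards, located by linear interpolation between
#' samples. To suppress chatter from stochastic fluctuations around the
#' threshold, a crossing only counts if the abundance stayed at or below the
#' threshold for at least `debounce` days beforehand.
#'
#' @param traj a [Trajectory-class] sampled at <= 0.02-day resolution.
#' @param outputGene gene index (default 1).
#' @param threshold daytime threshold (molecules/cell).
#' @param debounce required below-threshold dwell before a crossing (days).
#' @return Numeric vector of entry times (days), possibly empty.
#' @export
entryTimes <- function(traj, outputGene = 1L, threshold = 1000, debounce = 0.05) {
  tt <- traj@times
  yy <- traj@y[, outputGene]
  below <- yy <= threshold
  up <- which(below[-length(yy)] & !below[-1])
  if (!length(up)) return(numeric(0))
  stepDt <- if (length(tt) > 1) tt[2] - tt[1] else 0.02
  need <- max(1L, as.integer(ceiling(debounce / stepDt)))
  keep <- vapply(up, function(i) {
    lo <- max(1L, i - need + 1L)
    (i - lo + 1L) >= need && all(below[lo:i])
  }, logical(1))
  up <- up[keep]
  if (!length(up)) return(numeric(0))
  # linear interpolation of the crossing inside [t_i, t_{i+1}]
  frac <- (threshold - yy[up]) / (yy[up + 1L] - yy[up])
  tt[up] + frac * stepDt
}

#' Percentiles of a deviation sample
#'
#' @param hours numeric deviations (hours); NAs are dropped.
#' @param percentiles percentile levels in (0, 100).
#' @return Named numeric vector of linearly interpolated order statistics
#'   (quantile type 7), nondecreasing.
#' @export
deviationSummary <- function(hours, percentiles = c(5, 25, 50, 75, 95)) {
  q <- quantile(hours, probs = percentiles / 100, na.rm = TRUE,
                names = FALSE, type = 7)
  setNames(q, paste0("p", percentiles))
}

#' Entry-time deviation statistics of an ensemble
#'
#' For each measurement day d, the target day onset is the upward
#' 0.5-crossing of the rhythm at t = d - 0.5. Each trajectory contributes the
#' signed deviation (hours) of its daytime entry nearest that onset, folded
#' into (-12, +12]; trajectories with no entry within half a day of the onset
#' are counted as missing (and reported, not silently dropped).
#'
#' @param trajs list of [Trajectory-class] (see [simulateEnsemble()]).
#' @param w mean waiting time label for the output rows.
#' @param days measurement days (default `c(10, 20, 30)`).
#' @param percentiles percentile levels (default `c(5, 25, 50, 75, 95)`).
#' @param outputGene,threshold,debounce see [entryTimes()].
#' @return data.frame with columns `w`, `day`, `percentile`, `hours`,
#'   `n_valid`, `n_missing`. Cells where every trajectory is missing carry
#'   `NA` hours.
#' @export
deviationStats <- function(trajs, w, days = c(10, 20, 30),
                           percentiles = c(5, 25, 50, 75, 95),
                           outputGene = 1L, threshold = 1000, debounce = 0.05) {
  entries <- lapply(trajs, entryTimes, outputGene = outputGene,
                    threshold = threshold, debounce = debounce)
  rows <- list()
  for (d in days) {
    onset <- d - 0.5
    dev <- vapply(entries, function(et) {
      if (!length(et)) return(NA_real_)
      near <- et[which.min(abs(et - onset))]
      if (abs(near - onset) > 0.5) return(NA_real_)
      foldDeviation((near - onset) * 24)
    }, numeric(1))
    nv <- sum(!is.na(dev))
    qq <- if (nv > 0) deviationSummary(dev, percentiles)
          else setNames(rep(NA_real_, length(percentiles)),
                        paste0("p", percentiles))
    rows[[length(rows) + 1L]] <-
      data.frame(w = w, day = d, percentile = percentiles,
                 hours = as.numeric(qq), n_valid = nv,
                 n_missing = length(dev) - nv)
  }
  do.call(rbind, rows)
}

#' Ensemble evaluation over several light regimes
#'
#' Convenience wrapper: for each mean waiting time in `w`, simulates an
#' ensemble and summarizes entry-time deviations at the measurement days.
#'
#' @inheritParams simulateEnsemble
#' @param w vector of mean waiting times (days).
#' @param days measurement days.
#' @param percentiles percentile levels.
#' @return data.frame stacking [deviationStats()] rows for every `w`.
#' @export
evaluateCircuit <- function(params, w = c(2, 4, 8, 16, 1000), nTraj = 100,
                            days = c(10, 20, 30), seed = NULL,
                            drive = driveSpec(), dt = 1e-3, noiseScale = 1,
                            percentiles = c(5, 25, 50, 75, 95)) {
  tEnd <- max(days) + 0.5
  seeds <- if (is.null(seed)) rep(list(NULL), length(w))
           else as.list(subSeeds(seed, length(w)))
  out <- lapply(seq_along(w), function(i) {
    trajs <- simulateEnsemble(params, nTraj = nTraj, tEnd = tEnd, w = w[i],
                              seed = seeds[[i]], drive = drive, dt = dt,
                              noiseScale = noiseScale)
    deviationStats(trajs, w = w[i], days = days, percentiles = percentiles)
  })
  do.call(rbind, out)
}
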