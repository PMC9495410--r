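test_that("curriculum windows double geometrically up to the horizon", {
  expect_equal(curriculumWindows(4, 3), c(1, 2, 4))
  expect_equal(curriculumWindows(3, 1), 3)
  w <- curriculumWindows(12, 5)
  expect_true(all(diff(w) > 0))
  expect_equal(tail(w, 1), 12)
  expect_error(curriculumWindows(3, 0), "at least 1")
})

test_that("backpropagated gradients match central finite differences", {
  # 1-gene problem: every coordinate
  prob <- circuitProblem(1, tEnd = 1)
  v <- encodeParams(initParams(1, seed = 5, perturbSd = 0.2))
  g <- evaluateGradient(v, prob)
  fd <- vapply(seq_along(v), function(i) {
    e <- replace(rep(0, length(v)), i, 1e-4)
    (circuitLoss(v + e, prob) - circuitLoss(v - e, prob)) / 2e-4
  }, numeric(1))
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-3)
  # 2-gene problem: 20 random coordinates
  prob2 <- circuitProblem(2, tEnd = 1)
  v2 <- encodeParams(initParams(2, seed = 6, perturbSd = 0.2))
  g2 <- evaluateGradient(v2, prob2)
  set.seed(17)
  idx <- sample(length(v2), 20)
  fd2 <- vapply(idx, function(i) {
    e <- replace(rep(0, length(v2)), i, 1e-4)
    (circuitLoss(v2 + e, prob2) - circuitLoss(v2 - e, prob2)) / 2e-4
  }, numeric(1))
  # wider net, coarser bar: finite-difference truncation error dominates on
  # strongly curved coordinates of the larger problem
  expect_lt(max(abs(g2[idx] - fd2) / pmax(abs(fd2), 1e-8)), 1e-2)
})

test_that("the gradient vanishes at an exact minimum", {
  # target generated from the parameters themselves: loss = 0, gradient = 0
  p <- initParams(1, seed = 12, perturbSd = 0.1)
  probPlain <- circuitProblem(1, tEnd = 1)
  v <- encodeParams(p)
  grid <- tfcircuit:::lossGrid(1, 0.02)
  tr <- simulateODE(p, tEnd = 1, method = "euler", dt = 1e-3)
  yt <- transformAbundance(approx(trajTimes(tr), trajProtein(tr)[, 1], grid)$y)
  prob <- circuitProblem(1, tEnd = 1, targetTilde = yt)
  g <- evaluateGradient(v, prob)
  expect_lt(attr(g, "loss"), 1e-20)
  expect_lt(sqrt(sum(g^2)), 1e-6)
})

test_that("stochastic gradients are reproducible under a fixed seed", {
  prob <- circuitProblem(2, tEnd = 1)
  v <- encodeParams(initParams(2, seed = 8, perturbSd = 0.2))
  g1 <- evaluateGradient(v, prob, mode = "stochastic", seed = 4, nRealizations = 2)
  g2 <- evaluateGradient(v, prob, mode = "stochastic", seed = 4, nRealizations = 2)
  expect_identical(as.numeric(g1), as.numeric(g2))
  expect_identical(attr(g1, "loss"), attr(g2, "loss"))
})

test_that("a one-gene constant-target problem converges to machine-level loss", {
  prob <- circuitProblem(1, tEnd = 1, targetTilde = rep(0.3, 50))
  p0 <- initParams(1, seed = 7, perturbSd = 0.1)
  fit <- fitCircuit(p0, prob, iters = 2000, nStages = 1, seed = 1)
  expect_lt(fit@finalLoss, 1e-8)
})

test_that("zero iterations echo the start point with its loss", {
  prob <- circuitProblem(1, tEnd = 1)
  v0 <- encodeParams(initParams(1, seed = 2, perturbSd = 0))
  fit <- fitCircuit(v0, prob, iters = 0, nStages = 1)
  expect_identical(fit@par, v0)
  expect_equal(fit@finalLoss, circuitLoss(v0, prob))
  expect_identical(nrow(fit@lossHistory), 1L)
})

test_that("fits are deterministic under a fixed seed and track a nonincreasing best", {
  prob <- circuitProblem(1, tEnd = 1)
  p0 <- initParams(1, seed = 3, perturbSd = 0.1)
  f1 <- fitCircuit(p0, prob, iters = 30, nStages = 2, mode = "stochastic",
                   nRealizations = 2, seed = 11)
  f2 <- fitCircuit(p0, prob, iters = 30, nStages = 2, mode = "stochastic",
                   nRealizations = 2, seed = 11)
  expect_identical(f1@lossHistory$loss, f2@lossHistory$loss)
  expect_identical(f1@par, f2@par)
  for (st in unique(f1@lossHistory$stage)) {
    b <- f1@lossHistory$best[f1@lossHistory$stage == st]
    expect_true(all(diff(b) <= 0))
    expect_equal(b, cummin(f1@lossHistory$loss[f1@lossHistory$stage == st]))
  }
})

test_that("a perturbed 2-gene circuit recovers the generating trajectory", {
  set.seed(3)
  pTrue <- initParams(2, seed = 11, perturbSd = 0.3)
  grid <- tfcircuit:::lossGrid(2, 0.02)
  tr <- simulateODE(pTrue, tEnd = 2, method = "euler", dt = 1e-3)
  tilde <- transformAbundance(approx(trajTimes(tr), trajProtein(tr)[, 1], grid)$y)
  prob <- circuitProblem(2, tEnd = 2, targetTilde = tilde)
  vTrue <- encodeParams(pTrue)
  v0 <- vTrue * (1 + rnorm(length(vTrue), 0, 0.1))
  init <- circuitLoss(v0, prob)
  fit <- fitCircuit(v0, prob, iters = 1500, nStages = 1, seed = 1)
  expect_lt(fit@finalLoss, 0.01 * init)
  # trajectory agreement on the normalized scale (identifiability not claimed)
  trFit <- simulateODE(fit@params, tEnd = 2, method = "euler", dt = 1e-3)
  tildeFit <- transformAbundance(approx(trajTimes(trFit), trajProtein(trFit)[, 1], grid)$y)
  expect_lt(mean(abs(tildeFit - tilde)), 0.01)
})

test_that("invalid optimizer configurations are rejected", {
  prob <- circuitProblem(2, tEnd = 1)
  expect_error(fitCircuit(rep(0.5, 5), prob), "wrong length")
  expect_error(fitCircuit(encodeParams(initParams(2, seed = 1)), prob,
                          curriculum = c(2, 1)), "ascending")
  expect_error(evaluateGradient(c(NA, rep(0.5, 29)), prob), "finite")
})
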