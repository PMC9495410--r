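test_that("constant-activation single gene matches the closed-form linear solution", {
  p <- constantGene(level = 0.6)
  tr <- simulateODE(p, tEnd = 5, rtol = 1e-10, atol = 1e-10)
  cf <- constantGeneClosedForm(p, 0.6, trajTimes(tr))
  relx <- abs(trajMRNA(tr)[, 1] - cf$x) / pmax(abs(cf$x), 1e-8)
  rely <- abs(trajProtein(tr)[, 1] - cf$y) / pmax(abs(cf$y), 1e-8)
  expect_lt(max(relx), 1e-6)
  expect_lt(max(rely), 1e-6)
})

test_that("solver tolerance refinement leaves the endpoint unchanged", {
  p <- constantGene(level = 0.6)
  e1 <- tail(trajProtein(simulateODE(p, tEnd = 2, rtol = 1e-8, atol = 1e-8))[, 1], 1)
  e2 <- tail(trajProtein(simulateODE(p, tEnd = 2, rtol = 5e-9, atol = 5e-9))[, 1], 1)
  expect_lt(abs(e1 - e2) / abs(e2), 1e-6)
})

test_that("zero production from zero state stays at the origin", {
  p <- tfParams(1, m = 0, delta = 1e-4, s = 1e-3, gamma = 1e-3,
                x0 = 0, y0 = 0, k = 500, h = 2, alpha = 0, r = numeric(0))
  tr <- simulateODE(p, tEnd = 1)
  expect_true(all(trajMRNA(tr) == 0))
  expect_true(all(abs(trajProtein(tr)) < 1e-10))
})

test_that("deterministic mRNA respects the bound implied by m/delta", {
  for (sd in 1:20) {
    p <- randomInBounds(2, seed = 400 + sd)
    tr <- simulateODE(p, tEnd = 2, method = "euler")
    cap <- pmax(p@x0, p@m / p@delta) * (1 + 1e-9)
    expect_true(all(t(trajMRNA(tr)) <= cap))
    expect_true(all(cap <= 100 * (1 + 1e-9)))
  }
})

test_that("constant-activation system converges to its fixed point", {
  p <- constantGene(level = 0.6)
  D <- p@delta[1] * 86400; G <- p@gamma[1] * 86400
  tEnd <- ceiling(10 / min(D, G) / 0.02) * 0.02
  tr <- simulateODE(p, tEnd = tEnd)
  xs <- p@m[1] * 86400 * 0.6 / D
  ys <- p@s[1] * 86400 * xs / G
  expect_lt(abs(tail(trajMRNA(tr)[, 1], 1) - xs) / xs, 1e-3)
  expect_lt(abs(tail(trajProtein(tr)[, 1], 1) - ys) / ys, 1e-3)
})

test_that("noise amplitude uses sqrt above 16 and z/4 below, continuously", {
  expect_equal(noiseAmplitude(100), 10)
  expect_equal(noiseAmplitude(16), 4)          # both branches agree
  expect_equal(noiseAmplitude(16 + 1e-12), 4, tolerance = 1e-9)
  expect_equal(noiseAmplitude(8), 2)
  expect_equal(noiseAmplitude(0), 0)
  expect_error(noiseAmplitude(-1), "nonnegative")
})

test_that("noise-free Euler-Maruyama reproduces the ODE endpoint", {
  p <- constantGene(level = 0.6)
  ode <- simulateODE(p, tEnd = 5)
  sde <- simulateSDE(p, tEnd = 5, dt = 1e-3, seed = 1, noiseScale = 0)
  endO <- tail(trajProtein(ode)[, 1], 1)
  endS <- tail(trajProtein(sde)[, 1], 1)
  expect_lt(abs(endO - endS) / abs(endO), 1e-3)
})

test_that("stochastic simulation is seed-reproducible and never negative", {
  p <- randomInBounds(2, seed = 31)
  a <- simulateSDE(p, tEnd = 2, seed = 7)
  b <- simulateSDE(p, tEnd = 2, seed = 7)
  expect_identical(trajProtein(a), trajProtein(b))
  expect_identical(trajMRNA(a), trajMRNA(b))
  for (sd in 1:100) {
    tr <- simulateSDE(p, tEnd = 1, seed = sd)
    expect_true(all(trajMRNA(tr) >= 0) && all(trajProtein(tr) >= 0))
  }
})

test_that("per-step noise variance scales with abundance", {
  # frozen dynamics (all rates zero): pure noise around z = 1e4
  p <- tfParams(1, m = 0, delta = 0, s = 0, gamma = 0, x0 = 1e4, y0 = 1e4,
                k = 500, h = 2, alpha = 0, r = numeric(0))
  tr <- simulateSDE(p, tEnd = 1, dt = 1e-4, seed = 9, saveDt = 1e-4)
  inc <- diff(trajMRNA(tr)[, 1])
  expect_lt(abs(var(inc) / (1e4 * 1e-4) - 1), 0.05)
})

test_that("a schedule without switches is identical to no light drive", {
  p <- randomInBounds(2, seed = 77)
  drv <- driveSpec(gene = 2, gain = 1e6)
  a <- simulateSDE(p, tEnd = 2, seed = 3, schedule = darkSchedule(2), drive = drv)
  b <- simulateSDE(p, tEnd = 2, seed = 3, schedule = NULL, drive = NULL)
  expect_identical(trajProtein(a), trajProtein(b))
})

test_that("light schedules follow the telegraph law and start off", {
  s <- sampleLightSchedule(2, 20, seed = 1)
  expect_identical(lightState(s, 0), 0L)
  expect_true(all(diff(s@switchTimes) > 0))
  # parity: state flips at each switch
  if (length(s@switchTimes) >= 2) {
    eps <- 1e-9
    expect_identical(lightState(s, s@switchTimes[1] + eps), 1L)
    expect_identical(lightState(s, s@switchTimes[2] + eps), 0L)
  }
  set.seed(5)
  cnt <- replicate(1e4, length(sampleLightSchedule(2, 20)@switchTimes))
  se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - 10), 3 * se)
  noswitch <- replicate(1e4, length(sampleLightSchedule(1000, 20)@switchTimes) == 0)
  expect_lt(abs(mean(noswitch) - exp(-0.02)), 0.01)
})

test_that("the light drive boosts only the driven TF during lit daytime", {
  p <- constantGene(level = 0.5)
  drv <- driveSpec(gene = 1, gain = 1e6, exponent = 4)
  alwaysOn <- new("LightSchedule", switchTimes = 1e-9, tEnd = 1, meanWait = 1)
  d0 <- odeRHS(c(5, 50), t = 0.75, p, alwaysOn, drv)    # midday, z = 1
  dOff <- odeRHS(c(5, 50), t = 0.75, p, NULL, NULL)
  expect_equal(d0[2] - dOff[2], 1e6)
  dNight <- odeRHS(c(5, 50), t = 0.25, p, alwaysOn, drv) # midnight, z = 0
  expect_equal(dNight[2], dOff[2])
})

test_that("trajectories convert to tidy data frames", {
  p <- randomInBounds(2, seed = 3)
  tr <- simulateODE(p, tEnd = 0.5)
  df <- as.data.frame(tr)
  expect_identical(names(df), c("time", "gene", "mRNA", "protein", "light_state"))
  expect_equal(nrow(df), 2 * length(trajTimes(tr)))
  expect_identical(nTF(tr), 2L)
})
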