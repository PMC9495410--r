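test_that("parameter count matches the closed form and structural enumeration", {
  expect_identical(countParameters(1), 10)
  expect_identical(countParameters(2), 30)
  expect_identical(countParameters(4), 164)
  for (n in 1:6) {
    p <- initParams(n, seed = n, perturbSd = 0)
    enumerated <- length(tfcircuit:::flattenParams(p))
    expect_equal(countParameters(n), enumerated)
  }
  expect_error(countParameters(0), "positive integer")
  expect_error(countParameters(-3), "positive integer")
})

test_that("squash is the identity inside, continuous at the joins, monotone, in (0,1)", {
  expect_identical(squash(0.5), 0.5)
  expect_identical(squash(0.3), 0.3)
  # continuity at the boundary-layer joins
  for (b in c(0.01, 0.99)) {
    expect_lt(abs(squash(b - 1e-8) - squash(b + 1e-8)), 1e-6)
  }
  # exact join values: squash(d) = d and squash(1-d) = 1-d
  expect_equal(squash(0.01 - 1e-15), 0.01, tolerance = 1e-9)
  grid <- seq(-100, 100, length.out = 1e4)
  sg <- squash(grid)
  expect_true(all(diff(sg) >= 0))
  expect_true(all(sg > 0 & sg < 1))
  # tails approach but never reach the limits
  expect_lt(squash(-1e6), 0.01)
  expect_gt(squash(-1e6), 0)
})

test_that("unsquash inverts squash on both tails and the identity region", {
  expect_identical(unsquash(0.3), 0.3)
  for (th in c(0.005, 0.001, 0.3, 0.7, 0.995, 0.999)) {
    expect_lt(abs(squash(unsquash(th)) - th), 1e-9)
  }
  expect_error(unsquash(0), "inside")
  expect_error(unsquash(1), "inside")
})

test_that("squash derivative matches numerical differentiation and never overflows", {
  # away from the piecewise joins at d and 1-d, where the transform is kinked
  pts <- c(-50, -1, 0.005, 0.02, 0.5, 0.95, 0.985, 1.5, 50)
  num <- (squash(pts + 1e-7) - squash(pts - 1e-7)) / 2e-7
  expect_equal(squashDeriv(pts), num, tolerance = 1e-5)
  expect_true(all(is.finite(squashDeriv(seq(-1e4, 1e4, length.out = 101)))))
})

test_that("decode/encode round trips within 1e-9", {
  for (n in c(1, 2, 4)) {
    set.seed(n)
    v <- runif(countParameters(n), 0.05, 0.95)  # identity region
    p <- decodeParams(v, n)
    expect_lt(max(abs(encodeParams(p) - v)), 1e-9)
    # and in the opposite direction from a random in-bounds parameter set
    p2 <- randomInBounds(n, seed = 10 + n)
    v2 <- encodeParams(p2)
    p3 <- decodeParams(v2, n)
    rel <- abs(tfcircuit:::flattenParams(p3) - tfcircuit:::flattenParams(p2)) /
      pmax(abs(tfcircuit:::flattenParams(p2)), 1e-12)
    expect_lt(max(rel), 1e-9)
  }
})

test_that("decode maps midpoint slots to the family midpoints", {
  n <- 2
  v <- rep(0.5, countParameters(n))
  p <- decodeParams(v, n)
  b <- defaultBounds()
  mid <- function(f) unname((b[f, 1] + b[f, 2]) / 2)
  expect_equal(p@m, rep(mid("m"), n))
  expect_equal(p@gamma, rep(mid("gamma"), n))
  expect_equal(as.vector(p@k), rep(mid("k"), n * n))
  expect_equal(as.vector(p@alpha), rep(0.5, n * 2^n))
  expect_equal(as.vector(p@r), rep(5, n))
  expect_equal(p@y0, rep(500, n))
})

test_that("decode and encode validate their inputs", {
  expect_error(decodeParams(rep(0.5, 11), 1), "countParameters")
  p <- constantGene()
  p@k[1, 1] <- 2e4                       # above the k upper bound
  expect_error(encodeParams(p), "k")
  viol <- checkBounds(p)
  expect_identical(viol$family, "k")
})

test_that("initialization reproduces the documented base values and is seed-stable", {
  p <- initParams(3, seed = 1, perturbSd = 0)
  expect_equal(p@delta, rep(1.01e-4, 3))
  expect_equal(p@s, rep(1.01e-1, 3))
  expect_equal(p@gamma, rep(1.01e-3, 3))
  expect_true(all(p@h == 2))
  expect_true(all(p@k == 5e2))
  expect_true(all(p@r == 1))
  expect_true(all(p@m > 1e-4 & p@m < 1e-2))
  expect_true(all(p@alpha >= 0 & p@alpha <= 1))
  a <- initParams(3, seed = 42, perturbSd = 0.1)
  b <- initParams(3, seed = 42, perturbSd = 0.1)
  expect_identical(tfcircuit:::flattenParams(a), tfcircuit:::flattenParams(b))
  expect_identical(nrow(checkBounds(a)), 0L)
})

test_that("perturbed initialization has the 1+z multiplicative structure", {
  # Monte-Carlo mean of one slot (h[1,1], base 2) across many seeded draws
  set.seed(99)
  draws <- replicate(1e4, initParams(1, perturbSd = 0.1)@h[1, 1])
  se <- 2 * 0.1 / sqrt(1e4)
  expect_lt(abs(mean(draws) - 2), 3 * se)
})

test_that("parameter JSON serialization round-trips losslessly", {
  p <- randomInBounds(3, seed = 5)
  path <- tempfile(fileext = ".json")
  writeParams(p, path)
  q <- readParams(path)
  expect_identical(tfcircuit:::flattenParams(p), tfcircuit:::flattenParams(q))
  expect_identical(p@n, q@n)
  unlink(path)
})

test_that("the unbounded vector layout is documented and consistent", {
  lay <- paramLayout(3)
  expect_equal(nrow(lay), countParameters(3))
  expect_identical(lay$family[1:3], rep("m", 3))
  # k block is gene-major: gene 1 row first
  krows <- lay[lay$family == "k", ]
  expect_identical(krows$gene[1:3], c(1L, 1L, 1L))
  expect_identical(krows$j[1:3], 1:3)
  # r masks all have popcount >= 2
  rrows <- lay[lay$family == "r", ]
  expect_true(all(tfcircuit:::maskPopcount(rrows$j) >= 2))
})
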