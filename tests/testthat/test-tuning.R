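# Tuning-curve statistics: discriminability, modulation depth, midpoint,
# Fano factors, and the Fisher-information relation.

test_that("deterministic counts give zero spread and zero Fano factor", {
  counts <- matrix(7L, nrow = 3, ncol = 20)
  tc <- curveFromCounts(counts, c(-10, 0, 10))
  expect_equal(tc$meanRate, rep(14, 3))
  expect_equal(tc$sdRate, rep(0, 3))
  expect_equal(tc$fano, rep(0, 3))
  # zero-count points have undefined Fano factor
  tc0 <- curveFromCounts(matrix(0L, 1, 10), 0)
  expect_true(is.na(tc0$fano))
})

test_that("discriminability implements the pooled-SD d-prime", {
  tc <- tuningCurve(c(0, 2), c(100, 80), c(10, 10))
  expect_equal(discriminability(tc)$D, 2)
  # identical neighboring points -> 0
  tc2 <- tuningCurve(c(0, 2), c(50, 50), c(5, 5))
  expect_equal(discriminability(tc2)$D, 0)
  # undefined when both variances vanish but means differ
  tc3 <- tuningCurve(c(0, 2), c(50, 40))
  expect_true(is.na(discriminability(tc3)$D))
  expect_error(discriminability(tuningCurve(0, 10)), "2 grid points")
  expect_equal(discriminability(tc)$midpoint, 1)
})

test_that("sampled Gaussian rates recover the analytic discriminability", {
  n <- 1e5
  set.seed(123)
  x1 <- rnorm(n, 100, 10); x2 <- rnorm(n, 80, 10)
  tc <- tuningCurve(c(0, 2), c(mean(x1), mean(x2)), c(sd(x1), sd(x2)))
  # SE of d-prime-like estimate ~ sqrt(2/n (1 + D^2/4))
  se <- sqrt(2 / n * (1 + 4 / 4))
  expect_lt(abs(discriminability(tc)$D - 2), 3 * se)
})

test_that("absolute discriminability equals step times root Fisher information", {
  # Gaussian tuning model: mu(S) = 200 - 5 S, sigma = 8 constant, so
  # I_F = (mu'/sigma)^2 and |D| = dS sqrt(I_F) exactly; verified on samples
  grid <- seq(-10, 10, by = 2)
  mu <- 200 - 5 * grid
  sig <- 8
  n <- 2e4
  set.seed(7)
  samp <- lapply(mu, function(m) rnorm(n, m, sig))
  tc <- tuningCurve(grid, vapply(samp, mean, 1), vapply(samp, sd, 1))
  D <- discriminability(tc)$D
  analytic <- 2 * sqrt((5 / sig)^2)
  expect_true(all(abs(abs(D) - analytic) < 3 * sqrt(2 / n * (1 + analytic^2 / 4))))
})

test_that("modulation depth is the max-min rate difference", {
  expect_equal(modulationDepth(tuningCurve(1:3, c(10, 50, 30))), 40)
  expect_equal(modulationDepth(tuningCurve(1:4, rep(20, 4))), 0)
})

test_that("midpoint locates the half-height crossing of a sigmoid", {
  tc <- stubSigmoidCurve(mid = -18)
  expect_lt(abs(midpointIld(tc) + 18), 0.1)
  tc2 <- stubSigmoidCurve(mid = -21.5)
  expect_lt(abs(midpointIld(tc2) + 21.5), 0.1)
  expect_error(midpointIld(tuningCurve(1:5, rep(10, 5))), "flat")
})

test_that("averaged discriminability uses absolute values within the range", {
  d <- structure(data.frame(midpoint = c(-1, 1), D = c(2, -2)),
                 class = c("lso_discrim", "data.frame"))
  expect_equal(summarizeDiscriminability(d), 2)
  d0 <- structure(data.frame(midpoint = c(-1, 1), D = c(0, 0)),
                  class = c("lso_discrim", "data.frame"))
  expect_equal(summarizeDiscriminability(d0), 0)
  expect_equal(summarizeDiscriminability(d, c(0, 2)), 2)
  expect_error(summarizeDiscriminability(d, c(5, 6)), "range")
})

test_that("Poisson count stubs have unit Fano factor", {
  set.seed(11)
  counts <- matrix(rpois(4000, 60), nrow = 1)
  tc <- curveFromCounts(counts, 0)
  expect_lt(abs(tc$fano - 1), 3 * sqrt(2 / 4000))
})

test_that("doubling the trial count tightens but does not move the estimate", {
  g <- c(-45, -21, -5)
  a <- runTuning("ild", grid = g, nTrials = 100, seed = 51)
  b <- runTuning("ild", grid = g, nTrials = 200, seed = 52)
  sea <- a$sdRate / sqrt(100); seb <- b$sdRate / sqrt(200)
  expect_true(all(abs(a$meanRate - b$meanRate) < 3 * sqrt(sea^2 + seb^2)))
  # SE of the mean scales as 1/sqrt(n)
  expect_lt(mean(seb / sea), 1 / sqrt(2) * 1.25)
})
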