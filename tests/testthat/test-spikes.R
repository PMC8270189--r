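# Presynaptic spike generation: Poisson statistics, phase locking,
# independence, determinism, and train-set assembly.

test_that("homogeneous generator obeys Poisson count statistics", {
  expect_identical(homogeneousPoisson(0, 500, seed = 1), numeric(0))
  n <- 4000
  counts <- vapply(seq_len(n), function(i)
    length(homogeneousPoisson(250, 500, seed = 42, stream = i)), numeric(1))
  # expected count 125; sample mean within 3 SE, Fano within 3 SE of 1
  expect_lt(abs(mean(counts) - 125), 3 * sqrt(125 / n))
  expect_lt(abs(var(counts) / mean(counts) - 1), 3 * sqrt(2 / n))
  tr <- homogeneousPoisson(300, 200, seed = 9)
  expect_true(all(tr >= 0 & tr < 200))
  expect_true(all(diff(tr) > 0))
  expect_error(homogeneousPoisson(-5, 100), "non-negative")
})

test_that("substreams are deterministic and mutually independent", {
  a <- homogeneousPoisson(200, 500, seed = 7, stream = 3)
  b <- homogeneousPoisson(200, 500, seed = 7, stream = 3)
  expect_identical(a, b)
  expect_false(identical(a, homogeneousPoisson(200, 500, seed = 7, stream = 4)))
  expect_false(identical(a, homogeneousPoisson(200, 500, seed = 8, stream = 3)))
  n <- 2000
  x <- vapply(seq_len(n), function(i)
    length(homogeneousPoisson(200, 100, seed = 5, stream = 2 * i)), numeric(1))
  y <- vapply(seq_len(n), function(i)
    length(homogeneousPoisson(200, 100, seed = 5, stream = 2 * i + 1)),
    numeric(1))
  expect_lt(abs(cor(x, y)), 0.05)
})

test_that("phase-locked generator reproduces target VS, rate and phase", {
  for (fm in c(150, 300, 450)) {
    rv <- amRateAndVs(fm)
    dur <- ceiling(1.1e5 / rv$rate * 1000) # enough for >= 1e5 spikes
    tr <- phaseLockedPoisson(rv$rate, rv$vs, fm, phase = 0, duration = dur,
                             seed = fm)
    expect_gt(length(tr), 1e5)
    m <- vectorStrength(tr, fm)
    expect_lt(abs(m$vs - rv$vs), 0.01)
    expect_lt(abs(m$phase), 2)
    # cycle-averaged rate within 1% of the target
    expect_lt(abs(length(tr) / dur * 1000 - rv$rate) / rv$rate, 0.01)
  }
})

test_that("shifting the locking phase shifts the measured phase", {
  tr0 <- phaseLockedPoisson(171, 0.6, 300, phase = 0, duration = 2e4, seed = 2)
  tr90 <- phaseLockedPoisson(171, 0.6, 300, phase = 90, duration = 2e4,
                             seed = 2)
  d <- vectorStrength(tr90, 300)$phase - vectorStrength(tr0, 300)$phase
  d <- (d + 180) %% 360 - 180
  expect_lt(abs(d - 90), 3)
})

test_that("zero vector strength gives a flat cycle histogram", {
  tr <- phaseLockedPoisson(200, 0, 300, duration = 6e5, seed = 3)
  expect_gt(length(tr), 1e5)
  ph <- (300 * tr / 1000) %% 1
  h <- table(cut(ph, breaks = seq(0, 1, by = 0.05)))
  expect_gt(chisq.test(h)$p.value, 0.01)
})

test_that("spike-train sets follow the stimulus and scenario", {
  sc <- scenarioSpec(8)
  st <- makeSpikeTrains(ildStimulus(-45), sc, seed = 1)
  expect_length(st$excitatory, 20)
  expect_length(st$inhibitory, 8)
  # pathway rates: excitatory at rateFromSpl(35), inhibitory at rateFromSpl(-10)
  exRate <- sum(lengths(st$excitatory)) / 20 / 0.5
  inhRate <- sum(lengths(st$inhibitory)) / 8 / 0.5
  expect_lt(abs(exRate - rateFromSpl(35)), 3 * sqrt(rateFromSpl(35) / 20 / 0.5))
  expect_lt(abs(inhRate - rateFromSpl(-10)), 3 * sqrt(rateFromSpl(-10) / 8 / 0.5))
  # no inhibitory fibers at mInh = 0
  st0 <- makeSpikeTrains(ildStimulus(0), scenarioSpec(0), seed = 1)
  expect_length(st0$inhibitory, 0)
  # determinism of the whole set
  expect_identical(makeSpikeTrains(ildStimulus(-10), sc, seed = 99, trial = 4),
                   makeSpikeTrains(ildStimulus(-10), sc, seed = 99, trial = 4))
})

test_that("AM train sets lock inhibition earlier by the phase difference", {
  sc <- scenarioSpec(8)
  st <- makeSpikeTrains(amStimulus(300, dphi = 0, duration = 4000), sc, seed = 6)
  phEx <- vectorStrength(unlist(st$excitatory), 300)$phase
  phInh <- vectorStrength(unlist(st$inhibitory), 300)$phase
  d0 <- ((phEx - phInh) + 180) %% 360 - 180
  expect_lt(abs(d0), 6)
  st2 <- makeSpikeTrains(amStimulus(300, dphi = 60, duration = 4000), sc,
                         seed = 6)
  phInh2 <- vectorStrength(unlist(st2$inhibitory), 300)$phase
  # positive dphi: inhibitory locking phase is earlier (at -dphi)
  d <- (phInh2 + 60 + 180) %% 360 - 180
  expect_lt(abs(d), 6)
})

test_that("spike-train export writes fiber/time rows", {
  st <- makeSpikeTrains(ildStimulus(-20, duration = 100), scenarioSpec(2),
                        seed = 3)
  f <- tempfile(fileext = ".tsv")
  writeSpikeTrains(st, f)
  tab <- read.delim(f)
  expect_named(tab, c("fiber_id", "time_ms"))
  expect_equal(nrow(tab),
               sum(lengths(st$excitatory)) + sum(lengths(st$inhibitory)))
  expect_setequal(unique(tab$fiber_id),
                  c(seq_len(20), 1000 + seq_len(2)))
  unlink(f)
})
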