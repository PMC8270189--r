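# Experiment driver: config validation, presets, outputs, determinism.

test_that("config validation rejects unknown keys and bad values", {
  expect_error(validateExperimentConfig(list(task = "ild", bogus = 1)),
               "bogus")
  expect_error(validateExperimentConfig(list(task = "banana")), "task")
  expect_error(validateExperimentConfig(list(model = "hodgkin")), "model")
  cfg <- validateExperimentConfig(list(task = "phase", fm = 150))
  expect_s3_class(cfg, "lso_config")
  expect_equal(cfg$fm, 150)
})

test_that("YAML configs round-trip through the reader", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("task: ild", "nTrials: 10", "seed: 5", "scenarios:",
               "  - mInh: 8", "  - mInh: 4", "    mode: compensated"), f)
  cfg <- readExperimentConfig(f)
  expect_equal(cfg$nTrials, 10)
  expect_length(cfg$scenarios, 2)
  expect_equal(cfg$scenarios[[2]]$mode, "compensated")
  unlink(f)
})

test_that("presets cover the uncompensated fiber sweep", {
  cfg <- experimentPreset("uncompensated-sweep", scale = 0.02)
  expect_equal(vapply(cfg$scenarios, `[[`, 1, "mInh"),
               c(0, 1, 2, 4, 6, 8, 12, 16))
  expect_true(all(vapply(cfg$scenarios, `[[`, "", "mode") == "uncompensated"))
  expect_equal(cfg$nTrials, 10)
  expect_error(experimentPreset("fig99"), "unknown preset")
})

test_that("a smoke run writes outputs and a faithful manifest", {
  cfg <- validateExperimentConfig(list(
    task = "ild", grid = c(-45, -20, 5), nTrials = 10, seed = 77,
    name = "smoke",
    scenarios = list(list(mInh = 8), list(mInh = 4, mode = "compensated"))))
  out <- file.path(tempdir(), "lso-smoke")
  unlink(out, recursive = TRUE)
  summ <- runExperiment(cfg, out, quiet = TRUE)
  expect_true(all(file.exists(file.path(out, c("tuning.csv",
                                               "discriminability.csv",
                                               "summary.json",
                                               "manifest.json")))))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 77)
  expect_equal(man$config$task, "ild")
  tab <- read.csv(file.path(out, "tuning.csv"))
  expect_equal(nrow(tab), 2 * 3)
  expect_setequal(unique(tab$mInh), c(8, 4))
  # normalization against the mInh = 8 scenario
  expect_equal(summ[["m08_uncompensated"]]$normalizedD, 1)
  unlink(out, recursive = TRUE)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- validateExperimentConfig(list(task = "ild", grid = c(-30, -10),
                                       nTrials = 8, seed = 3, name = "det",
                                       scenarios = list(list(mInh = 6))))
  o1 <- file.path(tempdir(), "det1"); o2 <- file.path(tempdir(), "det2")
  unlink(c(o1, o2), recursive = TRUE)
  runExperiment(cfg, o1, quiet = TRUE)
  runExperiment(cfg, o2, quiet = TRUE)
  expect_identical(readLines(file.path(o1, "tuning.csv")),
                   readLines(file.path(o2, "tuning.csv")))
  expect_identical(readLines(file.path(o1, "summary.json")),
                   readLines(file.path(o2, "summary.json")))
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("population task writes pair-level discriminability", {
  cfg <- validateExperimentConfig(list(task = "population", nTrials = 8,
                                       duration = 200, seed = 2, name = "pop",
                                       scenarios = list(list(mInh = 8))))
  # shrink the population via a tiny trial count only; grid stays default
  out <- file.path(tempdir(), "lso-pop")
  unlink(out, recursive = TRUE)
  summ <- runExperiment(cfg, out, quiet = TRUE)
  expect_equal(summ[["m08_uncompensated"]]$nPairs, 22)
  expect_true(file.exists(file.path(out, "discriminability.csv")))
  unlink(out, recursive = TRUE)
})
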