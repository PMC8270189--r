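#' Construct a tuning curve object
#'
#' Container for across-trial spike-rate statistics on a stimulus grid. Used
#' both for simulated curves (see [runTuning()]) and for analytically
#' constructed test curves.
#'
#' @param stimulus Stimulus grid (dB ILD or degrees phase difference).
#' @param meanRate,sdRate Across-trial mean and SD of spike rate, spikes/s.
#' @param fano Fano factor (count variance / count mean) per point; `NA`
#'   where the mean count is zero.
#' @param nTrials Number of trials per point.
#' @param duration Trial duration, ms.
#' @param task `"ild"` or `"phase"`.
#' @return A data frame of class `lso_tuning` with attributes `nTrials`,
#'   `duration`, `task`.
#' @export
tuningCurve <- function(stimulus, meanRate, sdRate = rep(0, length(stimulus)),
                        fano = rep(NA_real_, length(stimulus)),
                        nTrials = 1L, duration = 500, task = "ild") {
  stopifnot(length(meanRate) == length(stimulus),
            length(sdRate) == length(stimulus),
            length(fano) == length(stimulus),
            all(sdRate >= 0), all(is.na(fano) | fano >= 0))
  out <- data.frame(stimulus = stimulus, meanRate = meanRate,
                    sdRate = sdRate, fano = fano)
  structure(out, class = c("lso_tuning", "data.frame"),
            nTrials = nTrials, duration = duration, task = task)
}

#' @export
print.lso_tuning <- function(x, ...) {
  cat(sprintf("<lso_tuning: %s task, %d points, %d trials x %g ms>\n",
              attr(x, "task"), nrow(x), attr(x, "nTrials"),
              attr(x, "duration")))
  print.data.frame(x, ...)
  invisible(x)
}

.curve_from_counts <- function(counts, stimulus, duration, task) {
  # counts: nPoints x nTrials integer matrix
  mu_c <- rowMeans(counts)
  var_c <- apply(counts, 1, stats::var)
  scale <- 1000 / duration
  tc <- tuningCurve(stimulus,
                    meanRate = mu_c * scale,
                    sdRate = sqrt(var_c) * scale,
                    fano = ifelse(mu_c > 0, var_c / mu_c, NA_real_),
                    nTrials = ncol(counts), duration = duration, task = task)
  tc
}

#' Simulate a tuning curve over a stimulus grid
#'
#' Runs `nTrials` independent 500-ms (by default) stimulations per grid
#' point, each with freshly drawn presynaptic spike trains, and summarizes
#' the across-trial spike rates. The default grids are the ILD grid
#' `-45..+15` dB in 2-dB steps and the phase grid `-180..+180` degrees in
#' 10-degree steps.
#'
#' For the ILD task the ipsilateral level is fixed at +35 dB and the
#' contralateral level is `35 + ild - shift` dB; a nonzero `shift` therefore
#' translates the tuning curve exactly along the ILD axis (used for
#' population modeling). For the phase task all inputs share
#' `amRateAndVs(fm)` and the inhibitory locking phase leads the excitatory
#' one by the grid value.
#'
#' @param task `"ild"` or `"phase"`.
#' @param grid Stimulus grid; defaults as above.
#' @param scenario An [scenarioSpec()] fixing `mInh` and the compensation.
#' @param model `"active"` or `"passive"` IF model.
#' @param fm Modulation frequency (phase task only), Hz.
#' @param nTrials Trials per grid point.
#' @param duration Trial duration, ms.
#' @param dt Integration step, ms.
#' @param seed Master seed; identical seed and settings give identical
#'   results.
#' @param shift Midpoint shift in dB (ILD task only).
#' @param streamOffset Offset added to the per-point RNG substream index;
#'   runs meant to be statistically independent (e.g. different population
#'   pairs) should use disjoint offsets.
#' @param syn Baseline [synapseParams()].
#' @param keepCounts If `TRUE`, attach the per-trial spike-count matrix as
#'   attribute `"counts"` (points x trials), e.g. for resampling-based
#'   standard errors.
#' @return An `lso_tuning` data frame (see [tuningCurve()]).
#' @export
runTuning <- function(task = c("ild", "phase"), grid = NULL,
                      scenario = scenarioSpec(),
                      model = c("active", "passive"), fm = 300,
                      nTrials = 500, duration = 500, dt = 0.01, seed = 1,
                      shift = 0, streamOffset = 0, syn = synapseParams(),
                      keepCounts = FALSE) {
  task <- match.arg(task)
  model <- match.arg(model)
  if (is.null(grid))
    grid <- if (task == "ild") seq(-45, 15, by = 2) else seq(-180, 180, by = 10)
  if (length(grid) == 0) stop("empty stimulus grid")
  stopifnot(nTrials >= 2, duration > 0, dt > 0)
  neuron <- if (model == "active") activeIFParams() else passiveIFParams()
  syn <- scenarioSynapse(scenario, syn)
  seed <- .resolve_seed(seed)
  modelCode <- if (model == "active") 0L else 1L

  counts <- matrix(0L, nrow = length(grid), ncol = nTrials)
  for (i in seq_along(grid)) {
    if (task == "ild") {
      exRate <- rateFromSpl(35)
      inhRate <- rateFromSpl(35 + grid[i] - shift)
      counts[i, ] <- cpp_run_trials(modelCode, unclass(neuron),
                                    syn$AEx, syn$tauEx, syn$EEx,
                                    syn$AInh, syn$tauInh, syn$EInh,
                                    syn$MEx, syn$MInh,
                                    0L, exRate, inhRate,
                                    0, 1, 0, 0, 0,
                                    nTrials, duration, dt,
                                    seed, streamOffset + i)
    } else {
      rv <- amRateAndVs(fm)
      kap <- kappaFromVs(rv$vs)
      i0s <- besselI(kap, 0, expon.scaled = TRUE)
      counts[i, ] <- cpp_run_trials(modelCode, unclass(neuron),
                                    syn$AEx, syn$tauEx, syn$EEx,
                                    syn$AInh, syn$tauInh, syn$EInh,
                                    syn$MEx, syn$MInh,
                                    1L, rv$rate, rv$rate,
                                    kap, i0s, fm,
                                    0, -grid[i] * pi / 180,
                                    nTrials, duration, dt,
                                    seed, streamOffset + i)
    }
  }
  tc <- .curve_from_counts(counts, grid, duration, task)
  attr(tc, "scenario") <- scenario
  attr(tc, "model") <- model
  if (task == "phase") attr(tc, "fm") <- fm
  if (keepCounts) attr(tc, "counts") <- counts
  tc
}

#' Neuronal discriminability between neighboring stimuli
#'
#' The d-prime-like statistic
#' \deqn{D = (\mu_1 - \mu_2) / \sqrt{(\sigma_1^2 + \sigma_2^2)/2}}
#' for each pair of neighboring grid points (index 1 is the smaller
#' stimulus). `|D|` relates to the Fisher information as
#' \eqn{|D| = \Delta S \sqrt{I_F(S)}} for Gaussian rate distributions.
#'
#' @param curve An `lso_tuning` object (or any object with columns
#'   `stimulus`, `meanRate`, `sdRate`).
#' @return A data frame of class `lso_discrim` with columns `midpoint`
#'   (between-pair stimulus midpoint), `D`, and attribute `step`. Pairs with
#'   both SDs zero give `NA`.
#' @examples
#' tc <- tuningCurve(c(0, 2), c(100, 80), c(10, 10))
#' discriminability(tc)$D  # 2
#' @export
discriminability <- function(curve) {
  if (nrow(curve) < 2) stop("need at least 2 grid points")
  n <- nrow(curve)
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  pooled <- (curve$sdRate[i1]^2 + curve$sdRate[i2]^2) / 2
  D <- ifelse(pooled > 0,
              (curve$meanRate[i1] - curve$meanRate[i2]) / sqrt(pooled),
              ifelse(curve$meanRate[i1] == curve$meanRate[i2], 0, NA_real_))
  out <- data.frame(midpoint = (curve$stimulus[i1] + curve$stimulus[i2]) / 2,
                    D = D)
  structure(out, class = c("lso_discrim", "data.frame"),
            step = if (n > 1) curve$stimulus[2] - curve$stimulus[1] else NA,
            task = attr(curve, "task"))
}

#' Modulation depth of a tuning curve
#'
#' Difference between the maximum and minimum across-trial mean spike rate.
#'
#' @inheritParams discriminability
#' @return Modulation depth in spikes/s.
#' @export
modulationDepth <- function(curve) {
  if (nrow(curve) == 0) stop("empty tuning curve")
  max(curve$meanRate) - min(curve$meanRate)
}

#' Midpoint of a sigmoidal ILD-tuning curve
#'
#' The ILD at which the mean rate crosses half height,
#' `(max + min)/2`, located by linear interpolation between the bracketing
#' grid points. If the (noisy) curve crosses half height more than once, the
#' crossing nearest the steepest-slope segment is returned.
#'
#' @inheritParams discriminability
#' @return Midpoint ILD in dB.
#' @export
midpointIld <- function(curve) {
  mu <- curve$meanRate; s <- curve$stimulus
  if (max(mu) <= min(mu)) stop("flat tuning curve: midpoint undefined")
  h <- (max(mu) + min(mu)) / 2
  f <- mu - h
  n <- length(mu)
  cross <- which(f[-n] * f[-1] <= 0 & mu[-n] != mu[-1])
  if (length(cross) == 0) stop("no half-height crossing found")
  xing <- vapply(cross, function(i)
    s[i] + (s[i + 1] - s[i]) * f[i] / (mu[i] - mu[i + 1]), numeric(1))
  if (length(cross) > 1) {
    slopes <- abs(diff(mu) / diff(s))
    steep <- (s[which.max(slopes)] + s[which.max(slopes) + 1]) / 2
    xing <- xing[which.min(abs(xing - steep))]
  }
  xing
}

#' Average absolute discriminability over a stimulus range
#'
#' Mean of `|D|` over the pair midpoints falling inside `range` (inclusive).
#' Because D changes sign over periodic (phase) tuning curves, the absolute
#' value is averaged; any normalization to a reference scenario is performed
#' by the caller.
#'
#' @param dcurve An `lso_discrim` object (see [discriminability()]).
#' @param range Length-2 numeric, stimulus interval to average over;
#'   `NULL` for the whole curve.
#' @return Mean absolute discriminability (dimensionless).
#' @export
summarizeDiscriminability <- function(dcurve, range = NULL) {
  m <- dcurve$midpoint
  keep <- if (is.null(range)) rep(TRUE, length(m))
          else m >= range[1] & m <= range[2]
  if (!any(keep)) stop("no discriminability pairs inside the range")
  mean(abs(dcurve$D[keep]), na.rm = TRUE)
}

#' Resampling standard error of an averaged-discriminability ratio
#'
#' Bootstrap (over trials, within each grid point) of the ratio of the
#' averaged `|D|` of a test curve to that of a reference curve. Both curves
#' must have been run with `keepCounts = TRUE`.
#'
#' @param curve,reference `lso_tuning` objects carrying `"counts"`.
#' @param range Averaging range passed to [summarizeDiscriminability()].
#' @param nBoot Number of bootstrap replicates.
#' @param seed Seed for the resampling RNG.
#' @return List with `ratio` (point estimate) and `se` (bootstrap SE).
#' @export
discriminabilityRatioSE <- function(curve, reference, range = NULL,
                                    nBoot = 200, seed = 1) {
  cm <- attr(curve, "counts"); rm_ <- attr(reference, "counts")
  if (is.null(cm) || is.null(rm_))
    stop("curves must be run with keepCounts = TRUE")
  dur_c <- attr(curve, "duration"); dur_r <- attr(reference, "duration")
  summ <- function(counts, stim, dur, task)
    summarizeDiscriminability(
      discriminability(.curve_from_counts(counts, stim, dur, task)), range)
  est <- summ(cm, curve$stimulus, dur_c, attr(curve, "task")) /
    summ(rm_, reference$stimulus, dur_r, attr(reference, "task"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(nBoot), function(b) {
    rc <- cm[, sample.int(ncol(cm), replace = TRUE), drop = FALSE]
    rr <- rm_[, sample.int(ncol(rm_), replace = TRUE), drop = FALSE]
    summ(rc, curve$stimulus, dur_c, attr(curve, "task")) /
      summ(rr, reference$stimulus, dur_r, attr(reference, "task"))
  }, numeric(1))
  list(ratio = est, se = stats::sd(reps))
}
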