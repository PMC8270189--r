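#' @useDynLib lsosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.resolve_seed <- function(seed) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) || seed < 0)
    stop("'seed' must be a single non-negative number")
  as.double(floor(seed))
}

#' Homogeneous Poisson spike train
#'
#' Samples a spike train on `[0, duration)` by exponential inter-event
#' intervals; expected count is `rate * duration / 1000`.
#'
#' @param rate Firing rate, spikes/s (`>= 0`).
#' @param duration Duration, ms.
#' @param seed Seed of the counter-based generator substream. `NULL` draws a
#'   seed from R's RNG (so `set.seed()` still makes results reproducible).
#' @param stream Integer substream index; trains with different `stream`
#'   under the same `seed` are independent.
#' @return Sorted numeric vector of spike times in ms.
#' @export
homogeneousPoisson <- function(rate, duration, seed = NULL, stream = 0L) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("'rate' must be a single non-negative finite number")
  stopifnot(is.numeric(duration), duration > 0)
  cpp_hom_poisson(rate, duration, .resolve_seed(seed), 0, 0, stream)
}

#' Phase-locked (von Mises) inhomogeneous Poisson spike train
#'
#' Samples an inhomogeneous Poisson process whose intensity over the
#' modulation cycle is a von Mises density with concentration
#' `kappaFromVs(vs)`, scaled so the cycle-averaged rate equals `rate`:
#' \deqn{\lambda(t) = \mathrm{rate}\; e^{\kappa \cos(2\pi f_m t/1000 - \phi)} / I_0(\kappa).}
#' Sampling uses thinning against the homogeneous envelope at the intensity
#' peak, which is exact. Pooled over many spikes, the measured vector
#' strength converges to `vs` and the circular-mean phase to `phase`.
#'
#' @param rate Cycle-averaged firing rate, spikes/s.
#' @param vs Target vector strength, `0 <= vs < 1`.
#' @param fm Modulation frequency, Hz (`> 0`).
#' @param phase Locking phase in degrees.
#' @param duration Duration, ms.
#' @inheritParams homogeneousPoisson
#' @return Sorted numeric vector of spike times in ms.
#' @export
phaseLockedPoisson <- function(rate, vs, fm, phase = 0, duration = 500,
                               seed = NULL, stream = 0L) {
  if (!is.numeric(rate) || rate < 0 || !is.finite(rate))
    stop("'rate' must be non-negative and finite")
  if (!is.numeric(vs) || vs < 0 || vs >= 1) stop("'vs' must be in [0, 1)")
  stopifnot(fm > 0, duration > 0)
  kap <- kappaFromVs(vs)
  i0s <- besselI(kap, 0, expon.scaled = TRUE)
  cpp_vm_poisson(rate, kap, i0s, fm, phase * pi / 180, duration,
                 .resolve_seed(seed), 0, 0, stream)
}

#' Stimulus specifications
#'
#' `ildStimulus()` describes a binaural unmodulated tone: the ipsilateral
#' (excitatory) level is fixed at +35 dB and the contralateral (inhibitory)
#' level is `35 + ild` dB, following the convention ILD = contralateral minus
#' ipsilateral level. `amStimulus()` describes a binaural amplitude-modulated
#' tone with modulation frequency `fm` and envelope phase difference `dphi`
#' (degrees); a positive `dphi` means the inhibitory inputs arrive earlier
#' than the excitatory inputs.
#'
#' @param ild Interaural level difference, dB.
#' @param duration Stimulus duration, ms.
#' @param ipsiSpl Ipsilateral sound pressure level, dB.
#' @return An object of class `lso_stimulus`.
#' @export
ildStimulus <- function(ild, duration = 500, ipsiSpl = 35) {
  stopifnot(is.finite(ild), duration > 0)
  structure(list(kind = "ild", ild = ild, ipsiSpl = ipsiSpl,
                 duration = duration),
            class = "lso_stimulus")
}

#' @rdname ildStimulus
#' @param fm Modulation frequency, Hz.
#' @param dphi Envelope phase difference (inhibitory minus excitatory
#'   arrival), degrees.
#' @export
amStimulus <- function(fm = 300, dphi = 0, duration = 500) {
  stopifnot(fm > 0, fm < 2000, is.finite(dphi), duration > 0)
  structure(list(kind = "am", fm = fm, dphi = dphi, duration = duration),
            class = "lso_stimulus")
}

#' Generate the full presynaptic spike-train set for one trial
#'
#' Draws mutually independent spike trains for all `MEx = 20` excitatory and
#' `mInh` inhibitory fibers. For unmodulated tones the excitatory fibers fire
#' homogeneously at `rateFromSpl(35)` and the inhibitory fibers at
#' `rateFromSpl(35 + ild)`. For AM tones all fibers are phase-locked with
#' rate and vector strength `amRateAndVs(fm)`; the excitatory locking phase
#' is 0 and the inhibitory locking phase is `-dphi` so that positive `dphi`
#' makes inhibition arrive earlier within the cycle.
#'
#' Fiber substreams are counter-based and keyed by
#' `(seed, stream, trial, fiber)`, so any fiber of any trial is reproducible
#' independent of generation order.
#'
#' @param stim An [ildStimulus()] or [amStimulus()].
#' @param scenario An [scenarioSpec()]; only its `mInh` matters here.
#' @param seed Master seed (see [homogeneousPoisson()]).
#' @param trial Trial index (>= 1).
#' @param stream Extra substream component (e.g. a grid-point index).
#' @param syn Baseline [synapseParams()] supplying `MEx`.
#' @return An object of class `lso_spiketrains`: list with `excitatory` and
#'   `inhibitory` (lists of sorted spike-time vectors) and `duration`.
#' @export
makeSpikeTrains <- function(stim, scenario = scenarioSpec(), seed = NULL,
                            trial = 1L, stream = 0L, syn = synapseParams()) {
  stopifnot(inherits(stim, "lso_stimulus"), inherits(scenario, "lso_scenario"))
  seed <- .resolve_seed(seed)
  mEx <- syn$MEx
  mInh <- scenario$mInh
  if (stim$kind == "ild") {
    exRate <- rateFromSpl(stim$ipsiSpl)
    inhRate <- rateFromSpl(stim$ipsiSpl + stim$ild)
    ex <- lapply(seq_len(mEx), function(m)
      cpp_hom_poisson(exRate, stim$duration, seed, stream, trial, m))
    inh <- lapply(seq_len(mInh), function(m)
      cpp_hom_poisson(inhRate, stim$duration, seed, stream, trial, 1000 + m))
  } else if (stim$kind == "am") {
    rv <- amRateAndVs(stim$fm)
    kap <- kappaFromVs(rv$vs)
    i0s <- besselI(kap, 0, expon.scaled = TRUE)
    phiEx <- 0
    phiInh <- -stim$dphi * pi / 180
    ex <- lapply(seq_len(mEx), function(m)
      cpp_vm_poisson(rv$rate, kap, i0s, stim$fm, phiEx, stim$duration,
                     seed, stream, trial, m))
    inh <- lapply(seq_len(mInh), function(m)
      cpp_vm_poisson(rv$rate, kap, i0s, stim$fm, phiInh, stim$duration,
                     seed, stream, trial, 1000 + m))
  } else stop("unknown stimulus kind: ", stim$kind)
  structure(list(excitatory = ex, inhibitory = inh, duration = stim$duration),
            class = "lso_spiketrains")
}

#' @export
print.lso_spiketrains <- function(x, ...) {
  cat(sprintf("<lso_spiketrains: %d excitatory / %d inhibitory fibers, %g ms>\n",
              length(x$excitatory), length(x$inhibitory), x$duration))
  cat(sprintf("  spikes: %d excitatory, %d inhibitory\n",
              sum(lengths(x$excitatory)), sum(lengths(x$inhibitory))))
  invisible(x)
}

#' Export a spike-train set as two-column text
#'
#' Writes `fiber_id time_ms` rows (tab separated); excitatory fibers are
#' numbered `1..MEx`, inhibitory fibers `1001..1000+MInh`.
#'
#' @param trains An `lso_spiketrains` object.
#' @param path Output file path.
#' @export
writeSpikeTrains <- function(trains, path) {
  stopifnot(inherits(trains, "lso_spiketrains"))
  ids <- c(rep(seq_along(trains$excitatory), lengths(trains$excitatory)),
           rep(1000L + seq_along(trains$inhibitory),
               lengths(trains$inhibitory)))
  tms <- c(unlist(trains$excitatory, use.names = FALSE),
           unlist(trains$inhibitory, use.names = FALSE))
  utils::write.table(data.frame(fiber_id = ids, time_ms = tms), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
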