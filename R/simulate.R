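#' Total alpha-function synaptic conductance by direct kernel summation
#'
#' Evaluates \eqn{g(t) = \sum_m \sum_i \alpha(t - t^m_i)} with
#' \eqn{\alpha(s) = A (s/\tau) e^{1 - s/\tau}} for `s >= 0` (0 otherwise).
#' The unitary kernel peaks at exactly `A` a lag `tau` after the spike.
#' This direct evaluation serves as the reference for the event-driven
#' two-state update used inside the integrator.
#'
#' @param trains A list of sorted spike-time vectors (or one vector), ms.
#' @param A Unitary peak conductance, nS.
#' @param tau Alpha-function time constant, ms.
#' @param t Evaluation times, ms (vectorized).
#' @return Conductance in nS at each `t`.
#' @export
alphaConductance <- function(trains, A, tau, t) {
  if (!is.list(trains)) trains <- list(trains)
  spikes <- sort(unlist(trains, use.names = FALSE))
  if (length(spikes) == 0) return(rep(0, length(t)))
  vapply(t, function(tt) {
    lag <- tt - spikes
    lag <- lag[lag > 0]
    sum(A * (lag / tau) * exp(1 - lag / tau))
  }, numeric(1))
}

#' Simulate the LSO membrane response to a presynaptic spike-train set
#'
#' Integrates the active or passive IF model driven by alpha-conductance
#' synapses. Both membrane equations are conditionally linear in their own
#' state, so `V` and the KLVA activation `d` are advanced by exponential
#' Euler; the synaptic conductances are propagated by an exact event-driven
#' two-state update, equivalent to kernel summation at the grid times. A
#' spike is assigned to the first grid time with `V >= Vth`. During the
#' refractory period of the active model the dynamics (including the
#' injected spike current) continue but threshold testing is suspended; the
#' passive model clamps `V` to its reset potential instead.
#'
#' @param trains An `lso_spiketrains` object (see [makeSpikeTrains()]), or a
#'   list with elements `excitatory`, `inhibitory`, `duration`.
#' @param neuron An `lso_neuron` parameter set; default [activeIFParams()].
#' @param syn An [synapseParams()] object (fiber counts are taken from the
#'   supplied trains).
#' @param dt Integration step, ms.
#' @param gConstEx,gConstInh Optional constant (tonic) conductances in nS
#'   added to the synaptic ones; useful for analytic checks.
#' @param returnTrace If `TRUE`, also return membrane/conductance traces.
#' @param traceEvery Trace decimation in integration steps.
#' @return A list of class `lso_sim` with `spikeTimes` (ms) and, if
#'   requested, `trace` (data frame `t`, `V`, `gEx`, `gInh`).
#' @examples
#' tr <- makeSpikeTrains(ildStimulus(-45, duration = 100), seed = 1)
#' sim <- simulateLSO(tr)
#' length(sim$spikeTimes)
#' @export
simulateLSO <- function(trains, neuron = activeIFParams(),
                        syn = synapseParams(), dt = 0.01,
                        gConstEx = 0, gConstInh = 0,
                        returnTrace = FALSE, traceEvery = 10L) {
  stopifnot(inherits(neuron, "lso_neuron"), inherits(syn, "lso_synapse"),
            dt > 0)
  model <- if (attr(neuron, "model") == "active") 0L else 1L
  out <- cpp_simulate(model, unclass(neuron),
                      syn$AEx, syn$tauEx, syn$EEx,
                      syn$AInh, syn$tauInh, syn$EInh,
                      trains$excitatory, trains$inhibitory,
                      trains$duration, dt, gConstEx, gConstInh,
                      if (returnTrace) as.integer(traceEvery) else 0L)
  out$duration <- trains$duration
  class(out) <- "lso_sim"
  out
}

#' @export
print.lso_sim <- function(x, ...) {
  cat(sprintf("<lso_sim: %d spikes in %g ms (%.1f spikes/s)>\n",
              length(x$spikeTimes), x$duration,
              1000 * length(x$spikeTimes) / x$duration))
  invisible(x)
}

#' Resting potential of the active IF model
#'
#' Solves \eqn{g_L(E_L - V) + g_{KL} d_\infty(V)(E_K - V) = 0} for the
#' zero-input fixed point of the active model.
#'
#' @param neuron An [activeIFParams()] object.
#' @return Resting membrane potential, mV.
#' @export
restingPotential <- function(neuron = activeIFParams()) {
  stopifnot(attr(neuron, "model") == "active")
  p <- unclass(neuron)
  dinf <- function(V) {
    w <- exp((V + 50) / 16)
    w^2 / (w^2 + 1)
  }
  f <- function(V) p["gL"] * (p["EL"] - V) + p["gKL"] * dinf(V) * (p["EK"] - V)
  stats::uniroot(f, c(p["EK"], p["EL"]), tol = 1e-12)$root
}
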