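#' Membrane parameters of the active integrate-and-fire LSO model
#'
#' Single-compartment IF model augmented with a low-voltage-activated
#' potassium (KLVA) conductance and a spike-associated current. The
#' subthreshold dynamics are
#' \deqn{C \dot V = g_L(E_L - V) + g_{KL}\, d(V)(E_K - V) + I_{ex} + I_{inh} + I_{spike}}
#' with first-order KLVA activation `d(t)` governed by
#' \eqn{\alpha_d(V) = 0.5 e^{(V+50)/16}}, \eqn{\beta_d(V) = 0.5 e^{-(V+50)/16}}
#' (1/ms). A spike is counted when `V` reaches `Vth`; for the refractory
#' period `Tref` no further spikes are counted, while the dynamics (including
#' the injected spike current \eqn{I_{spike}(s) = 24 e^{-s/0.15} - 12 e^{-s/0.30}}
#' nA, `s` the time since threshold crossing) continue to evolve.
#'
#' @param C Membrane capacitance, pF.
#' @param gL Leak conductance, nS.
#' @param gKL Maximal KLVA conductance, nS.
#' @param EL Leak reversal potential, mV.
#' @param EK Potassium reversal potential, mV.
#' @param Vth Spike threshold, mV.
#' @param Tref Absolute refractory period, ms.
#' @return An object of class `lso_neuron` (named numeric vector with a
#'   `model` attribute).
#' @seealso [passiveIFParams()], [simulateLSO()]
#' @export
activeIFParams <- function(C = 24, gL = 14.4, gKL = 21.6, EL = -56,
                           EK = -75, Vth = -45.8, Tref = 1.6) {
  stopifnot(C > 0, gL >= 0, gKL >= 0, Tref >= 0, EK < Vth, Vth < 0)
  p <- c(C = C, gL = gL, gKL = gKL, EL = EL, EK = EK, Vth = Vth, Tref = Tref)
  structure(p, class = "lso_neuron", model = "active")
}

#' Membrane parameters of the passive integrate-and-fire LSO model
#'
#' Leaky IF variant without voltage-gated conductances: on reaching the
#' threshold `Vth` a spike is counted and the membrane potential is clamped
#' to the reset value `V0` for the refractory period `Tref`.
#'
#' @inheritParams activeIFParams
#' @param V0 Reset potential, mV (`V0 <= EL < Vth`).
#' @return An object of class `lso_neuron`.
#' @export
passiveIFParams <- function(C = 24, gL = 26.4, EL = -60, V0 = -60,
                            Vth = -45.1, Tref = 1.6) {
  stopifnot(C > 0, gL >= 0, Tref >= 0, V0 <= EL, EL < Vth)
  p <- c(C = C, gL = gL, gKL = 0, EL = EL, V0 = V0, Vth = Vth, Tref = Tref)
  structure(p, class = "lso_neuron", model = "passive")
}

#' @export
print.lso_neuron <- function(x, ...) {
  cat(sprintf("<lso_neuron: %s IF model>\n", attr(x, "model")))
  print(unclass(x))
  invisible(x)
}

#' Synaptic parameters of the LSO model
#'
#' Each presynaptic spike evokes a unitary alpha-function conductance
#' \eqn{\alpha(s) = A (s/\tau) e^{1 - s/\tau}} that peaks at `A` nS a lag
#' `tau` ms after the spike; conductances superpose linearly across spikes
#' and fibers. The default inhibitory amplitude `AInh = 12` nS corresponds to
#' the healthy condition with `MInh = 8` inhibitory fibers; inhibition-loss
#' scenarios modify `AInh` and `MInh` only (see [scenarioSpec()]).
#'
#' @param AEx,AInh Unitary peak conductances, nS.
#' @param tauEx,tauInh Alpha-function time constants, ms.
#' @param EEx,EInh Synaptic reversal potentials, mV.
#' @param MEx,MInh Number of excitatory / inhibitory input fibers.
#' @return An object of class `lso_synapse` (named list).
#' @export
synapseParams <- function(AEx = 3.5, AInh = 12, tauEx = 0.16, tauInh = 0.32,
                          EEx = 0, EInh = -75, MEx = 20, MInh = 8) {
  stopifnot(AEx >= 0, AInh >= 0, tauEx > 0, tauInh > 0,
            MEx >= 0, MInh >= 0, MEx == round(MEx), MInh == round(MInh))
  structure(list(AEx = AEx, AInh = AInh, tauEx = tauEx, tauInh = tauInh,
                 EEx = EEx, EInh = EInh, MEx = as.integer(MEx),
                 MInh = as.integer(MInh)),
            class = "lso_synapse")
}

#' @export
print.lso_synapse <- function(x, ...) {
  cat("<lso_synapse>\n")
  cat(sprintf("  excitatory: M = %d, A = %.3g nS, tau = %.3g ms, E = %g mV\n",
              x$MEx, x$AEx, x$tauEx, x$EEx))
  cat(sprintf("  inhibitory: M = %d, A = %.3g nS, tau = %.3g ms, E = %g mV\n",
              x$MInh, x$AInh, x$tauInh, x$EInh))
  invisible(x)
}
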