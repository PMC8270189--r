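# Reference implementations used as independent oracles: a plain scalar-loop
# integrator whose synaptic conductances come from direct kernel summation
# (alphaConductance), and small builders for analytic stub curves.

referenceSimulate <- function(trains, neuron = activeIFParams(),
                              syn = synapseParams(), dt = 0.01) {
  model <- attr(neuron, "model")
  p <- unclass(neuron)
  n <- round(trains$duration / dt)
  tgrid <- (seq_len(n) - 1) * dt
  gex <- alphaConductance(trains$excitatory, syn$AEx, syn$tauEx, tgrid)
  ginh <- alphaConductance(trains$inhibitory, syn$AInh, syn$tauInh, tgrid)
  V <- unname(p["EL"])
  w <- exp((V + 50) / 16)
  d <- w^2 / (w^2 + 1)
  ia <- 0; ib <- 0
  decA <- exp(-dt / 0.15); decB <- exp(-dt / 0.30)
  refr <- -Inf; clamped <- FALSE
  spikes <- numeric(0)
  for (k in seq_len(n)) {
    t1 <- k * dt
    if (model == "passive" && clamped) {
      if (t1 >= refr - 1e-9) clamped <- FALSE
      V <- unname(p["V0"])
    } else {
      if (model == "active") {
        G <- p["gL"] + p["gKL"] * d + gex[k] + ginh[k]
        B <- p["gL"] * p["EL"] + p["gKL"] * d * p["EK"] +
          gex[k] * syn$EEx + ginh[k] * syn$EInh + 1000 * (ia - ib)
      } else {
        G <- p["gL"] + gex[k] + ginh[k]
        B <- p["gL"] * p["EL"] + gex[k] * syn$EEx + ginh[k] * syn$EInh
      }
      Vinf <- B / G
      Vold <- V
      V <- unname(Vinf + (V - Vinf) * exp(-G * dt / p["C"]))
      if (model == "active") {
        wv <- exp((Vold + 50) / 16)
        ad <- 0.5 * wv; bd <- 0.5 / wv
        dinf <- ad / (ad + bd)
        d <- dinf + (d - dinf) * exp(-dt * (ad + bd))
      }
    }
    ia <- ia * decA; ib <- ib * decB
    if (t1 >= refr - 1e-9 && V >= p["Vth"]) {
      spikes <- c(spikes, t1)
      refr <- t1 + p["Tref"]
      if (model == "active") {
        ia <- ia + 24; ib <- ib + 12
      } else {
        V <- unname(p["V0"]); clamped <- TRUE
      }
    }
  }
  spikes
}

# analytic sigmoidal ILD curve: decreasing logistic with half-height at `mid`
stubSigmoidCurve <- function(grid = seq(-45, 15, by = 2), mid = -18,
                             lo = 30, hi = 130, slope = 4, sd = 8) {
  mu <- lo + (hi - lo) / (1 + exp((grid - mid) / slope))
  tuningCurve(grid, mu, rep(sd, length(grid)), nTrials = 1000)
}

# curve built from an explicit count matrix via the package's own summarizer
curveFromCounts <- function(counts, stimulus, duration = 500, task = "ild") {
  lsosim:::.curve_from_counts(counts, stimulus, duration, task)
}
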