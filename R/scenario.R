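#' Inhibition-loss scenario
#'
#' Describes the state of the inhibitory pathway after age-related fiber
#' loss: the number of surviving MNTB fibers `mInh` (healthy default 8, range
#' 0--16) and the homeostatic compensation mode applied to the surviving
#' unitary amplitudes:
#' \describe{
#'   \item{`"uncompensated"`}{amplitude stays at the default 12 nS; the total
#'     inhibitory conductance scales linearly with `mInh`.}
#'   \item{`"compensated"`}{amplitude is scaled by `8/mInh` so the total
#'     inhibitory conductance is conserved at its healthy value.}
#'   \item{`"overcompensated"`}{the compensated amplitude is additionally
#'     multiplied by `(2 - mInh/8)`, making the total conductance a linearly
#'     decreasing function of `mInh` (e.g. 50\% above the healthy total at
#'     `mInh = 4`, zero at `mInh = 16`).}
#' }
#' Compensation modes require at least one surviving fiber.
#'
#' @param mInh Number of inhibitory input fibers, integer 0--16.
#' @param mode Compensation mode.
#' @param aInhDefault Healthy unitary inhibitory amplitude, nS.
#' @param mInhDefault Healthy number of inhibitory fibers.
#' @return An object of class `lso_scenario`.
#' @examples
#' scenarioSpec(4, "compensated")  # unitary amplitude doubled to 24 nS
#' @export
scenarioSpec <- function(mInh = 8,
                         mode = c("uncompensated", "compensated",
                                  "overcompensated"),
                         aInhDefault = 12, mInhDefault = 8) {
  mode <- match.arg(mode)
  if (!is.numeric(mInh) || length(mInh) != 1L || mInh != round(mInh) ||
      mInh < 0 || mInh > 16)
    stop("'mInh' must be an integer in 0..16")
  if (mInh == 0 && mode != "uncompensated")
    stop("compensation modes are undefined at mInh = 0 (no fibers remain)")
  structure(list(mInh = as.integer(mInh), mode = mode,
                 aInhDefault = aInhDefault,
                 mInhDefault = as.integer(mInhDefault)),
            class = "lso_scenario")
}

#' Effective unitary inhibitory amplitude of a scenario
#'
#' @param scenario An [scenarioSpec()] object.
#' @return Unitary inhibitory peak conductance in nS.
#' @examples
#' effectiveInhibitoryAmplitude(scenarioSpec(4, "compensated"))   # 24
#' effectiveInhibitoryAmplitude(scenarioSpec(16, "overcompensated"))  # 0
#' @export
effectiveInhibitoryAmplitude <- function(scenario) {
  stopifnot(inherits(scenario, "lso_scenario"))
  a0 <- scenario$aInhDefault
  m0 <- scenario$mInhDefault
  m <- scenario$mInh
  switch(scenario$mode,
         uncompensated = a0,
         compensated = a0 * m0 / m,
         overcompensated = a0 * (m0 / m) * (2 - m / m0))
}

#' Total inhibitory conductance of a scenario
#'
#' `mInh` times the effective unitary amplitude: linear in `mInh` when
#' uncompensated, constant when compensated, linearly decreasing when
#' overcompensated.
#'
#' @inheritParams effectiveInhibitoryAmplitude
#' @return Summed peak inhibitory conductance in nS.
#' @export
totalInhibitoryConductance <- function(scenario) {
  stopifnot(inherits(scenario, "lso_scenario"))
  if (scenario$mInh == 0) return(0)
  scenario$mInh * effectiveInhibitoryAmplitude(scenario)
}

#' Synapse parameters resolved for a scenario
#'
#' @inheritParams effectiveInhibitoryAmplitude
#' @param syn Baseline [synapseParams()]; its `AInh` and `MInh` are replaced
#'   by the scenario's effective values.
#' @return An `lso_synapse` object.
#' @export
scenarioSynapse <- function(scenario, syn = synapseParams()) {
  stopifnot(inherits(scenario, "lso_scenario"), inherits(syn, "lso_synapse"))
  syn$MInh <- scenario$mInh
  syn$AInh <- if (scenario$mInh == 0) 0 else
    effectiveInhibitoryAmplitude(scenario)
  syn
}

#' @export
print.lso_scenario <- function(x, ...) {
  cat(sprintf("<lso_scenario: mInh = %d, %s, unitary AInh = %.3g nS (total %.3g nS)>\n",
              x$mInh, x$mode, effectiveInhibitoryAmplitude(x),
              totalInhibitoryConductance(x)))
  invisible(x)
}
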