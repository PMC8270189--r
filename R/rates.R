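#' Level-dependent input rate for unmodulated tones
#'
#' Sigmoidal rate-level function of the model's input fibers (spherical bushy
#' cells for the excitatory pathway, MNTB neurons for the inhibitory pathway):
#' \deqn{\lambda(\mathrm{SPL}) = 30 + \frac{240}{1 + \exp(-(\mathrm{SPL} - 20)/6)}}
#' so the rate rises from a 30 spikes/s floor towards 270 spikes/s, with the
#' half-maximum at 20 dB SPL.
#'
#' @param spl Sound pressure level in dB (finite numeric, vectorized).
#' @return Input firing rate in spikes/s.
#' @examples
#' rateFromSpl(20)  # sigmoid midpoint: 150 spikes/s
#' rateFromSpl(35)  # ipsilateral (excitatory) drive used throughout
#' @export
rateFromSpl <- function(spl) {
  if (!is.numeric(spl) || any(!is.finite(spl)))
    stop("'spl' must be finite numeric")
  30 + 240 / (1 + exp(-(spl - 20) / 6.0))
}

#' Mean rate and vector strength of phase-locked inputs to AM tones
#'
#' For an amplitude-modulated tone with modulation frequency `fm` (Hz), the
#' input fibers fire at mean rate \eqn{\lambda(f_m) = 180 - 0.03 f_m} spikes/s
#' with phase-locking strength
#' \deqn{VS(f_m) = 0.65 \frac{1 - e^{(f_m - 2000)/500}}{1 + e^{(f_m - 2000)/500}}.}
#' The vector-strength formula is only defined for `fm < 2000` Hz; the model
#' uses modulation frequencies up to 450 Hz.
#'
#' @param fm Modulation frequency in Hz, `0 <= fm < 2000` (vectorized).
#' @return A list with elements `rate` (spikes/s) and `vs` (dimensionless).
#' @examples
#' amRateAndVs(300)
#' @export
amRateAndVs <- function(fm) {
  if (!is.numeric(fm) || any(!is.finite(fm)) || any(fm < 0) || any(fm >= 2000))
    stop("'fm' must satisfy 0 <= fm < 2000 Hz")
  z <- exp((fm - 2000) / 500)
  list(rate = 180 - 0.03 * fm, vs = 0.65 * (1 - z) / (1 + z))
}

# cache for the VS -> kappa inversion (keyed by formatted VS)
.kappa_cache <- new.env(parent = emptyenv())

#' Concentration parameter of a von Mises distribution from vector strength
#'
#' Inverts the standard relation \eqn{VS = I_1(\kappa)/I_0(\kappa)} (ratio of
#' modified Bessel functions of the first kind) by bracketed root finding.
#'
#' @param vs Vector strength, `0 <= vs < 1`.
#' @param tol Relative tolerance of the inversion.
#' @return Concentration `kappa >= 0` with `besselI(kappa, 1)/besselI(kappa, 0)`
#'   equal to `vs` within `tol`.
#' @examples
#' kappaFromVs(0.65)
#' @export
kappaFromVs <- function(vs, tol = 1e-12) {
  if (!is.numeric(vs) || length(vs) != 1L || !is.finite(vs) || vs < 0 || vs >= 1)
    stop("'vs' must be a single value in [0, 1)")
  if (vs == 0) return(0)
  key <- sprintf("%.15g", vs)
  if (!is.null(.kappa_cache[[key]])) return(.kappa_cache[[key]])
  ratio <- function(k) {
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE) - vs
  }
  # bracket: ratio is increasing in kappa; I1/I0 ~ 1 - 1/(2k) for large k
  hi <- max(4, 1 / (1 - vs))
  while (ratio(hi) < 0) hi <- hi * 2
  k <- stats::uniroot(ratio, c(0, hi), tol = tol)$root
  .kappa_cache[[key]] <- k
  k
}

#' Vector strength of a pooled spike train
#'
#' Circular-statistics measure of phase locking to a periodic stimulus:
#' the resultant length of spike phases on the modulation cycle.
#'
#' @param times Spike times in ms.
#' @param fm Modulation frequency in Hz.
#' @return A list with `vs` (resultant length in `[0, 1]`) and `phase`
#'   (circular-mean phase in degrees in `[-180, 180)`).
#' @export
vectorStrength <- function(times, fm) {
  if (length(times) == 0) return(list(vs = NA_real_, phase = NA_real_))
  th <- 2 * pi * fm * times / 1000
  cc <- mean(cos(th)); ss <- mean(sin(th))
  ph <- atan2(ss, cc) * 180 / pi
  if (ph >= 180) ph <- ph - 360
  list(vs = sqrt(cc^2 + ss^2), phase = ph)
}
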