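#' Population specification for mirrored LSO pairs
#'
#' Describes a population of LSO neurons whose ILD-tuning midpoints are
#' shifted versions of the default curve, each paired with a "mirrored"
#' contralateral neuron (tuning curve reflected about zero ILD). The default
#' covers midpoint shifts `-26..+16` dB in 2-dB steps (22 pairs), simulated
#' on a symmetric ILD grid wide enough that the `+/-35` dB averaging window
#' is always covered.
#'
#' @param shifts Midpoint shifts in dB.
#' @param ildGrid Symmetric ILD grid, dB.
#' @param averageRange Length-2 ILD interval for the population average, dB.
#' @return An object of class `lso_population_spec`.
#' @export
populationSpec <- function(shifts = seq(-26, 16, by = 2),
                           ildGrid = seq(-44, 44, by = 2),
                           averageRange = c(-35, 35)) {
  if (!isTRUE(all.equal(sort(ildGrid), sort(-ildGrid))))
    stop("'ildGrid' must be symmetric about zero ILD")
  structure(list(shifts = shifts, ildGrid = ildGrid,
                 averageRange = averageRange),
            class = "lso_population_spec")
}

#' @export
print.lso_population_spec <- function(x, ...) {
  cat(sprintf("<lso_population_spec: %d mirrored pairs (shifts %g..%g dB), grid %g..%g dB, average over [%g, %g] dB>\n",
              length(x$shifts), min(x$shifts), max(x$shifts),
              min(x$ildGrid), max(x$ildGrid),
              x$averageRange[1], x$averageRange[2]))
  invisible(x)
}

#' Simulate a midpoint-shifted ILD tuning curve
#'
#' Thin wrapper around [runTuning()] that realizes the shift at the input
#' level (contralateral SPL offset by `-shift`), which translates the tuning
#' curve exactly along the ILD axis.
#'
#' @param shift Midpoint shift, dB.
#' @param spec A [populationSpec()] providing the ILD grid.
#' @param ... Passed to [runTuning()] (`scenario`, `nTrials`, `seed`, ...).
#' @return An `lso_tuning` object with attribute `shift`.
#' @export
shiftedTuning <- function(shift, spec = populationSpec(), ...) {
  tc <- runTuning(task = "ild", grid = spec$ildGrid, shift = shift, ...)
  attr(tc, "shift") <- shift
  tc
}

#' Mirrored bilateral pair and its rate difference
#'
#' Pairs a simulated tuning curve with its mirrored image (mean and SD
#' reflected about zero ILD, representing the similarly tuned neuron of the
#' contralateral LSO) and computes the bilateral rate difference. The two
#' sides fire independently, so the difference SD adds in quadrature:
#' `diffSd^2(ild) = sd(ild)^2 + sd(-ild)^2`, and the difference mean is
#' antisymmetric by construction.
#'
#' @param curve An `lso_tuning` object on a symmetric ILD grid.
#' @return An object of class `lso_pair`: list with `original`, `mirrored`
#'   (tuning curves) and `difference` (data frame `ild`, `diffMean`,
#'   `diffSd`).
#' @export
mirroredPair <- function(curve) {
  s <- curve$stimulus
  if (!isTRUE(all.equal(sort(s), sort(-s))))
    stop("mirroring requires a symmetric ILD grid")
  idx <- match(-s, s) # position of -ild for each ild
  mir <- tuningCurve(s, curve$meanRate[idx], curve$sdRate[idx],
                     curve$fano[idx], attr(curve, "nTrials"),
                     attr(curve, "duration"), attr(curve, "task"))
  diff <- data.frame(ild = s,
                     diffMean = curve$meanRate - mir$meanRate,
                     diffSd = sqrt(curve$sdRate^2 + mir$sdRate^2))
  structure(list(original = curve, mirrored = mir, difference = diff,
                 shift = attr(curve, "shift")),
            class = "lso_pair")
}

#' Bilateral rate difference of a mirrored pair
#'
#' @param pair An [mirroredPair()] object.
#' @return Data frame with `ild`, `diffMean`, `diffSd`.
#' @export
bilateralDifference <- function(pair) {
  stopifnot(inherits(pair, "lso_pair"))
  pair$difference
}

#' Discriminability of the bilateral rate difference
#'
#' Applies the neighboring-pair d-prime statistic to the bilateral rate
#' difference of a mirrored pair.
#'
#' @param pair An [mirroredPair()] object.
#' @return An `lso_discrim` data frame (midpoint ILD, D).
#' @export
pairDiscriminability <- function(pair) {
  d <- pair$difference
  tc <- tuningCurve(d$ild, d$diffMean, d$diffSd,
                    nTrials = attr(pair$original, "nTrials"),
                    duration = attr(pair$original, "duration"))
  discriminability(tc)
}

#' Simulate a full mirrored-pair population
#'
#' Runs one shifted tuning curve per midpoint shift (each on its own RNG
#' substream block so pairs are mutually independent) and forms the mirrored
#' pairs.
#'
#' @param spec A [populationSpec()].
#' @param scenario An [scenarioSpec()].
#' @param nTrials,duration,dt,seed,model Passed to [runTuning()].
#' @return A list of `lso_pair` objects, class `lso_population`.
#' @export
runPopulation <- function(spec = populationSpec(), scenario = scenarioSpec(),
                          nTrials = 500, duration = 500, dt = 0.01, seed = 1,
                          model = "active") {
  pairs <- lapply(seq_along(spec$shifts), function(i) {
    tc <- shiftedTuning(spec$shifts[i], spec, scenario = scenario,
                        nTrials = nTrials, duration = duration, dt = dt,
                        seed = seed, model = model,
                        streamOffset = (i - 1) * 10000)
    mirroredPair(tc)
  })
  structure(pairs, class = "lso_population", spec = spec,
            scenario = scenario)
}

#' Population-averaged discriminability
#'
#' Averages the absolute discriminability functions of the bilateral rate
#' differences across mirrored pairs, then averages the resulting per-ILD
#' curve over `range`. Dividing by the same scalar of a reference scenario
#' gives the normalized population discriminability, which is invariant to
#' population size (duplicating every pair leaves it unchanged).
#'
#' @param pairs A list of `lso_pair` objects (e.g. [runPopulation()] output).
#' @param range ILD interval for the scalar average; defaults to `+/-35` dB.
#' @param referenceScalar Optional scalar of the reference scenario; when
#'   given, `scalar` is divided by it (`normalized`).
#' @return List with `curve` (data frame `midpoint`, `meanAbsD`), `scalar`,
#'   and `normalized` (NA unless a reference was supplied).
#' @export
populationDiscriminability <- function(pairs, range = c(-35, 35),
                                       referenceScalar = NULL) {
  if (length(pairs) == 0) stop("empty pair list")
  dmats <- lapply(pairs, function(p) abs(pairDiscriminability(p)$D))
  mids <- pairDiscriminability(pairs[[1]])$midpoint
  meanAbsD <- rowMeans(do.call(cbind, dmats))
  keep <- mids >= range[1] & mids <= range[2]
  if (!any(keep)) stop("no pairs inside the averaging range")
  scalar <- mean(meanAbsD[keep], na.rm = TRUE)
  list(curve = data.frame(midpoint = mids, meanAbsD = meanAbsD),
       scalar = scalar,
       normalized = if (is.null(referenceScalar)) NA_real_
                    else scalar / referenceScalar)
}
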