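#' Screen unknown products against a reference PLS-DA model
#'
#' Projects raw product fingerprints with the model's stored pretreatment
#' and flags "suspicious" samples — the formalization of the boundary drawn
#' around the authentic reference cluster in score space. A sample is
#' suspicious if (a) its Hotelling T2 distance to the declared class's
#' training score cloud exceeds the F-distribution critical value at
#' \code{alpha} (new-observation form), (b) its predicted class differs
#' from the declared class, or (c) its classification margin falls below
#' \code{marginMin}. No randomness is involved: verdicts are deterministic
#' given model and samples.
#'
#' @param model A [PlsdaModel-class] trained on authentic reference samples.
#' @param x Product fingerprints: a [TagFeatureMatrix-class] in state
#'   \code{"raw"} (or \code{"normalized"}) sharing the model's ion set.
#' @param declaredClass Declared species, one of the model's classes.
#' @param alpha Significance level of the T2 boundary (default 0.05).
#' @param marginMin Minimum acceptable classification margin (default 0,
#'   disabling rule (c)).
#' @return \code{data.frame} with one row per sample: \code{sample_id},
#'   \code{predicted}, \code{margin}, \code{hotellingT2}, \code{t2Critical},
#'   \code{suspicious}, \code{reason} (one of \code{"boundary_exceeded"},
#'   \code{"class_mismatch"}, \code{"low_margin"}, \code{"ok"}).
#' @examples
#' \dontrun{
#' verdicts <- screenSamples(model, products, declaredClass = "pork")
#' }
#' @export
screenSamples <- function(model, x, declaredClass, alpha = 0.05,
                          marginMin = 0) {
  if (!declaredClass %in% model@classes)
    stop("unknown declared class '", declaredClass, "'")
  Xs <- if (methods::is(x, "TagFeatureMatrix")) {
    if (featureState(x) == "pareto") intensityMatrix(x)
    else applyPretreatment(x, model)
  } else as.matrix(x)
  cls <- classifySamples(model, Xs)
  scores <- .projectScores(model, Xs)
  ref <- model@scores[model@labels == declaredClass, , drop = FALSE]
  nc <- nrow(ref); A <- ncol(ref)
  if (nc <= A)
    stop("declared class has too few training samples for a T2 boundary")
  mu <- colMeans(ref)
  S <- stats::cov(ref)
  t2 <- stats::mahalanobis(scores, mu, S)
  ## critical value for a NEW observation from the class
  crit <- A * (nc - 1) * (nc + 1) / (nc * (nc - A)) *
    stats::qf(1 - alpha, A, nc - A)
  reason <- rep("ok", nrow(Xs))
  reason[cls$margin < marginMin] <- "low_margin"
  reason[cls$predicted != declaredClass] <- "class_mismatch"
  reason[t2 > crit] <- "boundary_exceeded"
  data.frame(
    sample_id = cls$sample_id,
    predicted = cls$predicted,
    margin = cls$margin,
    hotellingT2 = as.numeric(t2),
    t2Critical = crit,
    suspicious = reason != "ok",
    reason = reason,
    stringsAsFactors = FALSE)
}

#' Admixture detection limit of the synthetic fingerprint model
#'
#' Estimates the smallest spike fraction at which an undeclared species is
#' detectable by the intensity-threshold rule: in at least \code{conf} of
#' replicates, the spike species' contribution to at least one of its
#' species-specific marker ions (markers associated with the spike species
#' but not the base species) exceeds \code{threshold} cps in the blended
#' spectrum. The contribution is read from the generator's exact
#' per-species component decomposition, which shares the replicate's noise
#' realization.
#'
#' @param baseSpecies,spikeSpecies Species names (spike is the admixture).
#' @param fractions Ascending grid of spike mass fractions in (0, 0.5].
#' @param nReps Replicates per fraction (default 200).
#' @param seed Integer seed.
#' @param threshold Detection threshold in cps (default 1000).
#' @param conf Required per-fraction detection rate (default 0.95).
#' @param profiles A \code{"SpeciesProfiles"} object.
#' @return List: \code{limit} (smallest detectable fraction, \code{NA} if
#'   none on the grid), \code{rates} (data.frame fraction/detection_rate),
#'   \code{markerIons} (the spike-specific ion labels used).
#' @examples
#' \dontrun{
#' detectionLimit("pork", "chicken", fractions = seq(0.01, 0.10, 0.01),
#'                seed = 1)
#' }
#' @export
detectionLimit <- function(baseSpecies, spikeSpecies,
                           fractions = seq(0.01, 0.10, by = 0.01),
                           nReps = 200, seed = 1, threshold = 1000,
                           conf = 0.95, profiles = defaultProfiles()) {
  if (!length(fractions)) stop("empty fraction grid")
  if (is.unsorted(fractions) || any(fractions < 0) || any(fractions > 0.5))
    stop("fractions must be ascending and in [0, 0.5]")
  lib <- markerLibrary()
  ions <- .speciesMarkers(lib, spikeSpecies, excluding = baseSpecies)
  if (!length(ions))
    stop("no markers specific to '", spikeSpecies, "' vs '", baseSpecies, "'")
  rates <- vapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    if (f == 0) return(0)
    fr <- stats::setNames(c(1 - f, f), c(baseSpecies, spikeSpecies))
    blends <- generateProduct(list(fractions = fr), nReps,
                              seed = seed + i, profiles = profiles,
                              keepComponents = TRUE)
    mean(vapply(blends, function(b) {
      comp <- attr(b, "components")
      max(comp[spikeSpecies, ions]) >= threshold
    }, logical(1)))
  }, numeric(1))
  hit <- which(rates >= conf)
  list(limit = if (length(hit)) fractions[min(hit)] else NA_real_,
       rates = data.frame(fraction = fractions, detection_rate = rates),
       markerIons = ions)
}
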