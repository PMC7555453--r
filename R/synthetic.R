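## Evaluate `code` under a private RNG stream seeded with `seed`, restoring
## the caller's RNG state afterwards.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

.SPECIES <- c("beef", "chicken", "pork")

## filler TAG compositions (n:d), even-carbon, not in the marker library,
## all with [M+NH4]+ m/z inside 800-1000 Th
.FILLER_TAGS <- list(
  c(48, 0), c(48, 1), c(48, 2), c(48, 3), c(48, 4),
  c(50, 4), c(50, 5), c(50, 6),
  c(52, 5), c(52, 6), c(52, 7),
  c(54, 7), c(54, 8),
  c(56, 0), c(56, 1), c(56, 2), c(56, 3), c(56, 4),
  c(56, 5), c(56, 6), c(56, 7), c(56, 8),
  c(58, 1), c(58, 2), c(58, 3)
)

## anchor intensity for a species' strongest species-specific marker: the
## mean cps such that an `anchorFraction` admixture contributes at least
## `threshold` cps with probability `anchorConfidence` under the lognormal
## noise model (per-ion sigma = log(1+cv), global scale sigma = scaleSigma)
.spikeAnchorMean <- function(cv, scaleSigma, threshold = 1000,
                             anchorFraction = 0.03, anchorConfidence = 0.975) {
  s2 <- log(1 + cv)^2 + scaleSigma^2
  threshold / anchorFraction *
    exp(s2 / 2 + stats::qnorm(anchorConfidence) * sqrt(s2))
}

#' Default synthetic TAG fingerprint profiles for beef, pork and chicken
#'
#' Builds the 40-compound ion panel (the 15 curated markers plus 25 filler
#' TAGs with even-carbon formulas in m/z 800-1000) and per-species mean
#' intensity profiles. Means are chosen to respect the qualitative dominance
#' structure of real fingerprints: chicken is dominated by the ions at
#' 848.7682, 874.7837 and 900.7996 Th, pork by 850.7836, 876.7995 and
#' 902.8148 Th, beef by 850.7836, 876.7995 and 904.8306 Th, with
#' non-dominant markers at 5-40\% of the dominant scale and every panel ion
#' above 1000 cps in every species. The strongest species-specific marker of
#' chicken (TAG C 52:3) and beef (TAG C 54:2) is set to the analytic spike
#' anchor: the mean at which a 3\% admixture contributes >= 1000 cps with
#' 97.5\% per-replicate probability under the noise model (so the
#' 95\%-of-replicates detection-limit rule concentrates on the 3\% anchor).
#'
#' @param cv Per-ion multiplicative noise coefficient of variation
#'   (lognormal sigma \code{log(1+cv)}; default 0.15).
#' @param scaleSigma Lognormal sigma of the shared per-sample scale factor
#'   emulating DART shot-to-shot signal variability (default 0.3).
#' @param mzJitterPpm Gaussian m/z jitter, in ppm (default 1).
#' @param threshold,anchorFraction,anchorConfidence Spike-anchor calibration
#'   (see Details above); defaults 1000 cps, 0.03, 0.975.
#' @param library Marker library (default [markerLibrary()]).
#' @return A list of class \code{"SpeciesProfiles"} with elements
#'   \code{panel} (data.frame: label, formula, mz, is_marker,
#'   marker_species), \code{means} (named list per species: named numeric
#'   mean cps per panel label), \code{cv}, \code{scaleSigma},
#'   \code{mzJitterPpm}.
#' @examples
#' pr <- defaultProfiles()
#' pr$means$chicken[["C 52:3"]] > pr$means$chicken[["C 52:2"]]   # TRUE
#' @export
defaultProfiles <- function(cv = 0.15, scaleSigma = 0.3, mzJitterPpm = 1,
                            threshold = 1000, anchorFraction = 0.03,
                            anchorConfidence = 0.975,
                            library = markerLibrary()) {
  anchor <- .spikeAnchorMean(cv, scaleSigma, threshold,
                             anchorFraction, anchorConfidence)
  fillerLabel <- vapply(.FILLER_TAGS, function(t)
    sprintf("C %d:%d", t[1], t[2]), character(1))
  fillerFormula <- vapply(.FILLER_TAGS, function(t) {
    f <- tagFormula(t[1], t[2])
    paste0("C", f[["C"]], "H", f[["H"]], "O", f[["O"]])
  }, character(1))
  fillerMz <- vapply(.FILLER_TAGS, function(t)
    ammoniumAdductMz(tagFormula(t[1], t[2])), numeric(1))
  panel <- rbind(
    data.frame(label = library$label, formula = library$formula,
               mz = library$annotated_mz, is_marker = TRUE,
               stringsAsFactors = FALSE),
    data.frame(label = fillerLabel, formula = fillerFormula,
               mz = fillerMz, is_marker = FALSE, stringsAsFactors = FALSE)
  )
  panel <- panel[order(panel$mz), , drop = FALSE]
  rownames(panel) <- NULL
  panel$marker_species <- lapply(panel$label, function(l) {
    i <- match(l, library$label)
    if (is.na(i)) character(0) else library$marker_species[[i]]
  })

  marker <- function(...) c(...)
  chicken <- marker(
    "C 50:3" = 15000, "C 50:2" = 100000, "C 50:1" = 42000, "C 50:0" = 10000,
    "C 52:4" = 10000, "C 52:3" = anchor, "C 52:2" = 20000, "C 52:1" = 8000,
    "C 52:0" = 5000, "C 54:6" = 8000, "C 54:5" = 12000,
    "C 54:4" = 0.75 * anchor, "C 54:3" = 12000, "C 54:2" = 5000,
    "C 54:1" = 5000)
  pork <- marker(
    "C 50:3" = 2500, "C 50:2" = 40000, "C 50:1" = 100000, "C 50:0" = 25000,
    "C 52:4" = 8000, "C 52:3" = 10000, "C 52:2" = 95000, "C 52:1" = 35000,
    "C 52:0" = 12000, "C 54:6" = 1500, "C 54:5" = 2500, "C 54:4" = 5000,
    "C 54:3" = 70000, "C 54:2" = 15000, "C 54:1" = 3000)
  beef <- marker(
    "C 50:3" = 3000, "C 50:2" = 15000, "C 50:1" = 70000, "C 50:0" = 15000,
    "C 52:4" = 5000, "C 52:3" = 8000, "C 52:2" = 100000, "C 52:1" = 30000,
    "C 52:0" = 10000, "C 54:6" = 2000, "C 54:5" = 3000, "C 54:4" = 5000,
    "C 54:3" = 40000, "C 54:2" = anchor, "C 54:1" = 20000)
  filler <- stats::setNames(2000 + 250 * seq_along(fillerLabel), fillerLabel)
  means <- list(
    beef = c(beef, filler)[panel$label],
    chicken = c(chicken, filler)[panel$label],
    pork = c(pork, filler)[panel$label]
  )
  for (s in names(means)) names(means[[s]]) <- panel$label
  structure(
    list(panel = panel, means = means, cv = cv, scaleSigma = scaleSigma,
         mzJitterPpm = mzJitterPpm),
    class = "SpeciesProfiles")
}

## one synthetic spectrum: returns list(mz, intensity, ionFactor, scale)
.simulateSpectrum <- function(meanInt, mzRef, cv, scaleSigma, mzJitterPpm) {
  sigmaIon <- log(1 + cv)
  ionFactor <- if (sigmaIon > 0)
    stats::rlnorm(length(meanInt), meanlog = -sigmaIon^2 / 2, sdlog = sigmaIon)
  else rep(1, length(meanInt))
  scale <- if (scaleSigma > 0)
    stats::rlnorm(1, meanlog = -scaleSigma^2 / 2, sdlog = scaleSigma)
  else 1
  mz <- mzRef * (1 + stats::rnorm(length(mzRef), 0, mzJitterPpm * 1e-6))
  list(mz = mz, intensity = meanInt * ionFactor * scale,
       ionFactor = ionFactor, scale = scale)
}

#' Generate synthetic pure-meat fingerprints
#'
#' Draws \code{nSamples} DART-HRMS-like TAG peak lists for one species:
#' intensity = profile mean x per-ion lognormal noise x a shared per-sample
#' lognormal scale factor; m/z = panel m/z x (1 + N(0, jitter ppm)).
#' Reproducible under a fixed seed; the caller's RNG state is untouched.
#'
#' @param species \code{"beef"}, \code{"pork"} or \code{"chicken"}.
#' @param nSamples Number of samples (>= 1).
#' @param seed Integer seed.
#' @param profiles A \code{"SpeciesProfiles"} object ([defaultProfiles()]).
#' @return Named list of [PeakList-class] objects
#'   (\code{<species>_1 ...}).
#' @examples
#' pk <- generatePure("chicken", 2, seed = 1)
#' @export
generatePure <- function(species, nSamples, seed, profiles = defaultProfiles()) {
  if (!species %in% .SPECIES) stop("unknown species '", species, "'")
  if (nSamples < 1) stop("nSamples must be >= 1")
  fr <- stats::setNames(numeric(length(.SPECIES)), .SPECIES)
  fr[species] <- 1
  out <- generateProduct(list(fractions = fr, background_level = 0),
                         nSamples, seed, profiles = profiles)
  names(out) <- paste0(species, "_", seq_len(nSamples))
  for (i in seq_along(out)) out[[i]]@sampleId <- names(out)[i]
  out
}

## background/ingredient ions: fixed m/z placed far (>>20 ppm) from every
## panel ion
.BACKGROUND_MZ <- c(812.3456, 835.1122, 951.7788)
.BACKGROUND_CPS <- c(5000, 3000, 2000)

#' Generate synthetic meat-product fingerprints
#'
#' Mean intensities are the fraction-weighted convex combination of the
#' species profiles; noise is as in [generatePure()]. Optional low-level
#' background ions (emulating non-TAG ingredient signals) are placed off the
#' marker m/z grid.
#'
#' @param recipe List with \code{fractions} (named numeric over species,
#'   summing to 1), optional \code{background_level} (relative scale of
#'   background ions, default 0) and optional \code{label} (declared
#'   composition text).
#' @param nSamples Number of samples.
#' @param seed Integer seed.
#' @param profiles A \code{"SpeciesProfiles"} object.
#' @param keepComponents Logical; attach, per sample, the species x ion
#'   matrix of each species' intensity contribution (attribute
#'   \code{"components"}). The decomposition shares the sample's noise
#'   factors, so components sum exactly to the panel intensities.
#' @return Named list of [PeakList-class] objects.
#' @examples
#' blend <- generateProduct(
#'   list(fractions = c(pork = 0.8, chicken = 0.2)), 1, seed = 3)
#' @export
generateProduct <- function(recipe, nSamples, seed,
                            profiles = defaultProfiles(),
                            keepComponents = FALSE) {
  fr <- recipe$fractions
  if (is.null(names(fr)) || any(!names(fr) %in% .SPECIES))
    stop("recipe fractions must be named by species (beef/pork/chicken)")
  if (any(fr < 0)) stop("recipe fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) stop("recipe fractions must sum to 1")
  if (nSamples < 1) stop("nSamples must be >= 1")
  bg <- recipe$background_level
  if (is.null(bg)) bg <- 0
  panel <- profiles$panel
  meanMix <- Reduce(`+`, lapply(names(fr), function(s)
    fr[[s]] * profiles$means[[s]]))
  .withSeed(seed, {
    out <- lapply(seq_len(nSamples), function(i) {
      sp <- .simulateSpectrum(meanMix, panel$mz, profiles$cv,
                              profiles$scaleSigma, profiles$mzJitterPpm)
      mz <- sp$mz; inten <- sp$intensity
      if (bg > 0) {
        mz <- c(mz, .BACKGROUND_MZ)
        inten <- c(inten, bg * .BACKGROUND_CPS * sp$scale)
      }
      pk <- PeakList(sprintf("product_%d", i), mz, inten)
      if (keepComponents) {
        comp <- do.call(rbind, lapply(names(fr), function(s)
          fr[[s]] * profiles$means[[s]] * sp$ionFactor * sp$scale))
        rownames(comp) <- names(fr)
        colnames(comp) <- panel$label
        attr(pk, "components") <- comp
      }
      pk
    })
    names(out) <- vapply(out, sampleId, character(1))
    out
  })
}

#' Assemble a randomized acquisition sequence with QC pools and blanks
#'
#' Test samples are placed in a seeded random order; a pooled QC spectrum
#' (the arithmetic mean of all sample peak lists) leads the sequence and is
#' re-injected after every \code{qcPeriod} test samples; blank injections
#' open and close the sequence.
#'
#' @param samples Named list of [PeakList-class] objects (role
#'   \code{"sample"}).
#' @param qcPeriod QC insertion period (>= 1; default 10).
#' @param seed Integer seed for the run-order permutation.
#' @param blankLevel Intensity (cps) of the residual background ions in
#'   blank injections (default 200).
#' @return List of class \code{"AcquisitionSequence"}: \code{order}
#'   (data.frame position/sample_id/role), \code{peakLists} (all injections,
#'   in order, with run indices set), \code{qcPeriod}, \code{seed}.
#' @examples
#' seqn <- buildSequence(generatePure("pork", 12, seed = 1), seed = 2)
#' seqn$order$role
#' @export
buildSequence <- function(samples, qcPeriod = 10, seed, blankLevel = 200) {
  if (length(samples) < 1) stop("need at least one sample")
  if (qcPeriod < 1) stop("qcPeriod must be >= 1")
  qc <- .poolSpectrum(samples)
  blank <- function(id) PeakList(id, .BACKGROUND_MZ,
                                 rep(blankLevel, length(.BACKGROUND_MZ)),
                                 role = "blank")
  perm <- .withSeed(seed, sample(seq_along(samples)))
  ordered <- samples[perm]
  entries <- list(blank("blank_start"), .asQc(qc, "QC_0"))
  qcCount <- 0L
  for (i in seq_along(ordered)) {
    entries[[length(entries) + 1L]] <- ordered[[i]]
    if (i %% qcPeriod == 0L && i < length(ordered) + 1L) {
      qcCount <- qcCount + 1L
      entries[[length(entries) + 1L]] <- .asQc(qc, paste0("QC_", qcCount))
    }
  }
  entries[[length(entries) + 1L]] <- blank("blank_end")
  for (i in seq_along(entries)) entries[[i]]@runIndex <- i
  ord <- data.frame(
    position = seq_along(entries),
    sample_id = vapply(entries, sampleId, character(1)),
    role = vapply(entries, peakRole, character(1)),
    stringsAsFactors = FALSE
  )
  names(entries) <- ord$sample_id
  structure(list(order = ord, peakLists = entries, qcPeriod = qcPeriod,
                 seed = seed),
            class = "AcquisitionSequence")
}

.asQc <- function(qc, id) {
  qc@sampleId <- id
  qc@role <- "QC"
  qc
}

## arithmetic mean spectrum: peaks are clustered by sorting all m/z and
## splitting at gaps > 0.05 Th (panel spacing >= 1.5 Th, jitter ~ 1 ppm);
## peaks absent from a sample count as zero
.poolSpectrum <- function(samples) {
  all <- do.call(rbind, lapply(samples, peakTable))
  o <- order(all$mz)
  all <- all[o, , drop = FALSE]
  grp <- cumsum(c(1, diff(all$mz) > 0.05))
  mz <- tapply(all$mz, grp, mean)
  total <- tapply(all$intensity, grp, sum)
  PeakList("QC_pool", as.numeric(mz), as.numeric(total) / length(samples),
           role = "QC")
}

#' Generate a synthetic declarations/PCR-calls dataset
#'
#' Fixture source for the label-compliance checker: random declared species
#' compositions over four product types; real-time (gDNA) multiplex calls
#' always consistent with the declaration; endpoint mitochondrial multiplex
#' calls carrying seeded false negatives, at the given rate, in fat-rich
#' product types (luncheon meat and meat in natural juices) — emulating the
#' poor mtDNA recovery from white adipose tissue.
#'
#' @param nSamples Number of samples.
#' @param discrepancyRate Probability, per fat-rich sample, of one
#'   false-negative mitochondrial call (0..1).
#' @param seed Integer seed.
#' @return List with data.frames \code{declarations} (sample_id,
#'   product_type, pork/chicken/beef as "+"/"-"), \code{mpcr} and
#'   \code{mqpcr} (sample_id, assay, pork/chicken/beef).
#' @export
generatePcrDataset <- function(nSamples, discrepancyRate, seed) {
  if (discrepancyRate < 0 || discrepancyRate > 1)
    stop("discrepancyRate must be in [0, 1]")
  types <- c("ham", "sausage", "luncheon", "natural_juices")
  .withSeed(seed, {
    productType <- sample(types, nSamples, replace = TRUE)
    species <- c("pork", "chicken", "beef")
    decl <- t(vapply(seq_len(nSamples), function(i) {
      d <- stats::runif(3) < c(0.8, 0.4, 0.4)
      if (!any(d)) d[sample(3, 1)] <- TRUE
      d
    }, logical(3)))
    colnames(decl) <- species
    mpcr <- decl
    fatRich <- productType %in% c("luncheon", "natural_juices")
    for (i in which(fatRich)) {
      if (stats::runif(1) < discrepancyRate) {
        present <- which(decl[i, ])
        drop <- if (length(present) == 1L) present else sample(present, 1)
        mpcr[i, drop] <- FALSE
      }
    }
    enc <- function(m) ifelse(m, "+", "-")
    ids <- paste0("S", seq_len(nSamples))
    list(
      declarations = data.frame(sample_id = ids, product_type = productType,
                                enc(decl), stringsAsFactors = FALSE),
      mpcr = data.frame(sample_id = ids, assay = "mpcr", enc(mpcr),
                        stringsAsFactors = FALSE),
      mqpcr = data.frame(sample_id = ids, assay = "mqpcr", enc(decl),
                         stringsAsFactors = FALSE)
    )
  })
}
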