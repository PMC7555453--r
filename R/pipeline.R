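#' Default end-to-end demonstration configuration
#'
#' Mirrors the reference study design: 3 pure samples per species for the
#' training model and 27 retail-style products screened against it, with a
#' QC-pooled acquisition sequence, 7-fold cross-validation and a
#' permutation test.
#'
#' @param outDir Output directory for run artifacts.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @return A named list (the run configuration).
#' @export
defaultPipelineConfig <- function(outDir = tempfile("tagprint_run_"),
                                  seed = 42) {
  list(
    outDir = outDir,
    seed = seed,
    nPerClass = 3,
    nProducts = 27,
    tolPpm = 5,
    minCps = 1000,
    cvFolds = 7,
    nPermutations = 99,
    alpha = 0.05,
    qcPeriod = 10,
    libraryFile = NULL
  )
}

.validateConfig <- function(config) {
  need <- c("outDir", "seed", "nPerClass", "nProducts", "tolPpm", "minCps",
            "cvFolds", "nPermutations", "alpha", "qcPeriod")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("pipeline config is missing field(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(config$libraryFile) && !file.exists(config$libraryFile))
    stop("marker library file not found: ", config$libraryFile)
  invisible(config)
}

#' Run the full authentication pipeline
#'
#' simulate -> sequence -> annotate -> preprocess -> train -> screen ->
#' comply. Generates pure-meat training fingerprints and blended products,
#' annotates them against the marker library, builds and pretreats the
#' 15-ion feature matrix, fits the three-species PLS-DA reference model
#' with its full quality apparatus (R2X, R2Y, cross-validated Q2,
#' recognition and prediction ability, permutation p), screens every
#' product against its declared species, runs the declared-vs-PCR
#' compliance check on a synthetic call set, and writes all artifacts
#' (matrices, verdicts, compliance report, \code{metrics.json}) to the run
#' directory. Identical config and seed give identical metrics.
#'
#' @param config List from [defaultPipelineConfig()] (possibly modified).
#' @return The metrics list, invisibly; artifacts on disk under
#'   \code{config$outDir}.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  .validateConfig(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  lib <- markerLibrary(config$libraryFile)
  profiles <- defaultProfiles(threshold = config$minCps)

  ## -- simulate training meats and products --
  train <- c(generatePure("beef", config$nPerClass, seed + 1, profiles),
             generatePure("chicken", config$nPerClass, seed + 2, profiles),
             generatePure("pork", config$nPerClass, seed + 3, profiles))
  trainLabels <- sub("_[0-9]+$", "", names(train))
  recipes <- .demoRecipes(config$nProducts, seed + 4)
  products <- list()
  for (i in seq_along(recipes)) {
    pk <- generateProduct(recipes[[i]], 1, seed + 100 + i, profiles)[[1]]
    pk@sampleId <- sprintf("product_%02d", i)
    products[[pk@sampleId]] <- pk
  }
  seqn <- buildSequence(c(train, products), qcPeriod = config$qcPeriod,
                        seed = seed + 5)
  utils::write.csv(seqn$order, file.path(config$outDir, "sequence.csv"),
                   row.names = FALSE)

  ## -- annotate + preprocess --
  tabs <- annotateSamples(c(train, products), lib,
                          tolPpm = config$tolPpm,
                          minIntensity = config$minCps)
  labels <- c(stats::setNames(trainLabels, names(train)),
              stats::setNames(vapply(recipes, function(r)
                names(which.max(r$fractions)), character(1)),
                names(products)))
  fm <- buildFeatureMatrix(tabs, classLabels = labels)
  utils::write.csv(intensityMatrix(fm),
                   file.path(config$outDir, "matrix_raw.csv"))
  fmTrain <- fm[, names(train)]
  fmTrain <- paretoScale(rowSumNormalize(fmTrain))

  ## -- train + validate --
  model <- fitPlsda(fmTrain, trainLabels)
  q2 <- q2Cv(fm[, names(train)], trainLabels, k = config$cvFolds,
             seed = seed + 6)
  recog <- recognitionAbility(model, fmTrain, trainLabels)
  predAb <- predictionAbility(fm[, names(train)], trainLabels,
                              k = config$cvFolds, seed = seed + 6)
  perm <- permutationTest(fm[, names(train)], trainLabels,
                          nPerm = config$nPermutations, seed = seed + 7)
  if (!is.na(q2) && q2 > model@R2Y)
    warning("Q2 exceeds R2Y; the model is suspect")

  ## -- screen products against their declared species --
  verdicts <- do.call(rbind, lapply(seq_along(products), function(i) {
    declared <- labels[[names(products)[i]]]
    v <- screenSamples(model, fm[, names(products)[i], drop = FALSE],
                       declaredClass = declared, alpha = config$alpha)
    v$declared <- declared
    v
  }))
  utils::write.csv(verdicts, file.path(config$outDir, "verdicts.csv"),
                   row.names = FALSE)

  ## -- compliance on the packaged transcription --
  report <- checkCompliance(parseSpeciesCalls())
  utils::write.csv(report, file.path(config$outDir, "compliance.csv"),
                   row.names = FALSE)

  metrics <- list(
    seed = seed,
    n_training = length(train),
    n_products = length(products),
    R2X = model@R2X,
    R2Y = model@R2Y,
    Q2 = q2,
    recognition = recog,
    prediction = predAb,
    permutation_p = perm$pValue,
    n_suspicious = sum(verdicts$suspicious),
    n_label_compliant = sum(report$label_compliant),
    n_mt_gdna_discrepant = sum(report$mt_gdna_discrepant)
  )
  jsonlite::write_json(metrics, file.path(config$outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}

## retail-style product recipes: mostly pork products, a few chicken hams,
## one beef-dominated can, a few with undeclared chicken admixture
.demoRecipes <- function(n, seed) {
  .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      kind <- sample(c("pork", "pork_beef", "chicken", "beef70"), 1,
                     prob = c(0.45, 0.3, 0.15, 0.1))
      fr <- switch(kind,
        pork = c(pork = 1),
        pork_beef = {
          b <- stats::runif(1, 0.1, 0.4); c(pork = 1 - b, beef = b)
        },
        chicken = c(chicken = 1),
        beef70 = c(beef = 0.7, pork = 0.3))
      list(fractions = fr, background_level = stats::runif(1, 0, 0.5))
    })
  })
}
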