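# shared fixtures: built in code, small enough for fast repeated use

stickSpectrum <- function(library = markerLibrary(), intensity = 1e4,
                          id = "stick") {
  PeakList(id, library$annotated_mz, rep(intensity, nrow(library)))
}

# annotated + labeled feature matrix for n samples/class of pure meats
pureMeatMatrix <- function(nPerClass = 3, seed = 1,
                           profiles = defaultProfiles(),
                           lib = markerLibrary()) {
  pk <- c(generatePure("beef", nPerClass, seed, profiles),
          generatePure("chicken", nPerClass, seed + 1, profiles),
          generatePure("pork", nPerClass, seed + 2, profiles))
  labels <- sub("_[0-9]+$", "", names(pk))
  buildFeatureMatrix(annotateSamples(pk, lib),
                     classLabels = stats::setNames(labels, names(pk)))
}

# wrap an arbitrary samples x ions value matrix as a raw TagFeatureMatrix
matrixFromValues <- function(vals, classLabels = NULL) {
  if (is.null(rownames(vals))) rownames(vals) <- paste0("s", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- paste0("ion", seq_len(ncol(vals)))
  tabs <- lapply(seq_len(nrow(vals)), function(i) {
    data.frame(label = colnames(vals), theoretical_mz = NA_real_,
               annotated_mz = NA_real_, matched_mz = NA_real_,
               ppm_error = NA_real_, intensity = as.numeric(vals[i, ]),
               stringsAsFactors = FALSE)
  })
  names(tabs) <- rownames(vals)
  buildFeatureMatrix(tabs, classLabels = classLabels)
}

# two-class chicken/pork matrix (meats plus pork-recipe products)
chickenPorkMatrix <- function(nPerClass = 10, nProducts = 5, seed = 7,
                              profiles = defaultProfiles(),
                              lib = markerLibrary()) {
  pk <- c(generatePure("chicken", nPerClass, seed, profiles),
          generatePure("pork", nPerClass, seed + 1, profiles))
  if (nProducts > 0) {
    prod <- generateProduct(list(fractions = c(pork = 1)), nProducts,
                            seed + 2, profiles)
    names(prod) <- paste0("porkprod_", seq_len(nProducts))
    for (i in seq_along(prod)) prod[[i]]@sampleId <- names(prod)[i]
    pk <- c(pk, prod)
  }
  labels <- ifelse(grepl("^chicken", names(pk)), "chicken", "pork")
  buildFeatureMatrix(annotateSamples(pk, lib),
                     classLabels = stats::setNames(labels, names(pk)))
}
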