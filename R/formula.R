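#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula such as \code{"C55H104NO6"} into a
#' named integer vector of element counts. The underscore markup sometimes
#' used in typeset tables (\code{"C_53_H_102_NO_6_"}) is accepted and
#' stripped before parsing. Element symbols are case-sensitive: \code{"CO"}
#' is carbon + oxygen, while \code{"Co"} is rejected as unknown.
#'
#' @param text Character scalar, the formula.
#' @return Named integer vector of element counts (elements with count 0 are
#'   dropped). An empty vector is never returned: an empty or blank string is
#'   an error.
#' @examples
#' parseFormula("C_53_H_102_NO_6_")
#' parseFormula("H2O")
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  clean <- gsub("_", "", text, fixed = TRUE)
  clean <- gsub("[[:space:]]", "", clean)
  if (!nzchar(clean))
    stop("cannot parse an empty formula")
  ## tokens: an upper-case letter, optional lower-case letter, optional count
  m <- gregexpr("[A-Z][a-z]?[0-9]*", clean)[[1]]
  tokens <- regmatches(clean, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(clean))
    stop("malformed formula: '", text, "'")
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.ATOMIC_MASS))
      stop("unknown element symbol '", sym, "' in formula '", text, "'")
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  counts <- counts[counts > 0L]
  if (length(counts) == 0L)
    stop("formula '", text, "' contains no atoms")
  counts
}

#' Add two elemental formulas
#'
#' @param a,b Named integer vectors as returned by [parseFormula()].
#' @return Named integer vector with summed element counts.
#' @examples
#' addFormulas(parseFormula("C55H100O6"), parseFormula("NH4"))
#' @export
addFormulas <- function(a, b) {
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    sum(c(a[e], b[e]), na.rm = TRUE)
  }, numeric(1))
  out <- as.integer(round(out))
  names(out) <- els
  out[out > 0L]
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums most-abundant-isotope atomic masses. For a singly charged cation the
#' mass of one electron is subtracted (configurable), giving m/z in Th.
#'
#' @param formula Named integer vector of element counts
#'   ([parseFormula()] output) or a formula string.
#' @param charge Integer, 0 (neutral mass in Da) or +1 (cation m/z in Th).
#' @param electronCorrection Logical; subtract the electron mass per positive
#'   charge (default \code{TRUE}). The convention is configurable because
#'   some instrument software reports ion m/z without the correction.
#' @return Numeric scalar: mass in Da (charge 0) or m/z in Th (charge +1).
#'   An empty (length-0) formula gives 0.
#' @examples
#' monoisotopicMass(parseFormula("H2O"))                # 18.010565
#' monoisotopicMass("C53H102NO6", charge = 1)          # 848.77017
#' @export
monoisotopicMass <- function(formula, charge = 0L, electronCorrection = TRUE) {
  if (is.character(formula)) formula <- parseFormula(formula)
  if (!charge %in% c(0L, 1L))
    stop("only charge 0 or +1 is supported")
  if (length(formula) == 0L) return(0)
  unknown <- setdiff(names(formula), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  mass <- sum(.ATOMIC_MASS[names(formula)] * as.numeric(formula))
  if (charge == 1L && electronCorrection)
    mass <- mass - .ELECTRON_MASS
  mass
}

#' Theoretical m/z of the ammonium adduct of a neutral TAG
#'
#' Computes the \eqn{[M+NH_4]^+} m/z of a neutral triacylglycerol:
#' the monoisotopic mass of the composite formula (neutral + NH4) minus one
#' electron mass. Identical, by construction, to calling
#' [monoisotopicMass()] on the composite formula with \code{charge = 1}.
#'
#' @param neutral Neutral TAG formula (string or [parseFormula()] output).
#'   A triacylglycerol has exactly 6 oxygens; other oxygen counts trigger a
#'   warning, or an error when \code{strict = TRUE}.
#' @param strict Logical; escalate the oxygen-count check to an error.
#' @return m/z in Th.
#' @examples
#' ammoniumAdductMz("C55H100O6")   # TAG 52:3 -> 874.78582
#' @export
ammoniumAdductMz <- function(neutral, strict = FALSE) {
  if (is.character(neutral)) neutral <- parseFormula(neutral)
  nO <- if ("O" %in% names(neutral)) neutral[["O"]] else 0L
  if (nO != 6L) {
    msg <- sprintf("formula has %d oxygens; a neutral TAG has 6", nO)
    if (strict) stop(msg) else warning(msg)
  }
  adduct <- addFormulas(neutral, c(N = 1L, H = 4L))
  monoisotopicMass(adduct, charge = 1L)
}

#' Signed relative mass error in parts per million
#'
#' @param observed,theoretical m/z values in Th; \code{theoretical} must be
#'   strictly positive.
#' @return \code{(observed - theoretical) / theoretical * 1e6}, vectorised.
#' @examples
#' ppmError(848.7682, 848.77017)   # about -2.3 ppm
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0))
    stop("theoretical m/z must be > 0")
  (observed - theoretical) / theoretical * 1e6
}
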