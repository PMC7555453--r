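## Monoisotopic atomic masses (most abundant isotope), CODATA/NIST, in Da.
## Values carry >= 7 decimals; all mass arithmetic in the package goes
## through this table.
.ATOMIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0000000000,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  P  = 30.9737616320,
  S  = 31.9720710015,
  Cl = 34.9688526820,
  K  = 38.9637064864
)

## CODATA electron mass in Da; subtracted once per positive charge.
.ELECTRON_MASS <- 0.000548579909

#' Supported element symbols and their monoisotopic masses
#'
#' Returns the table of monoisotopic (most-abundant-isotope) atomic masses
#' used by all mass calculations in the package.
#'
#' @return Named numeric vector of masses in Da, named by element symbol.
#' @examples
#' atomicMasses()[["O"]]
#' @export
atomicMasses <- function() .ATOMIC_MASS
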