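# Unit handling (CODATA-2018 factors).

HARTREE_EV <- 27.211386245988
HARTREE_CM1 <- 219474.6313632
FINE_STRUCTURE <- 7.2973525693e-3
SPEED_OF_LIGHT_AU <- 137.035999084
ROTATORY_AU_TO_CGS40 <- 471.44360760  # 1 au -> 10^-40 esu^2 cm^2

#' Convert energies / frequencies between supported units
#'
#' Supported units: `"hartree"` (alias `"au"`), `"ev"`, `"cm-1"`. Round
#' trips are exact to floating-point precision.
#'
#' @param value numeric vector.
#' @param from,to unit names (case-insensitive).
#' @export
convert_units <- function(value, from, to) {
  norm <- function(u) {
    u <- tolower(u)
    if (u %in% c("hartree", "au", "a.u.")) return("hartree")
    if (u %in% c("ev")) return("ev")
    if (u %in% c("cm-1", "cm^-1", "wavenumber", "rcm")) return("cm-1")
    stop("unsupported unit ", sQuote(u), "; supported: hartree/au, eV, cm-1")
  }
  from <- norm(from); to <- norm(to)
  to_hartree <- switch(from, hartree = 1, ev = 1 / HARTREE_EV,
                       `cm-1` = 1 / HARTREE_CM1)
  from_hartree <- switch(to, hartree = 1, ev = HARTREE_EV,
                         `cm-1` = HARTREE_CM1)
  value * to_hartree * from_hartree
}
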