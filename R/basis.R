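# Basis-set registry.
#
# Two layers: (i) shell-composition tables for counting contracted functions
# (enough for sizing calculations in larger correlation-consistent / Pople
# sets), and (ii) full exponent/coefficient data for the bases the integral
# engine can run (STO-3G for H..Ne, 6-31G for H and O). STO-3G is stored as
# the universal three-Gaussian expansions of 1s and 2sp Slater functions at
# zeta = 1 together with the standard molecular Slater exponents; actual
# exponents scale as zeta^2.

# shells-per-l by element row: list(basis -> list(range_name -> c(s,p,d,f)))
.BASIS_COUNTS <- list(
  "sto-3g"      = list(row1 = c(1, 0, 0), row2 = c(2, 1, 0), row3 = c(3, 2, 0)),
  "6-31g"       = list(row1 = c(2, 0, 0), row2 = c(3, 2, 0)),
  "6-31g**"     = list(row1 = c(2, 1, 0), row2 = c(3, 2, 1)),
  "6-311g**"    = list(row1 = c(3, 1, 0), row2 = c(4, 3, 1)),
  "cc-pvdz"     = list(row1 = c(2, 1, 0), row2 = c(3, 2, 1)),
  "aug-cc-pvdz" = list(row1 = c(3, 2, 0), row2 = c(4, 3, 2))
)

.element_row <- function(z) {
  if (z <= 2) "row1" else if (z <= 10) "row2" else "row3"
}

#' Count contracted basis functions
#'
#' Sums the number of contracted functions a named standard Gaussian basis
#' assigns to every atom of a molecule: `2l+1` per shell of angular momentum
#' `l` for spherical harmonics, `(l+1)(l+2)/2` for Cartesian components.
#'
#' @param mol an `adc_molecule`.
#' @param basis basis-set name (case-insensitive), e.g. `"aug-cc-pVDZ"`.
#' @param spherical use spherical-harmonic components (default) rather than
#'   Cartesian ones.
#' @return integer count of contracted basis functions.
#' @examples
#' count_contracted_basis(molecule_fixture("h2"), "sto-3g")
#' @export
count_contracted_basis <- function(mol, basis, spherical = TRUE) {
  key <- tolower(basis)
  tab <- .BASIS_COUNTS[[key]]
  if (is.null(tab))
    stop("basis ", sQuote(basis), " not in the counting registry; known: ",
         paste(names(.BASIS_COUNTS), collapse = ", "))
  zs <- atomic_numbers(mol)
  total <- 0L
  for (z in zs) {
    row <- .element_row(z)
    shells <- tab[[row]]
    if (is.null(shells))
      stop("basis ", sQuote(basis), " has no definition for element Z=", z)
    l <- seq_along(shells) - 1L
    per <- if (spherical) 2L * l + 1L else ((l + 1L) * (l + 2L)) %/% 2L
    total <- total + sum(shells * per)
  }
  as.integer(total)
}

# --- integral-capable basis data ------------------------------------------

.STO3G_1S_EXP <- c(2.227660584, 0.405771156, 0.109818036)
.STO3G_1S_COEF <- c(0.154328967, 0.535328142, 0.444634542)
.STO3G_2SP_EXP <- c(0.994203, 0.231031, 0.0751386)
.STO3G_2S_COEF <- c(-0.09996723, 0.39951283, 0.70011547)
.STO3G_2P_COEF <- c(0.15591627, 0.60768372, 0.39195739)
# standard molecular Slater exponents (zeta_1s, zeta_2sp)
.STO3G_ZETA <- list(H = c(1.24), He = c(1.69),
                    Li = c(2.69, 0.80), Be = c(3.68, 1.15), B = c(4.68, 1.45),
                    C = c(5.67, 1.72), N = c(6.67, 1.95), O = c(7.66, 2.25),
                    F = c(8.65, 2.55), Ne = c(9.64, 2.88))

.sto3g_element <- function(symbol) {
  zeta <- .STO3G_ZETA[[symbol]]
  if (is.null(zeta))
    stop("STO-3G integral data not available for element ", symbol)
  shells <- list(list(l = 0L, exps = .STO3G_1S_EXP * zeta[1]^2,
                      coefs = .STO3G_1S_COEF))
  if (length(zeta) > 1) {
    sp <- .STO3G_2SP_EXP * zeta[2]^2
    shells <- c(shells,
                list(list(l = 0L, exps = sp, coefs = .STO3G_2S_COEF),
                     list(l = 1L, exps = sp, coefs = .STO3G_2P_COEF)))
  }
  shells
}

.B631G <- list(
  H = list(
    list(l = 0L, exps = c(18.73113696, 2.825394365, 0.6401216923),
         coefs = c(0.03349460434, 0.2347269535, 0.8137573261)),
    list(l = 0L, exps = 0.1612777588, coefs = 1.0)),
  O = list(
    list(l = 0L,
         exps = c(5484.671660, 825.2349460, 188.0469580, 52.96450000,
                  16.89757040, 5.799635340),
         coefs = c(0.001831074430, 0.01395017220, 0.06844507810,
                   0.2327143360, 0.4701928980, 0.3585208530)),
    list(l = 0L, exps = c(15.53961625, 3.599933586, 1.013761750),
         coefs = c(-0.1107775495, -0.1480262627, 1.130767015)),
    list(l = 1L, exps = c(15.53961625, 3.599933586, 1.013761750),
         coefs = c(0.07087426823, 0.3397528391, 0.7271585773)),
    list(l = 0L, exps = 0.2700058226, coefs = 1.0),
    list(l = 1L, exps = 0.2700058226, coefs = 1.0))
)

#' Shell list for an integral-capable basis
#'
#' Expands a molecule into a list of contracted shells
#' `(l, center [bohr], exps, coefs)` for the bases with embedded primitive
#' data (`"sto-3g"` for H..Ne, `"6-31g"` for H and O).
#'
#' @inheritParams count_contracted_basis
#' @return list of shells.
#' @export
basis_shells <- function(mol, basis) {
  key <- tolower(basis)
  xyz <- mol$coords * ANGSTROM_TO_BOHR
  out <- list()
  for (k in seq_along(mol$symbols)) {
    sym <- mol$symbols[k]
    sh <- if (key == "sto-3g") {
      .sto3g_element(sym)
    } else if (key == "6-31g") {
      el <- .B631G[[sym]]
      if (is.null(el))
        stop("6-31G integral data not available for element ", sym)
      el
    } else {
      stop("no integral data for basis ", sQuote(basis),
           "; integral-capable bases: sto-3g, 6-31g")
    }
    for (s in sh) {
      s$center <- xyz[k, ]
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
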