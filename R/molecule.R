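#' @useDynLib adcfold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
#' @importFrom utils head tail write.csv
NULL

# element symbol -> (atomic number, standard atomic weight)
.ELEMENTS <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar")
  mass <- c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
            18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06,
            35.45, 39.948)
  data.frame(symbol = sym, z = seq_along(sym), mass = mass,
             stringsAsFactors = FALSE)
})

ANGSTROM_TO_BOHR <- 1.8897261254578281

#' Create a molecule
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param charge total charge (integer).
#' @param multiplicity spin multiplicity; all correlated modules require a
#'   closed-shell singlet (multiplicity 1).
#' @return An object of class `adc_molecule`.
#' @export
molecule <- function(symbols, coords, charge = 0L, multiplicity = 1L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(symbols) < 1L) stop("molecule needs at least one atom")
  if (nrow(coords) != length(symbols))
    stop("coords must have one row per atom")
  if (any(!is.finite(coords))) stop("non-finite coordinate")
  unknown <- setdiff(symbols, .ELEMENTS$symbol)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  structure(list(symbols = as.character(symbols), coords = coords,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity)),
            class = "adc_molecule")
}

#' Parse XYZ-format text
#'
#' Standard two-header-line XYZ dialect: first line is the atom count, the
#' second a free-form comment, then one `symbol x y z` line per atom with
#' coordinates in Angstrom.
#'
#' @param text a character scalar (possibly multi-line) or character vector
#'   of lines.
#' @param charge,multiplicity passed to [molecule()].
#' @return An `adc_molecule`.
#' @export
parse_xyz <- function(text, charge = 0L, multiplicity = 1L) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 1L) stop("empty XYZ input")
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat) || nat < 1L)
    stop("XYZ line 1: malformed atom count: ", sQuote(trimws(lines[1])))
  if (length(lines) < nat + 2L)
    stop("XYZ input truncated: expected ", nat, " atom lines after the header")
  symbols <- character(nat)
  coords <- matrix(NA_real_, nat, 3)
  for (k in seq_len(nat)) {
    ln <- trimws(lines[k + 2L])
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 4L)
      stop("XYZ line ", k + 2L, ": expected 'symbol x y z', got ", sQuote(ln))
    if (!(tok[1] %in% .ELEMENTS$symbol))
      stop("XYZ line ", k + 2L, ": unknown element symbol ", sQuote(tok[1]))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)))
      stop("XYZ line ", k + 2L, ": non-numeric coordinate in ", sQuote(ln))
    symbols[k] <- tok[1]
    coords[k, ] <- xyz
  }
  molecule(symbols, coords, charge = charge, multiplicity = multiplicity)
}

#' Read a molecule from an XYZ file
#' @param path file path.
#' @inheritParams parse_xyz
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  parse_xyz(readLines(path), charge = charge, multiplicity = multiplicity)
}

#' Built-in small-molecule fixtures
#'
#' Returns one of the geometries shipped with the package: `"h2"` (0.74 A),
#' `"lih"` (1.5949 A), `"h2o"` (near-equilibrium water), `"h2o2_p"` /
#' `"h2o2_m"` (the two enantiomeric skew conformers of hydrogen peroxide)
#' and `"noradrenaline"` (an approximate, synthetic (R)-noradrenaline
#' geometry used only for basis-function counting).
#'
#' @param name fixture name.
#' @return An `adc_molecule`.
#' @export
molecule_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".xyz"), package = "adcfold")
  if (!nzchar(path)) stop("unknown fixture: ", name)
  read_xyz(path)
}

atomic_numbers <- function(mol) {
  .ELEMENTS$z[match(mol$symbols, .ELEMENTS$symbol)]
}

n_electrons <- function(mol) sum(atomic_numbers(mol)) - mol$charge

#' Nuclear repulsion energy (hartree)
#' @param mol an `adc_molecule`.
#' @export
nuclear_repulsion <- function(mol) {
  z <- atomic_numbers(mol)
  xyz <- mol$coords * ANGSTROM_TO_BOHR
  e <- 0
  n <- length(z)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      e <- e + z[i] * z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    }
  }
  e
}

#' Center of nuclear mass (bohr)
#' @param mol an `adc_molecule`.
#' @export
center_of_mass <- function(mol) {
  m <- .ELEMENTS$mass[match(mol$symbols, .ELEMENTS$symbol)]
  drop(m %*% (mol$coords * ANGSTROM_TO_BOHR)) / sum(m)
}

#' @export
print.adc_molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, charge %d, multiplicity %d>\n",
              length(x$symbols), x$charge, x$multiplicity))
  invisible(x)
}

#' Rigidly rotate a molecule
#'
#' Utility for invariance tests: applies a proper rotation matrix to all
#' coordinates.
#'
#' @param mol an `adc_molecule`.
#' @param R a 3x3 rotation matrix, or `NULL` to build one from `angles`.
#' @param angles Euler-like angles (radians) used when `R` is `NULL`.
#' @export
rotate_molecule <- function(mol, R = NULL, angles = c(0.3, 0.5, 0.7)) {
  if (is.null(R)) {
    cx <- cos(angles[1]); sx <- sin(angles[1])
    cy <- cos(angles[2]); sy <- sin(angles[2])
    cz <- cos(angles[3]); sz <- sin(angles[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    R <- Rz %*% Ry %*% Rx
  }
  molecule(mol$symbols, mol$coords %*% t(R), mol$charge, mol$multiplicity)
}

#' Mirror a molecule (x -> -x)
#'
#' Produces the enantiomer of a chiral geometry.
#' @param mol an `adc_molecule`.
#' @export
mirror_molecule <- function(mol) {
  xyz <- mol$coords
  xyz[, 1] <- -xyz[, 1]
  molecule(mol$symbols, xyz, mol$charge, mol$multiplicity)
}
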