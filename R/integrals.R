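# R-side wrapper of the McMurchie-Davidson engine: shell -> AO expansion,
# primitive and contracted normalization, and the AO integral interface.

.CART_COMPONENTS <- list(`0` = matrix(0L, 1, 3),
                         `1` = rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))

.dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

.prim_norm <- function(alpha, lmn) {
  L <- sum(lmn)
  (2 * alpha / pi)^0.75 * (4 * alpha)^(L / 2) /
    sqrt(prod(vapply(lmn, function(l) .dfact(2 * l - 1), 1.0)))
}

#' Build the contracted AO list for a molecule
#'
#' Expands shells into Cartesian AO components, folds primitive
#' normalization into the contraction coefficients and normalizes each
#' contracted function.
#'
#' @inheritParams count_contracted_basis
#' @return an `ao_basis` object (list with `lmn`, `centers`, `exps`,
#'   `coefs`, `n`).
#' @export
ao_basis <- function(mol, basis) {
  shells <- basis_shells(mol, basis)
  lmn <- NULL; centers <- NULL; exps <- list(); coefs <- list()
  for (s in shells) {
    comp <- .CART_COMPONENTS[[as.character(s$l)]]
    if (is.null(comp)) stop("angular momentum l=", s$l, " not supported")
    for (r in seq_len(nrow(comp))) {
      lmn <- rbind(lmn, comp[r, ])
      centers <- rbind(centers, s$center)
      cs <- s$coefs * vapply(s$exps, .prim_norm, 1.0, lmn = comp[r, ])
      exps[[length(exps) + 1L]] <- as.numeric(s$exps)
      coefs[[length(coefs) + 1L]] <- as.numeric(cs)
    }
  }
  obj <- list(lmn = matrix(as.integer(lmn), ncol = 3),
              centers = matrix(as.numeric(centers), ncol = 3),
              exps = exps, coefs = coefs, n = nrow(lmn))
  # normalize contracted functions against their self-overlap
  S <- .ao_int1e(obj$lmn, obj$centers, obj$exps, obj$coefs, 0L, 0L, numeric(3))
  for (i in seq_len(obj$n)) obj$coefs[[i]] <- obj$coefs[[i]] / sqrt(S[i, i])
  class(obj) <- "ao_basis"
  obj
}

.int1e <- function(aob, kind, comp = 0L, origin = numeric(3)) {
  .ao_int1e(aob$lmn, aob$centers, aob$exps, aob$coefs, as.integer(kind),
            as.integer(comp), as.numeric(origin))
}

#' AO integral matrices
#'
#' One-electron AO integrals over the contracted basis: `"overlap"`,
#' `"kinetic"`, `"nuclear"` (requires `mol`), `"moment"` (component of
#' `r - origin`), `"deriv"` (d/dx_comp) and `"angmom"`
#' (`[(r - origin) x del]_comp`).
#'
#' @param aob an `ao_basis`.
#' @param kind integral type, see Details.
#' @param mol molecule (needed for `"nuclear"`).
#' @param comp Cartesian component 1..3 for vector operators.
#' @param origin 3-vector (bohr) for moment/angular-momentum operators.
#' @return numeric matrix `n x n`.
#' @export
ao_integral <- function(aob, kind, mol = NULL, comp = 1L,
                        origin = numeric(3)) {
  kind <- match.arg(kind, c("overlap", "kinetic", "nuclear", "moment",
                            "deriv", "angmom"))
  if (kind == "nuclear") {
    if (is.null(mol)) stop("nuclear attraction integrals need mol=")
    return(.ao_nuclear(aob$lmn, aob$centers, aob$exps, aob$coefs,
                       as.numeric(atomic_numbers(mol)),
                       mol$coords * ANGSTROM_TO_BOHR))
  }
  code <- c(overlap = 0L, kinetic = 1L, moment = 2L, deriv = 3L, angmom = 4L)
  .int1e(aob, code[[kind]], comp - 1L, origin)
}

#' AO electron-repulsion integrals
#'
#' Full chemists'-notation tensor `(pq|rs)` as an `n^4` array; intended for
#' the desk-scale systems this package targets.
#'
#' @param aob an `ao_basis`.
#' @return 4-dimensional numeric array.
#' @export
ao_eri <- function(aob) {
  .ao_eri(aob$lmn, aob$centers, aob$exps, aob$coefs)
}
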