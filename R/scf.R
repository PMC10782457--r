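# Restricted Hartree-Fock with DIIS convergence acceleration.

#' Converged closed-shell SCF reference
#'
#' Runs restricted Hartree-Fock for a closed-shell molecule and returns the
#' reference state that anchors all correlated quantities: MO coefficients,
#' orbital energies, the occupied/virtual split and the AO integrals needed
#' downstream.
#'
#' @param mol an `adc_molecule`; must be a closed-shell singlet.
#' @param basis integral-capable basis name (see [basis_shells()]).
#' @param conv convergence threshold on the DIIS error norm and energy
#'   change (default `1e-10`).
#' @param max_cycles SCF cycle limit.
#' @return A `reference_state` object: `mo_coefficients`, `orbital_energies`
#'   (hartree), `n_occupied`/`n_virtual` (spatial orbitals), `ao_overlap`,
#'   `scf_energy` plus the AO basis and integrals.
#' @export
build_reference <- function(mol, basis, conv = 1e-10, max_cycles = 100L) {
  if (mol$multiplicity != 1L)
    stop("correlated modules require a closed-shell singlet reference")
  nel <- n_electrons(mol)
  if (nel %% 2L != 0L)
    stop("odd electron count (", nel, "): not a closed-shell system")
  nocc <- nel %/% 2L

  aob <- ao_basis(mol, basis)
  n <- aob$n
  if (nocc > n) stop("basis too small for ", nel, " electrons")
  S <- ao_integral(aob, "overlap")
  Tm <- ao_integral(aob, "kinetic")
  V <- ao_integral(aob, "nuclear", mol = mol)
  h <- Tm + V
  eri <- ao_eri(aob)
  Jmat <- matrix(eri, n * n, n * n)               # (mu nu | la si)
  Kmat <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)  # (mu la | nu si)
  enuc <- nuclear_repulsion(mol)

  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-10) stop("near-singular AO overlap")
  X <- es$vectors %*% diag(1 / sqrt(es$values), n, n) %*% t(es$vectors)

  solve_fock <- function(F) {
    Fp <- t(X) %*% F %*% X
    e <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    idx <- order(e$values)
    list(C = X %*% e$vectors[, idx, drop = FALSE], eps = e$values[idx])
  }
  density <- function(C) {
    Co <- C[, seq_len(nocc), drop = FALSE]
    2 * Co %*% t(Co)
  }
  fock <- function(P) {
    J <- matrix(Jmat %*% as.vector(P), n, n)
    K <- matrix(Kmat %*% as.vector(P), n, n)
    h + J - 0.5 * K
  }

  sol <- solve_fock(h)
  P <- density(sol$C)
  e_old <- Inf
  diis_F <- list(); diis_e <- list()
  energy <- NA_real_
  resid <- NA_real_
  for (cycle in seq_len(max_cycles)) {
    F <- fock(P)
    energy <- 0.5 * sum(P * (h + F)) + enuc
    err <- F %*% P %*% S - S %*% P %*% F
    resid <- max(abs(err))
    if (resid < conv && abs(energy - e_old) < conv) break
    e_old <- energy
    # DIIS extrapolation
    diis_F[[length(diis_F) + 1L]] <- F
    diis_e[[length(diis_e) + 1L]] <- as.vector(t(X) %*% err %*% X)
    if (length(diis_F) > 8L) { diis_F <- diis_F[-1]; diis_e <- diis_e[-1] }
    m <- length(diis_F)
    if (m > 1L) {
      B <- matrix(0, m + 1, m + 1)
      for (a in seq_len(m)) for (b in seq_len(m))
        B[a, b] <- sum(diis_e[[a]] * diis_e[[b]])
      B[m + 1, seq_len(m)] <- -1
      B[seq_len(m), m + 1] <- -1
      rhs <- c(numeric(m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf)) {
        F <- Reduce(`+`, Map(`*`, diis_F, cf))
      }
    }
    sol <- solve_fock(F)
    P <- density(sol$C)
    if (cycle == max_cycles)
      stop(sprintf(
        "SCF did not converge in %d cycles (last error norm %.3e)",
        max_cycles, resid))
  }

  C <- sol$C
  ref <- structure(list(
    mo_coefficients = C, orbital_energies = sol$eps,
    n_occupied = nocc, n_virtual = n - nocc,
    ao_overlap = S, scf_energy = energy,
    hcore = h, ao_eri = eri, ao = aob, molecule = mol, basis = basis,
    scf_residual = resid), class = "reference_state")
  ref
}

#' @export
print.reference_state <- function(x, ...) {
  cat(sprintf("<RHF reference: %d AO, %d occ / %d virt, E = %.10f hartree>\n",
              nrow(x$mo_coefficients), x$n_occupied, x$n_virtual, x$scf_energy))
  invisible(x)
}

#' MO matrix of a one-electron operator
#'
#' Transforms a property operator to the MO basis. Real matrices are
#' returned for the electric dipole (`r`, symmetric); the linear-momentum,
#' angular-momentum and magnetic-dipole operators are imaginary-Hermitian
#' over real orbitals and are returned as complex matrices including their
#' factors of i: `p = -i del`, `L = -i (r-O) x del`, `m = -L/2`.
#'
#' @param ref a `reference_state`.
#' @param operator one of `"dipole"`, `"linmom"`, `"angmom"`, `"magdip"`.
#' @param comp Cartesian component 1..3.
#' @param origin gauge origin (bohr) for angular-momentum-type operators;
#'   default is the center of nuclear mass.
#' @return an `n x n` MO matrix (numeric or complex).
#' @export
mo_operator <- function(ref, operator, comp = 1L, origin = NULL) {
  operator <- match.arg(operator, c("dipole", "linmom", "angmom", "magdip"))
  C <- ref$mo_coefficients
  if (is.null(origin)) origin <- center_of_mass(ref$molecule)
  ao <- switch(operator,
    dipole = ao_integral(ref$ao, "moment", comp = comp, origin = numeric(3)),
    linmom = ao_integral(ref$ao, "deriv", comp = comp),
    angmom = ao_integral(ref$ao, "angmom", comp = comp, origin = origin),
    magdip = ao_integral(ref$ao, "angmom", comp = comp, origin = origin))
  M <- t(C) %*% ao %*% C
  switch(operator,
    dipole = M,
    linmom = -1i * M,
    angmom = -1i * M,
    magdip = 0.5i * M)
}
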