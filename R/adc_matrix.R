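# ADC(2) secular matrix: workspace, matrix-free block contractions and the
# explicit dense assembly used as the validation oracle.
#
# Spin-orbital conventions: occupied spin orbitals 1..no, virtual no+1..N.
# Singles index (i,a) packed with i fastest; doubles index over pairs
# i<j, a<b packed with the occupied pair fastest. The strict-ADC(2)
# 2p-2h/2p-2h block is zeroth order and therefore diagonal, with entries
# e_a + e_b - e_i - e_j.

#' ADC(2) workspace
#'
#' Precomputes amplitudes, integral blocks and second-order intermediates
#' for the matrix-free sigma builds. Accepts either a molecular
#' `mo_integral_set` or raw spin-orbital data (synthetic model systems).
#'
#' @param ints `mo_integral_set`, or a list with `orbital_energies`, `g`,
#'   `n_occ`.
#' @return an `adc_workspace`.
#' @export
adc_workspace <- function(ints) {
  eps <- ints$orbital_energies
  no <- as.integer(ints$n_occ)
  N <- length(eps)
  nv <- N - no
  if (no < 2L || nv < 2L)
    stop("ADC(2) workspace needs at least 2 occupied and 2 virtual spin orbitals")
  o <- seq_len(no); v <- (no + 1L):N
  amp <- t2_amplitudes(ints)
  t2 <- amp$t2
  g <- ints$g
  g_oovv <- g[o, o, v, v, drop = FALSE]
  g_ovov <- g[o, v, o, v, drop = FALSE]
  g_ooov <- g[o, o, o, v, drop = FALSE]
  g_vovv <- g[v, o, v, v, drop = FALSE]
  g_oooo <- g[o, o, o, o, drop = FALSE]
  g_vvvv <- g[v, v, v, v, drop = FALSE]

  ns <- no * nv
  ij <- t(utils::combn(no, 2L))
  ab <- t(utils::combn(nv, 2L))
  nd <- nrow(ij) * nrow(ab)
  # packed doubles index: occupied pair fastest
  pack_idx <- cbind(ij[rep(seq_len(nrow(ij)), nrow(ab)), , drop = FALSE],
                    ab[rep(seq_len(nrow(ab)), each = nrow(ij)), , drop = FALSE])

  # first-order singles block as an explicit ns x ns matrix (also the ADC(1)
  # secular matrix); (ia) packed with i fastest
  d0 <- as.vector(outer(-eps[o], eps[v], `+`))
  m1 <- diag(d0, ns, ns) -
    matrix(aperm(g_ovov, c(3, 2, 1, 4)), ns, ns)  # [(i,a),(j,b)] = <ja||ib>
  # second-order pp/hh intermediates
  # P[a,b] = sum_{klc} t2[k,l,a,c] g[k,l,b,c]
  P <- matrix(0, nv, nv)
  t_ac <- array(t2, c(no * no, nv, nv))
  g_bc <- array(g_oovv, c(no * no, nv, nv))
  for (a in seq_len(nv)) for (b in seq_len(nv))
    P[a, b] <- sum(t_ac[, a, ] * g_bc[, b, ])
  i_pp <- -0.25 * (P + t(P))
  t_i <- aperm(t2, c(2, 3, 4, 1))              # (k,c,d | i)
  g_j <- aperm(g_oovv, c(2, 3, 4, 1))
  tiM <- matrix(t_i, no * nv * nv, no)
  gjM <- matrix(g_j, no * nv * nv, no)
  Q <- crossprod(tiM, gjM)                     # Q[i,j] = sum_kcd t_ikcd g_jkcd
  i_hh <- -0.25 * (Q + t(Q))

  # matricized tensors for the ph second-order term: rows (j,b), cols (k,c)
  g_jbkc <- matrix(aperm(g_oovv, c(1, 3, 2, 4)), ns, ns)
  t_jbkc <- matrix(aperm(t2, c(1, 3, 2, 4)), ns, ns)

  structure(list(
    orbital_energies = eps, g = g, n_occ = no, n_vir = nv, n_so = N,
    t2 = t2, mp2_energy = amp$mp2_energy,
    g_oovv = g_oovv, g_ovov = g_ovov, g_ooov = g_ooov, g_vovv = g_vovv,
    g_oooo = g_oooo, g_vvvv = g_vvvv,
    n_singles = ns, n_doubles = nd, ij_pairs = ij, ab_pairs = ab,
    pack_idx = pack_idx, m1 = m1, i_pp = i_pp, i_hh = i_hh,
    g_jbkc = g_jbkc, t_jbkc = t_jbkc, cache = new.env(parent = emptyenv()),
    reference = if (inherits(ints, "mo_integral_set")) ints$reference else NULL),
    class = "adc_workspace")
}

#' @export
print.adc_workspace <- function(x, ...) {
  cat(sprintf(
    "<ADC(2) workspace: %d spin orbitals (%d occ), n_s = %d, n_d = %d, E_MP2 = %.8f>\n",
    x$n_so, x$n_occ, x$n_singles, x$n_doubles, x$mp2_energy))
  invisible(x)
}

#' Dimensions of the folded problem
#' @param ws an `adc_workspace` (or model problem).
#' @export
n_singles <- function(ws) UseMethod("n_singles")
#' @export
n_singles.adc_workspace <- function(ws) ws$n_singles
#' @rdname n_singles
#' @export
n_doubles <- function(ws) UseMethod("n_doubles")
#' @export
n_doubles.adc_workspace <- function(ws) ws$n_doubles

#' Singles-singles sigma build
#'
#' Applies the p-h/p-h block of the ADC(2) secular matrix (correct through
#' second order in the fluctuation potential) to a singles vector without
#' forming the second-order block explicitly.
#'
#' @param ws workspace.
#' @param b numeric vector of length `n_singles(ws)`.
#' @return numeric vector `M_ss b`.
#' @export
sigma_singles <- function(ws, b) UseMethod("sigma_singles")
#' @export
sigma_singles.adc_workspace <- function(ws, b) {
  if (length(b) != ws$n_singles) stop("singles vector has wrong length")
  no <- ws$n_occ; nv <- ws$n_vir
  s <- as.vector(ws$m1 %*% b)
  B <- matrix(b, no, nv)
  s <- s + as.vector(B %*% ws$i_pp) + as.vector(ws$i_hh %*% B)
  u1 <- as.vector(ws$g_jbkc %*% b)
  u2 <- as.vector(ws$t_jbkc %*% b)
  s + 0.5 * as.vector(ws$t_jbkc %*% u1 + ws$g_jbkc %*% u2)
}

#' Zeroth-order doubles diagonal
#'
#' Entries `e_a + e_b - e_i - e_j` over the packed 2p-2h index (i<j, a<b).
#' @param ws workspace.
#' @export
doubles_diagonal <- function(ws) UseMethod("doubles_diagonal")
#' @export
doubles_diagonal.adc_workspace <- function(ws) {
  eps <- ws$orbital_energies; no <- ws$n_occ
  idx <- ws$pack_idx
  eps[no + idx[, 3]] + eps[no + idx[, 4]] - eps[idx[, 1]] - eps[idx[, 2]]
}

# pack an antisymmetric full tensor to the i<j, a<b vector, and back
.pack_doubles <- function(ws, Tfull) {
  Tfull[ws$pack_idx]
}
.unpack_doubles <- function(ws, vd) {
  no <- ws$n_occ; nv <- ws$n_vir
  V <- array(0, c(no, no, nv, nv))
  p <- ws$pack_idx
  V[p] <- vd
  V[p[, c(2, 1, 3, 4)]] <- -vd
  V[p[, c(1, 2, 4, 3)]] <- -vd
  V[p[, c(2, 1, 4, 3)]] <- vd
  V
}

#' First-order singles -> doubles coupling
#'
#' Applies `M_ds` to a singles vector, returning the packed doubles vector.
#' `couple_sd` is the exact adjoint.
#'
#' @param ws workspace.
#' @param b singles vector.
#' @export
couple_ds <- function(ws, b) UseMethod("couple_ds")
#' @export
couple_ds.adc_workspace <- function(ws, b) {
  if (length(b) != ws$n_singles) stop("singles vector has wrong length")
  no <- ws$n_occ; nv <- ws$n_vir
  B <- matrix(b, no, nv)
  ooov <- ws$g_ooov; vovv <- ws$g_vovv
  # T1[k,l,c,d] = sum_i <kl||id> B[i,c]
  T1 <- array(matrix(aperm(ooov, c(1, 2, 4, 3)), no * no * nv, no) %*% B,
              c(no, no, nv, nv))
  T1 <- aperm(T1, c(1, 2, 4, 3))
  T2 <- -aperm(T1, c(1, 2, 4, 3))  # -sum_i <kl||ic> B[i,d] = -T1 with c<->d
  # T3[k,l,c,d] = sum_a <al||cd> B[k,a]
  T3 <- array(B %*% matrix(vovv, nv, no * nv * nv), c(no, no, nv, nv))
  T4 <- -aperm(T3, c(2, 1, 3, 4))
  full <- -(T1 + T2 - T3 - T4)
  .pack_doubles(ws, full)
}

#' @rdname couple_ds
#' @param v packed doubles vector.
#' @export
couple_sd <- function(ws, v) UseMethod("couple_sd")
#' @export
couple_sd.adc_workspace <- function(ws, v) {
  if (length(v) != ws$n_doubles) stop("doubles vector has wrong length")
  no <- ws$n_occ; nv <- ws$n_vir
  V <- .unpack_doubles(ws, v)
  ooov <- ws$g_ooov; vovv <- ws$g_vovv
  # s_ia = 1/2 [ sum_lcd <al||cd> V[i,l,c,d] - sum_kld <kl||id> V[k,l,a,d] ]
  Vm <- matrix(aperm(V, c(2, 3, 4, 1)), no * nv * nv, no)   # (l,c,d | i)
  Gm <- matrix(aperm(vovv, c(2, 3, 4, 1)), no * nv * nv, nv) # (l,c,d | a)
  term1 <- t(Vm) %*% Gm                                      # [i,a]
  Vm2 <- matrix(aperm(V, c(1, 2, 4, 3)), no * no * nv, nv)   # (k,l,d | a)
  Gm2 <- matrix(aperm(ooov, c(1, 2, 4, 3)), no * no * nv, no) # (k,l,d | i)
  term2 <- t(Gm2) %*% Vm2                                    # [i,a]
  0.5 * as.vector(term1 - term2)
}

#' Dense ADC(2) matrix (validation oracle)
#'
#' Assembles the full symmetric singles+doubles secular matrix explicitly.
#' Intended for small systems only; refuses above `cap` total dimension.
#'
#' @param ws workspace.
#' @param cap largest allowed `n_s + n_d`.
#' @return `dense_adc_matrix`: list with `M`, `ns`, `nd`.
#' @export
assemble_dense <- function(ws, cap = 5000L) UseMethod("assemble_dense")
#' @export
assemble_dense.adc_workspace <- function(ws, cap = 5000L) {
  ns <- ws$n_singles; nd <- ws$n_doubles
  if (ns + nd > cap)
    stop("dense oracle dimension ", ns + nd, " exceeds cap ", cap)
  no <- ws$n_occ; nv <- ws$n_vir
  eps <- ws$orbital_energies
  t2 <- ws$t2; g_oovv <- ws$g_oovv
  # M_ss: explicit second-order block
  Mss <- ws$m1
  ph <- 0.5 * (ws$t_jbkc %*% ws$g_jbkc + ws$g_jbkc %*% ws$t_jbkc)
  Mss <- Mss + ph
  for (ia in seq_len(ns)) {
    i <- (ia - 1L) %% no + 1L
    a <- (ia - 1L) %/% no + 1L
    for (jb in seq_len(ns)) {
      j <- (jb - 1L) %% no + 1L
      b <- (jb - 1L) %/% no + 1L
      val <- 0
      if (i == j) val <- val + ws$i_pp[a, b]
      if (a == b) val <- val + ws$i_hh[i, j]
      Mss[ia, jb] <- Mss[ia, jb] + val
    }
  }
  # M_sd columns from the explicit coupling formula
  Msd <- matrix(0, ns, nd)
  ooov <- ws$g_ooov; vovv <- ws$g_vovv
  for (col in seq_len(nd)) {
    k <- ws$pack_idx[col, 1]; l <- ws$pack_idx[col, 2]
    c <- ws$pack_idx[col, 3]; d <- ws$pack_idx[col, 4]
    colv <- matrix(0, no, nv)
    colv[, c] <- colv[, c] - ooov[k, l, , d]
    colv[, d] <- colv[, d] + ooov[k, l, , c]
    colv[k, ] <- colv[k, ] + vovv[, l, c, d]
    colv[l, ] <- colv[l, ] - vovv[, k, c, d]
    Msd[, col] <- as.vector(colv)
  }
  ddiag <- doubles_diagonal(ws)
  M <- matrix(0, ns + nd, ns + nd)
  M[seq_len(ns), seq_len(ns)] <- Mss
  M[seq_len(ns), ns + seq_len(nd)] <- Msd
  M[ns + seq_len(nd), seq_len(ns)] <- t(Msd)
  M[ns + seq_len(nd), ns + seq_len(nd)] <- diag(ddiag, nd, nd)
  structure(list(M = M, ns = ns, nd = nd), class = "dense_adc_matrix")
}

#' Block views of a dense ADC matrix
#' @param dm a `dense_adc_matrix`.
#' @param which one of `"ss"`, `"sd"`, `"ds"`, `"dd"`.
#' @export
dense_block <- function(dm, which = c("ss", "sd", "ds", "dd")) {
  which <- match.arg(which)
  s <- seq_len(dm$ns); d <- dm$ns + seq_len(dm$nd)
  switch(which,
         ss = dm$M[s, s, drop = FALSE], sd = dm$M[s, d, drop = FALSE],
         ds = dm$M[d, s, drop = FALSE], dd = dm$M[d, d, drop = FALSE])
}
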