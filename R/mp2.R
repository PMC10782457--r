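# Moller-Plesset ground state: first-order doubles amplitudes and MP2 energy.

#' First-order doubles amplitudes and MP2 energy
#'
#' Spin-orbital amplitudes `t_ijab = <ij||ab> / (e_i + e_j - e_a - e_b)` and
#' the correlation energy `E_MP2 = 1/4 sum <ij||ab> t_ijab`.
#'
#' @param ints an `mo_integral_set`, or any list with fields
#'   `orbital_energies`, `g` (antisymmetrized spin-orbital tensor) and
#'   `n_occ`.
#' @param denominator_floor smallest allowed `|e_i+e_j-e_a-e_b|`; hitting it
#'   raises a degeneracy error naming the orbital quadruple (no silent
#'   level shifting).
#' @return list with `t2` (array occ x occ x virt x virt) and `mp2_energy`.
#' @export
t2_amplitudes <- function(ints, denominator_floor = 1e-8) {
  eps <- ints$orbital_energies
  no <- ints$n_occ
  N <- length(eps)
  if (no < 1L || no >= N) stop("invalid occupation")
  o <- seq_len(no); v <- (no + 1L):N
  g_oovv <- ints$g[o, o, v, v, drop = FALSE]
  D <- outer(eps[o], eps[o], `+`)
  D <- outer(D, outer(eps[v], eps[v], `+`), `-`)
  bad <- which(abs(D) < denominator_floor, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf(
      "orbital-energy denominator below floor for quadruple (i=%d, j=%d, a=%d, b=%d)",
      b[1], b[2], no + b[3], no + b[4]))
  }
  t2 <- g_oovv / D
  list(t2 = t2, mp2_energy = 0.25 * sum(g_oovv * t2))
}
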