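# MO-basis electron-repulsion integrals.
#
# Production path: batched auxiliary-Fock builds. For every batch of MO index
# pairs (p,q) a set of pair density matrices D^{pq} = C_p C_q^T is contracted
# with the AO integrals in a single Coulomb-type matrix multiplication,
# yielding auxiliary Fock matrices F^{pq}_{gd} = sum_{ab} (gd|ab) D^{pq}_{ab};
# a final half-transformation gives (rs|pq). Peak memory is bounded by the
# batch size times one AO matrix. A direct O(N^5) four-index transformation
# is kept as the validation oracle.

#' MO electron-repulsion integrals via batched Fock builds
#'
#' @param ref a `reference_state`.
#' @param batch_size number of MO pairs per auxiliary-Fock batch, or
#'   `"all"`.
#' @param method `"fock"` (incremental auxiliary-Fock builds, production) or
#'   `"direct"` (one-shot four-index transformation, oracle).
#' @param max_memory_mb refuse to allocate more than this for the batch of
#'   auxiliary Fock matrices.
#' @return spatial-MO chemists' notation array `(pq|rs)`.
#' @export
mo_eri_spatial <- function(ref, batch_size = "all", method = c("fock", "direct"),
                           max_memory_mb = 2048) {
  method <- match.arg(method)
  C <- ref$mo_coefficients
  n <- nrow(C)
  eri <- ref$ao_eri
  if (method == "direct") {
    # sequential quarter transformations
    g <- array(eri, c(n, n, n, n))
    for (k in 1:4) {
      m <- matrix(aperm(g, c(2, 3, 4, 1)), n^3, n)
      g <- array(m %*% C, c(n, n, n, n))
    }
    return(g)
  }
  pairs <- cbind(rep(seq_len(n), each = n), rep(seq_len(n), n))
  pairs <- pairs[pairs[, 1] <= pairs[, 2], , drop = FALSE]
  npair <- nrow(pairs)
  bs <- if (identical(batch_size, "all")) npair else as.integer(batch_size)
  if (bs < 1L) stop("batch_size must be >= 1")
  need_mb <- bs * n * n * 8 / 2^20
  if (need_mb > max_memory_mb)
    stop(sprintf(paste0("auxiliary-Fock batch needs %.1f MB > budget %.1f MB; ",
                        "reduce batch_size"), need_mb, max_memory_mb))
  Gmat <- matrix(eri, n * n, n * n)
  out <- array(0, c(n, n, n, n))
  for (start in seq(1L, npair, by = bs)) {
    idx <- start:min(start + bs - 1L, npair)
    # pair densities as columns
    D <- vapply(idx, function(k) {
      as.vector(C[, pairs[k, 1]] %o% C[, pairs[k, 2]])
    }, numeric(n * n))
    Fb <- Gmat %*% D                       # (gd|pq) for the batch
    for (col in seq_along(idx)) {
      Fm <- matrix(Fb[, col], n, n)
      half <- t(C) %*% Fm %*% C            # (rs|pq)
      p <- pairs[idx[col], 1]; q <- pairs[idx[col], 2]
      out[p, q, , ] <- half
      out[q, p, , ] <- half
    }
  }
  out
}

.so_spatial <- function(p) (p + 1L) %/% 2L
.so_spin <- function(p) ((p - 1L) %% 2L) + 1L

#' Antisymmetrized spin-orbital integral set
#'
#' Builds `<pq||rs>` over spin orbitals (alpha/beta interleaved per spatial
#' orbital) from the spatial MO integrals, together with the spin-orbital
#' energies and occupation. The full tensor is stored; space blocks
#' (`oovv`, `ovov`, ...) are views extracted by [eri_block()].
#'
#' @param ref a `reference_state`.
#' @inheritParams mo_eri_spatial
#' @return an `mo_integral_set`.
#' @export
mo_integral_set <- function(ref, batch_size = "all",
                            method = c("fock", "direct")) {
  g_spat <- mo_eri_spatial(ref, batch_size = batch_size, method = method)
  n <- dim(g_spat)[1]
  phys <- aperm(g_spat, c(1, 3, 2, 4))    # <PQ|RS> = (PR|QS)
  N <- 2L * n
  spat <- .so_spatial(seq_len(N))
  spin <- .so_spin(seq_len(N))
  gi <- as.matrix(expand.grid(p = seq_len(N), q = seq_len(N),
                              r = seq_len(N), s = seq_len(N)))
  d1 <- (spin[gi[, 1]] == spin[gi[, 3]]) & (spin[gi[, 2]] == spin[gi[, 4]])
  d2 <- (spin[gi[, 1]] == spin[gi[, 4]]) & (spin[gi[, 2]] == spin[gi[, 3]])
  v <- numeric(nrow(gi))
  if (any(d1))
    v[d1] <- phys[cbind(spat[gi[d1, 1]], spat[gi[d1, 2]],
                        spat[gi[d1, 3]], spat[gi[d1, 4]])]
  if (any(d2))
    v[d2] <- v[d2] - phys[cbind(spat[gi[d2, 1]], spat[gi[d2, 2]],
                                spat[gi[d2, 4]], spat[gi[d2, 3]])]
  g <- array(v, c(N, N, N, N))
  eps <- ref$orbital_energies[spat]
  structure(list(g = g, orbital_energies = eps,
                 n_occ = 2L * ref$n_occupied, n_so = N,
                 spatial = g_spat, reference = ref),
            class = "mo_integral_set")
}

#' Extract a space block of `<pq||rs>`
#'
#' @param ints an `mo_integral_set` (or an `adc_workspace`).
#' @param block four-letter string over `o`/`v`, e.g. `"oovv"`.
#' @return rank-4 array over the requested spaces.
#' @export
eri_block <- function(ints, block) {
  no <- ints$n_occ
  sl <- lapply(strsplit(block, "")[[1]], function(ch) {
    if (ch == "o") seq_len(no) else (no + 1L):ints$n_so
  })
  ints$g[sl[[1]], sl[[2]], sl[[3]], sl[[4]], drop = FALSE]
}

#' Spin-expand an MO operator matrix
#'
#' Maps a spatial MO one-electron matrix to the interleaved spin-orbital
#' convention used by the correlated modules.
#'
#' @param theta spatial `n x n` matrix (numeric or complex).
#' @return `2n x 2n` matrix.
#' @export
so_expand <- function(theta) {
  n <- nrow(theta)
  N <- 2L * n
  spat <- .so_spatial(seq_len(N))
  spin <- .so_spin(seq_len(N))
  out <- theta[spat, spat]
  out[outer(spin, spin, `!=`)] <- 0
  out
}
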