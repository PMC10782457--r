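# Determinant-space, order-by-order construction of the intermediate-state
# representation on tiny synthetic fermion systems. Exact first-principles
# oracle for the ADC(2) working equations: builds the many-body Hamiltonian
# in the full determinant basis, forms the Moller-Plesset series by linear
# algebra, constructs intermediate states by class-wise Gram-Schmidt plus
# symmetric orthonormalization carried as a series in the perturbation
# order, and reads off the secular-matrix blocks and modified transition
# moments order by order.

synthetic_so_system <- function(n = 6L, nocc = 3L, seed = 1L, scale = 0.12) {
  set.seed(seed)
  eps <- sort(c(-2 - runif(nocc), 1 + 2 * runif(n - nocc)))
  g <- array(rnorm(n^4) * scale, c(n, n, n, n))
  g <- g - aperm(g, c(2, 1, 3, 4))
  g <- g - aperm(g, c(1, 2, 4, 3))
  g <- 0.5 * (g + aperm(g, c(3, 4, 1, 2)))
  h <- diag(eps)
  occ <- seq_len(nocc)
  for (p in seq_len(n)) for (q in seq_len(n))
    h[p, q] <- h[p, q] - sum(g[p, occ, q, occ][cbind(occ, occ)])
  list(orbital_energies = eps, g = g, n_occ = nocc, h = h, n = n)
}

.det_space <- function(sys) {
  dets <- utils::combn(sys$n, sys$n_occ)
  ndet <- ncol(dets)
  key <- apply(dets, 2, paste, collapse = ",")
  index <- seq_len(ndet); names(index) <- key
  apply_epq <- function(p, q, det) {
    pos <- match(q, det)
    if (is.na(pos)) return(NULL)
    rest <- det[-pos]
    ph <- (-1)^(pos - 1)
    if (p %in% rest) return(NULL)
    ph <- ph * (-1)^sum(rest < p)
    list(phase = ph, det = sort(c(rest, p)))
  }
  E <- array(0, c(sys$n, sys$n, ndet, ndet))
  for (p in seq_len(sys$n)) for (q in seq_len(sys$n)) {
    for (j in seq_len(ndet)) {
      r <- apply_epq(p, q, dets[, j])
      if (!is.null(r)) {
        i <- index[[paste(r$det, collapse = ",")]]
        E[p, q, i, j] <- E[p, q, i, j] + r$phase
      }
    }
  }
  H <- matrix(0, ndet, ndet)
  for (p in seq_len(sys$n)) for (q in seq_len(sys$n))
    if (sys$h[p, q] != 0) H <- H + sys$h[p, q] * E[p, q, , ]
  for (p in seq_len(sys$n)) for (q in seq_len(sys$n))
    for (r in seq_len(sys$n)) for (s in seq_len(sys$n)) {
      gv <- sys$g[p, q, r, s]
      if (gv != 0) {
        B <- E[p, r, , ] %*% E[q, s, , ]
        if (q == r) B <- B - E[p, s, , ]
        H <- H + 0.25 * gv * B
      }
    }
  H0diag <- apply(dets, 2, function(d) sum(sys$orbital_energies[d]))
  list(dets = dets, index = index, ndet = ndet, E = E, H = H, H0diag = H0diag,
       ref = index[[paste(seq_len(sys$n_occ), collapse = ",")]])
}

# series helpers: a series is a list of 3 entries (orders 0..2)
.smul_scalar <- function(x, y) {
  out <- vector("list", 3)
  for (o in 1:3) {
    acc <- 0
    for (k in 1:o) acc <- acc + x[[k]] * y[[o - k + 1]]
    out[[o]] <- acc
  }
  out
}
.sdot <- function(x, y) {
  out <- numeric(3)
  for (o in 1:3) for (k in 1:o) out[o] <- out[o] + sum(x[[k]] * y[[o - k + 1]])
  out
}
.saxpy <- function(x, a, y) {  # x + a*y, a scalar series, x/y vector series
  out <- x
  for (o in 1:3) for (k in 1:o)
    out[[o]] <- out[[o]] + a[[k]] * y[[o - k + 1]]
  out
}

det_isr <- function(sys, theta = NULL) {
  sp <- .det_space(sys)
  nocc <- sys$n_occ; n <- sys$n
  occ <- seq_len(nocc); vir <- (nocc + 1L):n
  i0 <- sp$ref
  E0 <- sp$H0diag[i0]
  V <- sp$H - diag(sp$H0diag)
  phi <- numeric(sp$ndet); phi[i0] <- 1
  den <- E0 - sp$H0diag; den[i0] <- Inf
  psi1 <- V[, i0] / den
  E1 <- V[i0, i0]
  E2 <- sum(V[i0, ] * psi1)
  psi2 <- (V %*% psi1 - E1 * psi1) / den
  psi2 <- as.vector(psi2); psi2[i0] <- 0
  n2 <- sum(psi1^2)
  psin <- list(phi, psi1, psi2 - 0.5 * n2 * phi)
  Eser <- list(E0, E1, E2)

  singles <- expand.grid(i = occ, a = vir)
  doubles <- expand.grid(op = seq_len(ncol(utils::combn(nocc, 2))),
                         vp = seq_len(ncol(utils::combn(n - nocc, 2))))
  ij <- utils::combn(nocc, 2)
  ab <- utils::combn(n - nocc, 2) + nocc

  c_single <- function(i, a) sp$E[a, i, , ]
  c_double <- function(i, j, a, b) sp$E[a, i, , ] %*% sp$E[b, j, , ]

  precursor <- function(C) {
    Cpsi <- lapply(psin, function(v) as.vector(C %*% v))
    ov <- .sdot(psin, Cpsi)
    .saxpy(Cpsi, list(-ov[1], -ov[2], -ov[3]), psin)
  }
  pre_s <- lapply(seq_len(nrow(singles)), function(k)
    precursor(c_single(singles$i[k], singles$a[k])))
  pre_d <- lapply(seq_len(nrow(doubles)), function(k) {
    op <- doubles$op[k]; vp <- doubles$vp[k]
    precursor(c_double(ij[1, op], ij[2, op], ab[1, vp], ab[2, vp]))
  })

  overlap_series <- function(A, B) {
    S <- lapply(1:3, function(o) matrix(0, length(A), length(B)))
    for (J in seq_along(A)) for (K in seq_along(B)) {
      d <- .sdot(A[[J]], B[[K]])
      for (o in 1:3) S[[o]][J, K] <- d[o]
    }
    S
  }
  inv_sqrt_series <- function(S) {
    stopifnot(max(abs(S[[1]] - diag(nrow(S[[1]])))) < 1e-10)
    list(diag(nrow(S[[1]])), -0.5 * S[[2]],
         -0.5 * S[[3]] + 0.375 * S[[2]] %*% S[[2]])
  }
  rotate <- function(states, X) {
    lapply(seq_len(ncol(X[[1]])), function(J) {
      v <- lapply(1:3, function(o) numeric(length(states[[1]][[1]])))
      for (K in seq_along(states)) {
        for (o in 1:3) for (k in 1:o)
          v[[o]] <- v[[o]] + X[[k]][K, J] * states[[K]][[o - k + 1]]
      }
      v
    })
  }
  I_s <- rotate(pre_s, inv_sqrt_series(overlap_series(pre_s, pre_s)))
  pre_d2 <- lapply(pre_d, function(x) {
    y <- x
    for (Ik in I_s) {
      ov <- .sdot(Ik, y)
      y <- .saxpy(y, list(-ov[1], -ov[2], -ov[3]), Ik)
    }
    y
  })
  I_d <- rotate(pre_d2, inv_sqrt_series(overlap_series(pre_d2, pre_d2)))

  H0 <- diag(sp$H0diag)
  shifted <- function(v) {
    Hser <- list(H0, V, matrix(0, sp$ndet, sp$ndet))
    lapply(1:3, function(o) {
      acc <- numeric(sp$ndet)
      for (k in 1:o)
        acc <- acc + as.vector(Hser[[k]] %*% v[[o - k + 1]]) -
          Eser[[k]] * v[[o - k + 1]]
      acc
    })
  }
  block <- function(A, B) {
    M <- lapply(1:3, function(o) matrix(0, length(A), length(B)))
    for (K in seq_along(B)) {
      Hy <- shifted(B[[K]])
      for (J in seq_along(A)) {
        d <- .sdot(A[[J]], Hy)
        for (o in 1:3) M[[o]][J, K] <- d[o]
      }
    }
    M
  }
  res <- list(M_ss = block(I_s, I_s), M_sd = block(I_s, I_d),
              M_dd = block(I_d, I_d), singles = singles,
              ij = ij, ab = ab)
  if (!is.null(theta)) {
    D <- matrix(0, sp$ndet, sp$ndet)
    for (p in seq_len(n)) for (q in seq_len(n))
      if (theta[p, q] != 0) D <- D + theta[p, q] * sp$E[p, q, , ]
    Dpsi <- lapply(psin, function(v) as.vector(D %*% v))
    res$F_s <- lapply(1:3, function(o) numeric(length(I_s)))
    res$F_d <- lapply(1:3, function(o) numeric(length(I_d)))
    for (J in seq_along(I_s)) {
      d <- .sdot(I_s[[J]], Dpsi)
      for (o in 1:3) res$F_s[[o]][J] <- d[o]
    }
    for (J in seq_along(I_d)) {
      d <- .sdot(I_d[[J]], Dpsi)
      for (o in 1:3) res$F_d[[o]][J] <- d[o]
    }
  }
  res
}
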