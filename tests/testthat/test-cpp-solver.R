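# Folded CPP linear-response solver.

test_that("frequency grids are equidistant and endpoint-inclusive", {
  g <- freq_grid(0.1650, 0.2250, step = 0.0025)
  expect_length(g, 25L)
  expect_equal(g[1], 0.1650)
  expect_equal(g[25], 0.2250)
  expect_equal(unique(round(diff(g), 12)), 0.0025)

  g2 <- freq_grid(4, 11, count = 101L)
  expect_length(g2, 101L)
  expect_equal(unique(round(diff(g2), 12)), 0.07)

  expect_equal(freq_grid(0.3, 0.5, count = 1L), 0.3)
  expect_error(freq_grid(0.165, 0.225, count = 10L, step = 0.0025),
               "inconsistent")
  expect_error(freq_grid(1, 0, count = 5L), "stop")
})

test_that("folding weights equal the complex reciprocal elementwise", {
  set.seed(5)
  d <- runif(50, 0.5, 3); omega <- 0.37; gamma <- 0.01
  w <- fold_weights(d, omega, gamma)
  oracle <- 1 / (d - omega - 1i * gamma)
  expect_lt(max(abs(w$re - Re(oracle))), 1e-14)
  expect_lt(max(abs(w$im - Im(oracle))), 1e-14)
  expect_true(all(w$im > 0))
  w0 <- fold_weights(d, omega, 0)
  expect_equal(w0$re, 1 / (d - omega), tolerance = 1e-14)
  expect_equal(w0$im, rep(0, 50))
  expect_error(fold_weights(c(0.5, 0.37), 0.37, 0), "resonance")
})

test_that("sigma pairs match the dense folded matrix and decay with gamma", {
  ws <- fixture_ws("h2o")
  dm <- fixture_dense("h2o")
  Mss <- dense_block(dm, "ss"); Msd <- dense_block(dm, "sd")
  d <- doubles_diagonal(ws)
  set.seed(3)
  b <- rnorm(n_singles(ws)); b <- b / sqrt(sum(b^2))
  for (omega in c(0.3, 0.45)) {
    w <- fold_weights(d, omega, GAMMA_AU)
    pr <- build_sigma_pair(ws, b, omega, GAMMA_AU)
    expect_lt(max(abs(pr$sp - (Mss - Msd %*% (w$re * t(Msd))) %*% b)), 1e-10)
    expect_lt(max(abs(pr$spp - (-Msd %*% (w$im * t(Msd))) %*% b)), 1e-10)
  }
  # resolvent decay: sigma'' -> 0 as O(1/gamma) once gamma dominates the
  # doubles diagonal (which reaches ~2|eps_core| for core-hole pairs)
  n1 <- sqrt(sum(build_sigma_pair(ws, b, 0.3, 300)$spp^2))
  n2 <- sqrt(sum(build_sigma_pair(ws, b, 0.3, 3000)$spp^2))
  expect_lt(n2, n1 / 8)
  # zero coupling: sigma' = M_ss b, sigma'' = 0
  mp <- generate_model_problem(8, 12, coupling = 0, seed = 2)
  pr <- build_sigma_pair(mp, b[1:8], 0.3, GAMMA_AU)
  expect_equal(pr$sp, as.vector(mp$M_ss %*% b[1:8]), tolerance = 1e-12)
  expect_equal(max(abs(pr$spp)), 0)
})

test_that("RHS folding reduces to B_s without doubles and matches block elimination", {
  ws <- fixture_ws("h2o")
  F <- modified_transition_moments(ws, "dipole", comp = 3)
  expect_equal(fold_rhs(ws, F$F_s, NULL), as.complex(F$F_s))
  omega <- 0.4
  bf <- fold_rhs(ws, F$F_s, F$F_d, omega, GAMMA_AU)
  Msd <- dense_block(fixture_dense("h2o"), "sd")
  oracle <- F$F_s - Msd %*% (F$F_d / (doubles_diagonal(ws) - omega - 1i * GAMMA_AU))
  expect_lt(max(abs(bf - oracle)), 1e-12)
})

test_that("reduced solve is exact on an enclosing subspace and remix-invariant", {
  mp <- generate_model_problem(12, 20, coupling = 0.08, seed = 4)
  omega <- 0.5
  sys <- folded_system("rhs", omega, GAMMA_AU, mp$rhs)
  sys$rhs_folded <- fold_rhs(mp, mp$rhs, NULL, omega, GAMMA_AU)
  # dense complex solution, then a subspace containing its real/imag parts
  dm <- assemble_dense(mp)
  X <- solve(dm$M - (omega + 1i * GAMMA_AU) * diag(nrow(dm$M)),
             c(mp$rhs, rep(0, mp$n_d)))[1:12]
  V <- qr.Q(qr(cbind(Re(X), Im(X), rnorm(12))))
  mk_sub <- function(V) {
    SP <- sapply(seq_len(ncol(V)), function(k)
      build_sigma_pair(mp, V[, k], omega, GAMMA_AU)$sp)
    SPP <- sapply(seq_len(ncol(V)), function(k)
      build_sigma_pair(mp, V[, k], omega, GAMMA_AU)$spp)
    list(V = V, SP = SP, SPP = SPP)
  }
  red <- solve_reduced(mk_sub(V), sys)
  expect_lt(red$relres, 1e-12)
  expect_lt(max(abs(red$X - X)), 1e-10)
  # orthogonal remix of the subspace leaves the solution invariant
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  red2 <- solve_reduced(mk_sub(V %*% Q), sys)
  expect_lt(max(abs(red2$X - red$X)), 1e-12)
})

test_that("one-vector subspace on a diagonal model matches the 2x2 closed form", {
  # diagonal singles block, no coupling: folded operator is a*I on the span
  mp <- generate_model_problem(1, 1, coupling = 0, seed = 9)
  a <- mp$M_ss[1, 1]; omega <- 0.3; gam <- 0.02
  sys <- folded_system("r", omega, gam, 1)
  sys$rhs_folded <- 1 + 0i
  sub <- list(V = matrix(1), SP = matrix(a), SPP = matrix(0))
  red <- solve_reduced(sub, sys)
  # K = [[a-w, g],[g, w-a]], rhs (1, 0)
  K <- rbind(c(a - omega, gam), c(gam, omega - a))
  z <- solve(K, c(1, 0))
  expect_equal(c(Re(red$X), Im(red$X)), z, tolerance = 1e-12)
  # equals the complex reciprocal
  expect_equal(red$X, 1 / (a - omega - 1i * gam), tolerance = 1e-12)
})

test_that("folded CPP solutions equal the dense complex solve, both strategies", {
  for (case_ in list(c("h2", "sto-3g"), c("lih", "sto-3g"), c("h2", "6-31g"))) {
    ws <- fixture_ws(case_[1], case_[2])
    dm <- fixture_dense(case_[1], case_[2])
    F <- modified_transition_moments(ws, "dipole", comp = 3)
    omegas <- c(0.35, 0.42)
    systems <- list()
    for (w in omegas)
      systems <- c(systems,
                   list(folded_system("muz", w, GAMMA_AU, F$F_s, F$F_d),
                        folded_system("muz", -w, GAMMA_AU, F$F_s, F$F_d)))
    for (strategy in c("separate", "common")) {
      out <- cpp_solve(ws, systems, strategy = strategy)
      for (k in seq_along(systems)) {
        s <- systems[[k]]
        X <- out$solutions[[k]]
        expect_true(X$converged)
        full <- solve(dm$M - (s$omega + 1i * s$gamma) * diag(nrow(dm$M)),
                      c(F$F_s, F$F_d))
        scale <- max(abs(full[seq_len(dm$ns)]))
        expect_lt(max(abs(X$X_s - full[seq_len(dm$ns)])) / scale, 1e-8)
        expect_lt(max(abs(X$X_d - full[dm$ns + seq_len(dm$nd)])) / scale, 1e-8)
      }
    }
  }
})

test_that("common-subspace operator pooling options give the same solutions", {
  ws <- fixture_ws("lih")
  systems <- enqueue_response_systems(ws, "dipole", 1:3, c(0.25, 0.30),
                                      GAMMA_AU, threshold = 1e-8)
  a <- cpp_solve(ws, systems, strategy = "common", common_pool = "all")
  b <- cpp_solve(ws, systems, strategy = "common",
                 common_pool = "per-operator")
  for (k in seq_along(systems)) {
    expect_true(a$solutions[[k]]$converged && b$solutions[[k]]$converged)
    expect_lt(max(abs(a$solutions[[k]]$X_s - b$solutions[[k]]$X_s)),
              1e-6 * max(1, max(abs(a$solutions[[k]]$X_s))))
  }
  expect_gte(length(b$diagnostics$groups), 3L)
})

test_that("zero right-hand side converges immediately to the zero solution", {
  ws <- fixture_ws("h2")
  sys <- folded_system("zero", 0.4, GAMMA_AU, rep(0, n_singles(ws)))
  out <- cpp_solve(ws, list(sys))
  expect_true(out$solutions[[1]]$converged)
  expect_equal(max(abs(out$solutions[[1]]$X_s)), 0)
  expect_lte(out$solutions[[1]]$iterations, 1L)
})

test_that("optimal subspace residual is monotone non-increasing with growth", {
  mp <- generate_model_problem(20, 40, coupling = 0.1, seed = 6)
  omega <- 0.45; gam <- GAMMA_AU
  sys <- folded_system("r", omega, gam, mp$rhs)
  sys$rhs_folded <- fold_rhs(mp, mp$rhs, NULL, omega, gam)
  g <- c(Re(sys$rhs_folded), Im(sys$rhs_folded))
  set.seed(8)
  cols <- cbind(mp$rhs, matrix(rnorm(20 * 6), 20))
  ls_res <- numeric(0)
  for (m in seq_len(ncol(cols))) {
    V <- qr.Q(qr(cols[, seq_len(m), drop = FALSE]))
    V <- matrix(V, ncol = m)
    SP <- matrix(sapply(seq_len(m), function(k)
      build_sigma_pair(mp, V[, k], omega, gam)$sp), ncol = m)
    SPP <- matrix(sapply(seq_len(m), function(k)
      build_sigma_pair(mp, V[, k], omega, gam)$spp), ncol = m)
    # columns of the coupled real system applied to the basis
    A <- cbind(rbind(SP - omega * V, SPP - gam * V),
               rbind(gam * V - SPP, SP - omega * V))
    fit <- qr.solve(qr(A), g)
    ls_res <- c(ls_res, sqrt(sum((A %*% fit - g)^2)) / sqrt(sum(g^2)))
    # the Galerkin solve can never beat the least-squares optimum
    red <- solve_reduced(list(V = V, SP = SP, SPP = SPP), sys)
    expect_gte(red$relres, ls_res[m] - 1e-12)
  }
  expect_true(all(diff(ls_res) <= 1e-10))
})
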