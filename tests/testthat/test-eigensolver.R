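# Folded nonlinear eigensolver.

test_that("ADC(1) guess: orthonormal vectors, exact in the non-interacting limit", {
  ws <- adc_workspace(noninteracting_system())
  g <- adc1_guess(ws, 4)
  eps <- ws$orbital_energies
  d0 <- sort(as.vector(outer(-eps[1:3], eps[4:6], `+`)))
  expect_equal(g$values, d0[1:4], tolerance = 1e-12)
  expect_equal(crossprod(g$vectors), diag(4), tolerance = 1e-12)
  expect_error(adc1_guess(ws, 100), "exceeds")
})

test_that("Theta contraction: derivative is non-positive and matches finite differences", {
  ws <- fixture_ws("h2o")
  set.seed(2)
  y <- rnorm(n_singles(ws)); y <- y / sqrt(sum(y^2))
  omega <- 0.4
  expect_lte(theta_derivative(ws, y, omega), 0)
  for (h in c(1e-3, 5e-4)) {
    fd <- (theta_contraction(ws, y, omega + h) -
             theta_contraction(ws, y, omega - h)) / (2 * h)
    expect_equal(theta_derivative(ws, y, omega), fd, tolerance = 10 * h^2)
  }
  # zero coupling: Theta = y' M_ss y, derivative 0
  mp <- generate_model_problem(8, 12, coupling = 0, seed = 2)
  y8 <- y[1:8] / sqrt(sum(y[1:8]^2))
  expect_equal(theta_contraction(mp, y8, 0.4), sum(y8 * (mp$M_ss %*% y8)),
               tolerance = 1e-12)
  expect_equal(theta_derivative(mp, y8, 0.4), 0)
})

test_that("Newton update: fixed point, closed-form quadratic convergence, theta'=0 limit", {
  expect_equal(newton_update(0.5, 0.5, -0.3), 0.5)          # Theta(w)=w
  expect_equal(newton_update(0.5, 0.62, 0), 0.62)           # plain fixed point
  expect_error(newton_update(0.5, 0.6, 1), "floor")
  # scalar model a + c^2/(w - d) = w
  a <- 0.5; cc <- 0.2; d <- 1.4
  root <- (a + d - sqrt((a - d)^2 + 4 * cc^2)) / 2
  w <- a
  errs <- numeric(0)
  for (k in 1:6) {
    th <- a + cc^2 / (w - d)
    dth <- -cc^2 / (w - d)^2
    w <- newton_update(w, th, dth)
    errs <- c(errs, abs(w - root))
  }
  expect_lt(errs[6], 1e-14)
  # quadratic convergence: error roughly squares while above round-off
  expect_lt(errs[3], errs[2]^2 * 100)
})

test_that("scalar folded model converges to the closed-form root", {
  mp <- generate_model_problem(1, 1, coupling = 0.2, seed = 7)
  a <- mp$M_ss[1, 1]; c2 <- mp$M_sd[1, 1]^2; d <- mp$d
  root <- (a + d - sqrt((a - d)^2 + 4 * c2)) / 2
  st <- solve_states(mp, 1)
  expect_equal(st[[1]]$omega, root, tolerance = 1e-10)
})

test_that("every folded root equals a dense eigenvalue; lowest sets are complete", {
  cases <- list(list("h2", "sto-3g", 4L), list("lih", "sto-3g", 6L),
                list("h2o", "sto-3g", 8L), list("h2", "6-31g", 6L))
  for (cs in cases) {
    ws <- fixture_ws(cs[[1]], cs[[2]])
    ev <- sort(eigen(fixture_dense(cs[[1]], cs[[2]])$M, symmetric = TRUE,
                     only.values = TRUE)$values)
    st <- solve_states(ws, cs[[3]])
    got <- sort(vapply(st, function(s) s$omega, numeric(1)))
    expect_true(all(vapply(st, function(s) s$converged, TRUE)))
    expect_lt(max(abs(got - ev[seq_along(got)])), 1e-8)
    # non-decreasing sequence, duplicates only where the dense oracle is
    # degenerate
    expect_true(all(diff(got) >= -1e-10))
    dup <- which(diff(got) < 1e-8)
    for (k in dup)
      expect_lt(abs(ev[k + 1] - ev[k]), 1e-8)
  }
})

test_that("reconstructed full-space vectors match dense eigenvectors up to phase", {
  ws <- fixture_ws("lih")
  dm <- fixture_dense("lih")
  e <- eigen(dm$M, symmetric = TRUE)
  st <- solve_states(ws, 4)
  for (s in st) {
    k <- which.min(abs(e$values - s$omega))
    vfull <- c(s$Y_s, s$Y_d)
    # overlap with the dense eigenspace of that eigenvalue
    idx <- which(abs(e$values - s$omega) < 1e-7)
    proj <- e$vectors[, idx, drop = FALSE] %*%
      crossprod(e$vectors[, idx, drop = FALSE], vfull)
    expect_lt(sqrt(sum((vfull - proj)^2)), 1e-6)
  }
})

test_that("forced subspace collapse does not lose converged roots", {
  ws <- fixture_ws("h2o")
  st_big <- solve_states(ws, 6, tol_residual = 1e-9, tol_eigenvalue = 1e-10)
  st_small <- solve_states(ws, 6, max_subspace = 14L, block_width = 3L,
                           tol_residual = 1e-9, tol_eigenvalue = 1e-10)
  ev_big <- sort(vapply(st_big, function(s) s$omega, numeric(1)))
  ev_small <- sort(vapply(st_small, function(s) s$omega, numeric(1)))
  expect_gte(attr(st_small, "diagnostics")$collapses, 1L)
  expect_lt(max(abs(ev_big - ev_small)), 1e-10)
})
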