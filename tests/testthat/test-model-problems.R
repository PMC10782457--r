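# Synthetic model problems and the DOS/convergence relation.

test_that("model problems are bit-reproducible from their seed", {
  a <- generate_model_problem(10, 20, clustering = 2, coupling = 0.1, seed = 42)
  b <- generate_model_problem(10, 20, clustering = 2, coupling = 0.1, seed = 42)
  expect_identical(a, b)
  c_ <- generate_model_problem(10, 20, clustering = 2, coupling = 0.1, seed = 43)
  expect_false(identical(a$M_ss, c_$M_ss))
})

test_that("zero coupling reduces folded solves to the pure singles problem", {
  mp <- generate_model_problem(12, 30, coupling = 0, seed = 5)
  omega <- 0.45
  sys <- folded_system("r", omega, GAMMA_AU, mp$rhs)
  out <- cpp_solve(mp, list(sys))
  oracle <- solve(mp$M_ss - (omega + 1i * GAMMA_AU) * diag(12), mp$rhs)
  expect_lt(max(abs(out$solutions[[1]]$X_s - oracle)), 1e-8 * max(abs(oracle)))
  expect_equal(max(abs(out$solutions[[1]]$X_d)), 0)
})

test_that("doubles diagonal sits above the singles range by default", {
  mp <- generate_model_problem(10, 25, seed = 3)
  expect_gt(min(mp$d), max(eigen(mp$M_ss, symmetric = TRUE,
                                 only.values = TRUE)$values))
})

test_that("DOS estimate: normalization, additivity, histogram limit", {
  mp <- generate_model_problem(10, 25, seed = 9)
  ev <- eigen(assemble_dense(mp)$M, symmetric = TRUE, only.values = TRUE)$values
  # isolate a window holding exactly one eigenvalue, narrow broadening
  e1 <- sort(ev)[1]
  win <- c(e1 - 0.02, e1 + 0.02)
  width_ev <- convert_units(diff(win), "hartree", "ev")
  expect_equal(dos_estimate(mp, win, broadening = 1e-4), 1 / width_ev,
               tolerance = 1e-6)
  # histogram oracle over a wide window
  win2 <- range(ev) + c(-0.1, 0.1)
  n_in <- length(ev)
  expect_equal(dos_estimate(mp, win2, broadening = 1e-4),
               n_in / convert_units(diff(win2), "hartree", "ev"),
               tolerance = 1e-6)
  expect_warning(z <- dos_estimate(mp, c(1, 1)), "empty")
  expect_equal(z, 0)
})

test_that("doubled degeneracy doubles the DOS", {
  mp <- generate_model_problem(6, 10, seed = 1)
  mp2 <- mp
  z6 <- matrix(0, 6, 6)
  mp2$M_ss <- rbind(cbind(mp$M_ss, z6), cbind(z6, mp$M_ss))
  mp2$M_sd <- rbind(mp$M_sd, mp$M_sd)
  mp2$n_s <- 12L
  win <- range(eigen(mp$M_ss, symmetric = TRUE, only.values = TRUE)$values) +
    c(-0.05, 0.05)
  d1 <- dos_estimate(mp, win, broadening = 1e-3)
  d2 <- dos_estimate(mp2, win, broadening = 1e-3)
  # doubling the singles block doubles its contribution to the window
  nd_in_win <- sum(mp$d >= win[1] & mp$d <= win[2])
  expect_equal(nd_in_win, 0L)
  expect_equal(d2 / d1, 2, tolerance = 0.15)
})

test_that("separate-subspace iteration counts grow with the density of states", {
  # the qualitative finding as a statistical property over >= 20 seeds:
  # frequencies probing a spectrally dense region need more iterations
  run1 <- function(clustering, seed) {
    mp <- generate_model_problem(150, 200, clustering = clustering,
                                 coupling = 0.04, seed = seed,
                                 singles_range = c(0.2, 2.0))
    omega <- 0.22           # inside the region where clustering piles states
    sys <- folded_system("r", omega, 0.005, mp$rhs, threshold = 1e-4)
    out <- cpp_solve(mp, list(sys), strategy = "separate", max_iter = 120L)
    c(it = out$diagnostics$groups[[1]]$iterations,
      dos = dos_estimate(mp, c(omega - 0.02, omega + 0.02), broadening = 0.004))
  }
  seeds <- 1:20
  low <- vapply(seeds, function(s) run1(1, s), numeric(2))
  high <- vapply(seeds, function(s) run1(6, s), numeric(2))
  expect_gt(mean(high["dos", ]), mean(low["dos", ]))   # the knob raises the DOS
  expect_gt(mean(high["it", ]), mean(low["it", ]))     # and the iteration count
})
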