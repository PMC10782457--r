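# Backend: XYZ parsing, basis counting, SCF reference, AO/MO integrals.

test_that("XYZ parsing handles valid input and reports malformed lines", {
  m <- parse_xyz("2\n\nH 0 0 0\nH 0 0 0.74")
  expect_s3_class(m, "adc_molecule")
  expect_length(m$symbols, 2L)
  expect_equal(m$coords[2, 3], 0.74)
  expect_equal(m$charge, 0L)
  expect_equal(m$multiplicity, 1L)

  expect_error(parse_xyz("1\n\nXx 0 0 0"), "unknown element")
  expect_error(parse_xyz("abc\n\nH 0 0 0"), "atom count")
  expect_error(parse_xyz("2\n\nH 0 0 0"), "truncated")
  expect_error(parse_xyz("1\n\nH 0 zero 0"), "non-numeric")

  w <- molecule_fixture("h2o")
  expect_length(w$symbols, 3L)
  expect_equal(w$charge, 0L)
  expect_equal(w$multiplicity, 1L)
})

test_that("contracted basis counting reproduces standard set sizes", {
  nora <- molecule_fixture("noradrenaline")
  expect_identical(count_contracted_basis(nora, "aug-cc-pVDZ"), 375L)

  h <- molecule("H", matrix(0, 1, 3))
  c1 <- molecule("C", matrix(0, 1, 3))
  expect_identical(count_contracted_basis(h, "cc-pvdz"), 5L)
  expect_identical(count_contracted_basis(h, "aug-cc-pvdz"), 9L)
  expect_identical(count_contracted_basis(c1, "aug-cc-pvdz"), 23L)
  # one d shell: spherical and Cartesian counts differ by exactly 1
  sph <- count_contracted_basis(c1, "6-311g**", spherical = TRUE)
  cart <- count_contracted_basis(c1, "6-311g**", spherical = FALSE)
  expect_identical(cart - sph, 1L)
  expect_error(count_contracted_basis(h, "no-such-basis"), "registry")
})

test_that("AO integrals match an independent implementation (frozen oracle)", {
  ref <- fixture_ref("h2o")
  aob <- ref$ao
  S <- ao_integral(aob, "overlap")
  expect_equal(dim(S), c(7L, 7L))
  expect_equal(S[3, ], c(0, 0, 1, 0, 0, 0, 0), tolerance = 1e-12)
  eri <- ref$ao_eri
  frozen <- c(`1,1,1,1` = 4.785069087287, `1,2,3,3` = 0.256683023444,
              `3,4,3,4` = 0.047444422900, `4,4,5,5` = 0.785269800099,
              `2,3,4,5` = 0.0)
  for (nm in names(frozen)) {
    idx <- as.integer(strsplit(nm, ",")[[1]])
    expect_equal(eri[idx[1], idx[2], idx[3], idx[4]], frozen[[nm]],
                 tolerance = 1e-9)
  }
  Ly <- ao_integral(aob, "angmom", comp = 2, origin = c(0.1, -0.2, 0.3))
  expect_equal(Ly[3, 6], -0.258573752093, tolerance = 1e-9)
  expect_equal(Ly, -t(Ly), tolerance = 1e-12)
})

test_that("restricted SCF converges to the independent-oracle energy", {
  ref <- fixture_ref("h2")
  expect_identical(ref$n_occupied, 1L)
  expect_identical(ref$n_virtual, 1L)
  # MO orthonormality in the AO metric
  C <- ref$mo_coefficients
  expect_equal(t(C) %*% ref$ao_overlap %*% C, diag(2), tolerance = 1e-10)

  refw <- fixture_ref("h2o")
  expect_equal(refw$scf_energy, -74.9631463432, tolerance = 1e-8)
  C <- refw$mo_coefficients
  expect_equal(t(C) %*% refw$ao_overlap %*% C, diag(7), tolerance = 1e-10)
  # density idempotency: P S P = 2 P for the closed-shell density
  Co <- C[, 1:5]
  P <- 2 * Co %*% t(Co)
  expect_equal(P %*% refw$ao_overlap %*% P, 2 * P, tolerance = 1e-8)
  expect_true(all(diff(refw$orbital_energies[1:5]) > -1e-12))

  expect_error(build_reference(molecule("H", matrix(0, 1, 3)), "sto-3g"),
               "odd electron")
})

test_that("helium property integrals vanish by symmetry; momentum is antisymmetric", {
  he <- build_reference(molecule("He", matrix(0, 1, 3)), "sto-3g")
  for (k in 1:3)
    expect_equal(max(abs(mo_operator(he, "dipole", comp = k))), 0,
                 tolerance = 1e-12)
  ref <- fixture_ref("h2o")
  for (k in 1:3) {
    p <- ao_integral(ref$ao, "deriv", comp = k)
    expect_equal(p, -t(p), tolerance = 1e-10)
  }
})

test_that("magnetic gauge-origin shift follows the cross-product rule", {
  ref <- fixture_ref("h2o")
  aob <- ref$ao
  O1 <- c(0, 0, 0); O2 <- c(0.4, -0.3, 0.7)
  d <- O2 - O1
  D <- lapply(1:3, function(k) ao_integral(aob, "deriv", comp = k))
  for (comp in 1:3) {
    L1 <- ao_integral(aob, "angmom", comp = comp, origin = O1)
    L2 <- ao_integral(aob, "angmom", comp = comp, origin = O2)
    cyc <- list(c(2, 3), c(3, 1), c(1, 2))[[comp]]
    shift <- d[cyc[1]] * D[[cyc[2]]] - d[cyc[2]] * D[[cyc[1]]]
    expect_equal(L2, L1 - shift, tolerance = 1e-10)
  }
})

test_that("batched auxiliary-Fock MO transform equals the direct transform", {
  ref <- fixture_ref("h2o")
  g_direct <- mo_eri_spatial(ref, method = "direct")
  g_all <- mo_eri_spatial(ref, "all", "fock")
  g_b1 <- mo_eri_spatial(ref, 1, "fock")
  g_b3 <- mo_eri_spatial(ref, 3, "fock")
  expect_lt(max(abs(g_all - g_direct)), 1e-10)
  expect_lt(max(abs(g_b1 - g_all)), 1e-12)
  expect_lt(max(abs(g_b3 - g_all)), 1e-12)
  expect_error(mo_eri_spatial(ref, 3, max_memory_mb = 1e-6), "batch")
})

test_that("spin-orbital antisymmetrized integrals have the right symmetries", {
  ints <- list(g = fixture_ws("h2")$g)  # reuse workspace tensor
  g <- ints$g
  expect_lt(max(abs(g + aperm(g, c(2, 1, 3, 4)))), 1e-10)
  expect_lt(max(abs(g + aperm(g, c(1, 2, 4, 3)))), 1e-10)
  expect_lt(max(abs(g - aperm(g, c(3, 4, 1, 2)))), 1e-10)
  # H2/STO-3G oovv block: every nonzero element is the same unique integral
  ws <- fixture_ws("h2")
  vals <- unique(round(abs(ws$g_oovv[abs(ws$g_oovv) > 1e-14]), 12))
  expect_length(vals, 1L)
})
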