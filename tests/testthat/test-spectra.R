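# Spectral observables.

test_that("CPP response equals the damped SOS over the complete dense spectrum", {
  ws <- fixture_ws("h2o")
  grid <- freq_grid(0.30, 0.52, count = 5)
  sr <- compute_uvvis_cpp(ws, grid, GAMMA_AU)
  amps <- fixture_amps("h2o")
  en <- vapply(fixture_dense_states("h2o"), function(s) s$omega, numeric(1))
  alpha_sos <- vapply(grid, function(w)
    (damped_sos(en, amps[[1]], amps[[1]], w, GAMMA_AU) +
       damped_sos(en, amps[[2]], amps[[2]], w, GAMMA_AU) +
       damped_sos(en, amps[[3]], amps[[3]], w, GAMMA_AU)) / 3, complex(1))
  expect_lt(max(abs(sr$alpha_iso - alpha_sos)) / max(abs(alpha_sos)), 1e-8)
  expect_true(all(Im(sr$alpha_iso) >= 0))
  expect_true(all(sr$data$sigma_au >= 0))
})

test_that("absorption spectrum is invariant under rigid molecular rotation", {
  ws1 <- fixture_ws("h2o")
  ref2 <- build_reference(rotate_molecule(molecule_fixture("h2o")), "sto-3g")
  ws2 <- adc_workspace(mo_integral_set(ref2))
  grid <- freq_grid(0.38, 0.50, count = 3)
  s1 <- compute_uvvis_cpp(ws1, grid, GAMMA_AU)
  s2 <- compute_uvvis_cpp(ws2, grid, GAMMA_AU)
  expect_lt(max(abs(s1$data$sigma_au - s2$data$sigma_au)), 1e-8)
})

test_that("ECD flips sign between enantiomers and rotates invariantly", {
  grid <- freq_grid(0.33, 0.40, count = 3)
  wsp <- fixture_ws("h2o2_p")
  wsm <- fixture_ws("h2o2_m")
  cdp <- compute_cd_cpp(wsp, grid, GAMMA_AU)
  cdm <- compute_cd_cpp(wsm, grid, GAMMA_AU)
  scale <- max(abs(cdp$data$delta_epsilon))
  expect_gt(scale, 0)
  expect_lt(max(abs(cdp$data$delta_epsilon + cdm$data$delta_epsilon)) / scale,
            1e-8)
  refr <- build_reference(rotate_molecule(molecule_fixture("h2o2_p")), "sto-3g")
  cdr <- compute_cd_cpp(adc_workspace(mo_integral_set(refr)), grid, GAMMA_AU)
  expect_lt(max(abs(cdp$data$delta_epsilon - cdr$data$delta_epsilon)) / scale,
            1e-6)
})

test_that("window-complete stick spectra reproduce the CPP spectra", {
  ws <- fixture_ws("h2o")
  grid <- freq_grid(0.38, 0.50, count = 4)
  uv <- compute_uvvis_cpp(ws, grid, GAMMA_AU)
  sticks_all <- stick_table(ws, fixture_dense_states("h2o"))
  lb <- lorentzian_broadening(sticks_all, GAMMA_AU, grid)
  expect_lt(max(abs(uv$data$sigma_au - lb$data$sigma_au)) /
              max(uv$data$sigma_au), 1e-2)
  wsp <- fixture_ws("h2o2_p")
  gridc <- freq_grid(0.33, 0.40, count = 3)
  cdp <- compute_cd_cpp(wsp, gridc, GAMMA_AU)
  lbc <- lorentzian_broadening(stick_table(wsp, fixture_dense_states("h2o2_p")),
                               GAMMA_AU, gridc)
  expect_lt(max(abs(cdp$data$delta_epsilon - lbc$data$delta_epsilon)) /
              max(abs(cdp$data$delta_epsilon)), 1e-2)
})

test_that("an energetically isolated state gives the analytic one-line profile", {
  # H2/STO-3G: a single bright singlet far from all other bright states
  ws <- fixture_ws("h2")
  tb <- stick_table(ws, fixture_dense_states("h2"))
  bright <- tb[tb$osc_strength > 1e-8, ]
  expect_identical(nrow(bright), 1L)
  w0 <- bright$energy_au[1]
  grid <- c(w0 - 2 * GAMMA_AU, w0, w0 + 2 * GAMMA_AU)
  uv <- compute_uvvis_cpp(ws, grid, GAMMA_AU)
  one <- lorentzian_broadening(bright, GAMMA_AU, grid)
  expect_lt(max(abs(uv$data$sigma_au - one$data$sigma_au)) /
              max(uv$data$sigma_au), 1e-6)
})

test_that("plain Lorentzian sticks: peak formula and integrated intensity", {
  sticks <- data.frame(energy_au = 0.4, osc_strength = 0.05)
  gam <- 0.005
  pk <- lorentzian_broadening(sticks, gam, 0.4, shape = "lorentzian")
  expect_equal(pk$data$sigma_au, 2 * pi * 0.05 / (137.035999084 * gam),
               tolerance = 1e-12)
  grid <- seq(0.1, 0.7, by = 1e-4)
  sp <- lorentzian_broadening(sticks, gam, grid, shape = "lorentzian")
  integral <- sum(sp$data$sigma_au) * 1e-4
  expect_equal(integral, 2 * pi^2 / 137.035999084 * 0.05, tolerance = 0.01)
})

test_that("empty stick lists give a zero spectrum with a warning", {
  grid <- freq_grid(0.3, 0.5, count = 5)
  expect_warning(sp <- lorentzian_broadening(
    data.frame(energy_au = numeric(0), osc_strength = numeric(0)),
    GAMMA_AU, grid), "empty")
  expect_equal(max(abs(sp$data$sigma_au)), 0)
})

test_that("unit conversion round trips and the damping value convert correctly", {
  expect_equal(convert_units(1000, "cm-1", "hartree"), 1000 / 219474.6313632,
               tolerance = 1e-12)
  expect_equal(convert_units(0, "ev", "cm-1"), 0)
  x <- c(0.2, 4.7, 11)
  expect_equal(convert_units(convert_units(x, "ev", "cm-1"), "cm-1", "ev"), x,
               tolerance = 1e-12)
  expect_equal(convert_units(convert_units(x, "hartree", "ev"), "ev", "hartree"),
               x, tolerance = 1e-12)
  expect_error(convert_units(1, "hartree", "parsec"), "unsupported")
})
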