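# Spectral observables: UV/vis absorption cross sections and ECD spectra
# from damped response functions (CPP route) or Lorentzian-broadened stick
# spectra, plus the damped sum-over-states used as an oracle and for the
# stick route.
#
# Conventions (atomic units unless stated): the absorption cross section is
# sigma(w) = (4 pi w / c) Im alpha_iso(w); the ECD intensity is expressed
# through a broadened rotatory-strength density rho_R(w) (au of rotatory
# strength per au of energy) converted to the decadic molar extinction
# anisotropy Delta-epsilon in L mol^-1 cm^-1 via the standard relation
# Delta-eps(nu) = nu * rho_R^{(1e-40 cgs, per cm^-1)}(nu) / 22.97.

CD_CONVERSION_DENOM <- 22.97  # R in 1e-40 esu^2 cm^2, nu in cm^-1

#' Full dense-spectrum eigenstates (oracle)
#'
#' Diagonalizes the dense singles+doubles matrix and returns every
#' eigenpair as an `eigen_state`, for sum-over-states oracles and stick
#' spectra on small systems.
#'
#' @param ws workspace.
#' @param cap dense-dimension cap (see [assemble_dense()]).
#' @export
dense_states <- function(ws, cap = 5000L) {
  dm <- assemble_dense(ws, cap)
  e <- eigen(dm$M, symmetric = TRUE)
  ord <- order(e$values)
  lapply(ord, function(k) {
    v <- e$vectors[, k]
    structure(list(omega = e$values[k], Y_s = v[seq_len(dm$ns)],
                   Y_d = v[dm$ns + seq_len(dm$nd)], residual_norm = 0,
                   eigenvalue_error = 0, converged = TRUE),
              class = "eigen_state")
  })
}

#' Damped sum-over-states response
#'
#' `sum_n [ x_n(A) conj(x_n(B)) / (w_n - w - i g) +
#'          conj(x_n(A)) x_n(B) / (w_n + w + i g) ]`
#' over a complete set of states.
#'
#' @param energies excitation energies (hartree).
#' @param amps_A,amps_B complex amplitude vectors over states.
#' @param omega frequency (hartree).
#' @param gamma damping (hartree).
#' @return complex response value.
#' @export
damped_sos <- function(energies, amps_A, amps_B, omega, gamma) {
  sum(amps_A * Conj(amps_B) / (energies - omega - 1i * gamma)) +
    sum(Conj(amps_A) * amps_B / (energies + omega + 1i * gamma))
}

#' Absorption cross section from the imaginary polarizability
#'
#' `sigma(w) = (4 pi w / c) Im alpha_iso(w)` (atomic units).
#' @param omega frequencies (hartree).
#' @param im_alpha_iso imaginary part of the isotropic dipole
#'   polarizability at those frequencies.
#' @export
absorption_cross_section <- function(omega, im_alpha_iso) {
  4 * pi * omega / SPEED_OF_LIGHT_AU * im_alpha_iso
}

# Delta-epsilon (L mol^-1 cm^-1) from a rotatory-strength density in au
.cd_from_rotdens <- function(omega, rotdens_au) {
  nu_cm <- convert_units(omega, "hartree", "cm-1")
  rho40_per_cm <- rotdens_au * ROTATORY_AU_TO_CGS40 / HARTREE_CM1
  nu_cm * rho40_per_cm / CD_CONVERSION_DENOM
}

.spectrum_result <- function(omega, sigma = NULL, delta_epsilon = NULL,
                             provenance, diagnostics = NULL) {
  df <- data.frame(omega_au = omega,
                   omega_ev = convert_units(omega, "hartree", "ev"))
  if (!is.null(sigma)) df$sigma_au <- sigma
  if (!is.null(delta_epsilon)) df$delta_epsilon <- delta_epsilon
  structure(list(data = df, provenance = provenance,
                 diagnostics = diagnostics), class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum (%s): %d grid points>\n", x$provenance, nrow(x$data)))
  print(utils::head(x$data, 4))
  invisible(x)
}

#' Write a spectrum as CSV
#' @param sr a `spectrum_result`.
#' @param path output file.
#' @export
write_spectrum_csv <- function(sr, path) {
  utils::write.csv(sr$data, path, row.names = FALSE)
  invisible(path)
}

#' Enqueue the folded response equations of a CPP setup
#'
#' Builds the full list of folded complex response equations for a set of
#' operator components over a frequency grid: one equation per component,
#' frequency and sign branch of the response function (two reduced-space
#' equations per response function).
#'
#' @param ws molecular workspace.
#' @param operator operator name (see [mo_operator()]).
#' @param comps Cartesian components.
#' @param omegas frequency grid (hartree).
#' @param gamma damping (hartree).
#' @param threshold relative-residual threshold.
#' @param moment_order perturbative order of the transition moments.
#' @return list of `folded_system` objects.
#' @export
enqueue_response_systems <- function(ws, operator = "dipole", comps = 1:3,
                                     omegas, gamma, threshold = 1e-4,
                                     moment_order = 2L) {
  systems <- list()
  for (k in comps) {
    F <- modified_transition_moments(ws, operator, comp = k,
                                     order = moment_order)
    for (w in omegas)
      systems <- c(systems, .pair_systems(F, w, gamma, threshold,
                                          paste0(operator, k)))
  }
  systems
}

# enqueue the +w/-w pair of folded systems for one (operator, frequency)
.pair_systems <- function(F, omega, gamma, threshold, tag) {
  list(folded_system(tag, omega, gamma, F$F_s, F$F_d, threshold,
                     id = paste0(tag, "@+", signif(omega, 8))),
       folded_system(tag, -omega, gamma, F$F_s, F$F_d, threshold,
                     id = paste0(tag, "@-", signif(omega, 8))))
}

#' UV/vis absorption spectrum via the folded CPP solver
#'
#' Solves the damped response equations for the three electric-dipole
#' components over a frequency grid (both frequency branches per response
#' function) and assembles `sigma(w)`.
#'
#' @param ws molecular workspace.
#' @param omegas frequency grid (hartree).
#' @param gamma damping (hartree), common to all states.
#' @param strategy subspace strategy, see [cpp_solve()].
#' @param threshold relative-residual threshold per equation.
#' @param moment_order perturbative order of the transition moments.
#' @return a `spectrum_result`; the CPP solutions and solver diagnostics
#'   are attached.
#' @export
compute_uvvis_cpp <- function(ws, omegas, gamma, strategy = "separate",
                              threshold = 1e-4, moment_order = 2L) {
  Fm <- lapply(1:3, function(k)
    modified_transition_moments(ws, "dipole", comp = k, order = moment_order))
  systems <- list()
  for (k in 1:3) for (w in omegas)
    systems <- c(systems, .pair_systems(Fm[[k]], w, gamma, threshold,
                                        paste0("mu", c("x", "y", "z")[k])))
  out <- cpp_solve(ws, systems, strategy = strategy)
  sol <- out$solutions
  alpha <- vapply(seq_along(omegas), function(iw) {
    acc <- 0 + 0i
    for (k in 1:3) {
      base <- (k - 1L) * 2L * length(omegas) + (match(omegas[iw], omegas) - 1L) * 2L
      sp <- sol[[base + 1L]]; sm <- sol[[base + 2L]]
      acc <- acc + response_value(Fm[[k]], sp, allow_unconverged = TRUE) +
        Conj(response_value(Fm[[k]], sm, allow_unconverged = TRUE))
    }
    acc / 3
  }, complex(1))
  sr <- .spectrum_result(omegas,
                         sigma = absorption_cross_section(omegas, Im(alpha)),
                         provenance = "cpp", diagnostics = out$diagnostics)
  sr$alpha_iso <- alpha
  sr$solutions <- sol
  sr
}

#' ECD spectrum via the folded CPP solver
#'
#' Velocity-form electronic circular dichroism: the mixed linear-momentum /
#' magnetic-dipole response is evaluated over the grid and converted to the
#' decadic molar extinction anisotropy.
#'
#' @inheritParams compute_uvvis_cpp
#' @param gauge_origin origin for the magnetic-dipole operator (bohr).
#' @export
compute_cd_cpp <- function(ws, omegas, gamma, strategy = "separate",
                           threshold = 1e-4, moment_order = 2L,
                           gauge_origin = NULL) {
  Fp <- lapply(1:3, function(k)
    modified_transition_moments(ws, "linmom", comp = k, order = moment_order))
  Fmg <- lapply(1:3, function(k)
    modified_transition_moments(ws, "magdip", comp = k, origin = gauge_origin,
                                order = moment_order))
  systems <- list()
  for (k in 1:3) for (w in omegas)
    systems <- c(systems, .pair_systems(Fmg[[k]], w, gamma, threshold,
                                        paste0("m", c("x", "y", "z")[k])))
  out <- cpp_solve(ws, systems, strategy = strategy)
  sol <- out$solutions
  mixed <- vapply(seq_along(omegas), function(iw) {
    acc <- 0 + 0i
    for (k in 1:3) {
      base <- (k - 1L) * 2L * length(omegas) + (iw - 1L) * 2L
      sp <- sol[[base + 1L]]; sm <- sol[[base + 2L]]
      acc <- acc + response_value(Fp[[k]], sp, allow_unconverged = TRUE) +
        Conj(response_value(Fp[[k]], sm, allow_unconverged = TRUE))
    }
    acc
  }, complex(1))
  rotdens <- -Im(mixed) / (pi * omegas)
  sr <- .spectrum_result(omegas,
                         delta_epsilon = .cd_from_rotdens(omegas, rotdens),
                         provenance = "cpp", diagnostics = out$diagnostics)
  sr$mixed_response <- mixed
  sr$rotdens <- rotdens
  sr
}

#' Stick table of excited-state properties
#'
#' Excitation energies, oscillator strengths and rotatory strengths (length
#' and velocity gauge) contracted from modified transition moments and a
#' list of states (from [solve_states()] or [dense_states()]).
#'
#' @param ws molecular workspace.
#' @param states list of `eigen_state` objects.
#' @param gauge_origin origin for the magnetic-dipole operator (bohr).
#' @param moment_order perturbative order of the transition moments.
#' @return data.frame with columns `state`, `energy_au`, `energy_ev`,
#'   `osc_strength`, `rot_length`, `rot_velocity`.
#' @export
stick_table <- function(ws, states, gauge_origin = NULL, moment_order = 2L) {
  en <- vapply(states, function(s) s$omega, numeric(1))
  amp <- function(opname) {
    t(vapply(1:3, function(k) {
      F <- modified_transition_moments(ws, opname, comp = k,
                                       origin = gauge_origin,
                                       order = moment_order)
      vapply(states, function(s)
        transition_amplitude(F, s, allow_unconverged = TRUE), complex(1))
    }, complex(length(states))))
  }
  dip <- amp("dipole"); p <- amp("linmom"); mg <- amp("magdip")
  if (length(states) == 1L) {
    dip <- matrix(dip, 3); p <- matrix(p, 3); mg <- matrix(mg, 3)
  }
  data.frame(state = seq_along(states), energy_au = en,
             energy_ev = convert_units(en, "hartree", "ev"),
             osc_strength = oscillator_strength(en, dip),
             rot_length = rotatory_strength(en, dip, mg, "length"),
             rot_velocity = rotatory_strength(en, p, mg, "velocity"))
}

#' Lorentzian broadening of a stick spectrum
#'
#' Superposes area-normalized Lorentzians of half-width `gamma` on a
#' frequency grid, in the same units as the CPP route so the two spectra
#' are directly comparable: oscillator-strength sticks give `sigma(w)` in
#' au; rotatory-strength sticks (velocity gauge, au) give Delta-epsilon in
#' L mol^-1 cm^-1.
#'
#' @param sticks data.frame with `energy_au` and `osc_strength` and/or
#'   `rot_velocity` (as from [stick_table()]).
#' @param gamma Lorentzian half-width at half-maximum (hartree).
#' @param grid frequency grid (hartree).
#' @param shape `"damped"` uses the exact line shape of the damped response
#'   function (resonant and antiresonant branch, `w/w_n` weighting), so a
#'   window-complete stick list reproduces the CPP spectrum; `"lorentzian"`
#'   is the plain resonant Lorentzian superposition.
#' @return a `spectrum_result` with provenance `"sticks"`.
#' @export
lorentzian_broadening <- function(sticks, gamma, grid,
                                  shape = c("damped", "lorentzian")) {
  shape <- match.arg(shape)
  if (gamma <= 0) stop("gamma must be positive")
  if (nrow(sticks) == 0L) {
    warning("empty stick list; returning zero spectrum")
    return(.spectrum_result(grid, sigma = rep(0, length(grid)),
                            delta_epsilon = rep(0, length(grid)),
                            provenance = "sticks"))
  }
  lor <- function(w0) (gamma / pi) / ((grid - w0)^2 + gamma^2)
  sig <- NULL
  de <- NULL
  if (!is.null(sticks$osc_strength)) {
    sig <- rep(0, length(grid))
    for (k in seq_len(nrow(sticks))) {
      wn <- sticks$energy_au[k]
      g <- if (shape == "damped")
        (grid / wn) * (lor(wn) - lor(-wn)) else lor(wn)
      sig <- sig + 2 * pi^2 / SPEED_OF_LIGHT_AU * sticks$osc_strength[k] * g
    }
  }
  if (!is.null(sticks$rot_velocity)) {
    rho <- rep(0, length(grid))
    for (k in seq_len(nrow(sticks))) {
      wn <- sticks$energy_au[k]
      g <- if (shape == "damped")
        (wn / grid) * (lor(wn) - lor(-wn)) else lor(wn)
      rho <- rho + sticks$rot_velocity[k] * g
    }
    de <- .cd_from_rotdens(grid, rho)
  }
  .spectrum_result(grid, sigma = sig, delta_epsilon = de,
                   provenance = "sticks")
}
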