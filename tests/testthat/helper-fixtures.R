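# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture_ref <- function(name, basis = "sto-3g") {
  key <- paste(name, basis, sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_reference(molecule_fixture(name), basis)
  .fixture_cache[[key]]
}

fixture_ws <- function(name, basis = "sto-3g") {
  key <- paste("ws", name, basis, sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- adc_workspace(mo_integral_set(fixture_ref(name, basis)))
  .fixture_cache[[key]]
}

fixture_dense <- function(name, basis = "sto-3g") {
  key <- paste("dense", name, basis, sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- assemble_dense(fixture_ws(name, basis))
  .fixture_cache[[key]]
}

fixture_dense_states <- function(name, basis = "sto-3g") {
  key <- paste("ds", name, basis, sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- dense_states(fixture_ws(name, basis))
  .fixture_cache[[key]]
}

# damping used throughout: 1000 cm^-1
GAMMA_AU <- 1000 / 219474.6313632

# complete-spectrum dipole (or other operator) amplitudes for SOS oracles
fixture_amps <- function(name, basis = "sto-3g", operator = "dipole") {
  key <- paste("amps", name, basis, operator, sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    ws <- fixture_ws(name, basis)
    ds <- fixture_dense_states(name, basis)
    .fixture_cache[[key]] <- lapply(1:3, function(k) {
      F <- modified_transition_moments(ws, operator, comp = k)
      vapply(ds, function(s) transition_amplitude(F, s), complex(1))
    })
  }
  .fixture_cache[[key]]
}

# synthetic zero-interaction system (Fock-only limit)
noninteracting_system <- function(n = 6L, nocc = 3L) {
  eps <- sort(c(-2, -1.4, -1.1, 0.7, 1.2, 2.1))[seq_len(n)]
  list(orbital_energies = eps, g = array(0, c(n, n, n, n)), n_occ = nocc)
}
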