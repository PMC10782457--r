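# adcfold

UV/vis absorption and electronic circular dichroism (ECD) spectra of small
closed-shell molecules at the ADC(2) level — the second-order
algebraic-diagrammatic construction scheme for the polarization propagator —
computed with *matrix-folded* solvers that never store vectors in the large
two-particle–two-hole (2p–2h) manifold.

## Who this is for

Method developers and students who want a compact, fully self-contained,
oracle-validated reference implementation of damped (complex polarization
propagator, CPP) linear response and nonlinear folded eigensolvers at the
ADC(2) level. Everything runs on desk-scale molecules (minimal and small
split-valence bases); there is no integral approximation, no
parallelization and no external quantum-chemistry dependency — the package
carries its own McMurchie–Davidson Gaussian integral engine and RHF/DIIS
backend.

## The method in brief

ADC(2) poses the Hermitian eigenvalue problem **M Y = Y Ω** for the shifted
Hamiltonian represented in an orthonormalized, correlated excited-state
basis spanned by particle–hole (p–h, "singles") and 2p–2h ("doubles")
excitations. In strict ADC(2) the doubles/doubles block is diagonal with
entries `ε_a + ε_b − ε_i − ε_j`, so both the damped response equation

    (M − (ω + iγ) 1) X = B

and the eigenvalue problem can be *folded* exactly onto the singles space
through the doubles resolvent:

    [M_ss − M_sd diag(1/(d − ω − iγ)) M_ds − (ω + iγ)] X_s = B_s′
    M_eff(ω) Y_s = ω Y_s ,   M_eff(ω) = M_ss + M_sd (ω − d)⁻¹ M_ds

The folded response equation is solved in real algebra as a symmetric
coupled system for (X^R, X^I) in an iterative subspace of trial vectors,
with either a *separate* subspace per frequency (each handling all
right-hand sides at that frequency) or one *common* pool for all
frequencies; the frequency-dependent actions σ′(ω), σ″(ω) of the folded
operator are counted per construction. The nonlinear eigenproblem is
solved root-by-root with Ritz extraction, Newton–Raphson refinement of the
eigenvalue through Θ(ω) = yᵀM_eff(ω)y, a block of higher roots feeding the
subspace, and controlled subspace collapse. Spectral intensities come from
modified transition moments F (singles block through second order — 13
second-order terms, dominated by the ⟨vv‖vv⟩ particle-ladder term — and
first-order doubles block):

    σ(ω)  = (4πω/c) · Im ᾱ(ω)                       (au)
    Δε(ω) from the mixed linear-momentum/magnetic-dipole response
           (velocity gauge), in L·mol⁻¹·cm⁻¹

A dense assembly of the full singles+doubles matrix serves as the
validation oracle, and the ADC(2) working equations themselves are
pinned against an exact determinant-space construction of the
intermediate-state representation (see the methods vignette).

## Worked example

```r
library(adcfold)
mol <- molecule_fixture("h2o")          # near-equilibrium water
ref <- build_reference(mol, "sto-3g")   # RHF/DIIS
ref
#> <RHF reference: 7 AO, 5 occ / 2 virt, E = -74.9631463432 hartree>

ws <- adc_workspace(mo_integral_set(ref))
ws
#> <ADC(2) workspace: 14 spin orbitals (10 occ), n_s = 40, n_d = 270, E_MP2 = -0.03560849>

states <- solve_states(ws, 8)           # folded nonlinear eigensolver
stick_table(ws, states)
#>   state energy_au energy_ev osc_strength rot_length rot_velocity
#> 1     1    0.4053     11.03    1.270e-31  2.934e-31   -1.773e-31
#> 4     4    0.4728     12.86    3.346e-03 -6.766e-16    4.698e-16
#> ...

gamma <- convert_units(1000, "cm-1", "hartree")
grid  <- convert_units(freq_grid(10, 14, count = 5), "ev", "hartree")
compute_uvvis_cpp(ws, grid, gamma)      # folded CPP solver
#> <spectrum (cpp): 5 grid points>
#>    omega_au omega_ev    sigma_au
#> 1 0.3674932       10 0.000713195
#> 2 0.4042425       11 0.001052872
#> 3 0.4409919       12 0.001949429
#> 4 0.4777412       13 0.017508395
```

The first three states are the components of a dark triplet at 11.03 eV;
the first bright singlet sits at 12.86 eV with oscillator strength 3.3·10⁻³
(rotatory strengths vanish for achiral water), and the CPP cross section
rises accordingly across the 10–14 eV window.

A thin command-line wrapper is installed under `inst/scripts/adcfold`:

```sh
Rscript inst/scripts/adcfold cpp    --xyz water.xyz --basis sto-3g --freqs 8:14:25 --gamma 1000
Rscript inst/scripts/adcfold states --xyz water.xyz --basis sto-3g --nstates 10
Rscript inst/scripts/adcfold model  --ns 50 --nd 120 --seed 7
```

## Scope and limitations

Strict ADC(2) only (no extended doubles block, no ADC(3)); closed-shell
RHF references; s/p Gaussian basis data embedded for STO-3G (H–Ne) and
6-31G (H, O), with shell-composition tables for counting larger standard
sets; no resolution-of-identity approximation and no distributed
parallelism. See `vignettes/folded-adc2-response.Rmd` for the model
assumptions, numerical choices and known limitations.
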