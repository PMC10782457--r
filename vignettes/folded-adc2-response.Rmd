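---
title: "Matrix-folded ADC(2) response and eigensolvers: models, conventions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-folded ADC(2) response and eigensolvers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcfold)
```

This vignette records the model, the conventions and the numerical choices
behind `adcfold`, in the spirit of a methods appendix: what exactly is
computed, which knobs matter, how the open design questions were settled,
and what the test suite does and does not demonstrate.

## The model

ADC(2) — the second-order algebraic-diagrammatic construction for the
polarization propagator — represents the Hamiltonian, shifted by the
ground-state energy, in an orthonormalized basis of correlated excited
states (the intermediate-state representation, ISR) built from
particle–hole (p–h) and two-particle–two-hole (2p–2h) excitations of the
Møller–Plesset ground state. The package works in a **spin-orbital
formulation** throughout (alpha/beta interleaved per spatial orbital):
this is the clearest mapping to the working equations, at the cost of
carrying spin-forbidden (triplet) roots explicitly — they appear as
degenerate multiplets with vanishing transition amplitudes, as seen for
water in the README example. Spatial-orbital spin adaptation would be an
optimization, not a change of model.

The secular-matrix blocks used are, with `t_ijab = <ij||ab>/(e_i+e_j-e_a-e_b)`:

* `M_ss` through second order: orbital-energy differences, the first-order
  coupling `-<ja||ib>`, and the symmetrized second-order
  particle/hole/mixed terms,
* `M_sd` at first order (four antisymmetrized one-index-overlap terms),
* `M_dd` at zeroth order: **diagonal**, `e_a + e_b - e_i - e_j` over pairs
  `i<j`, `a<b`.

The diagonality of `M_dd` is what makes exact *matrix folding* possible:
both the damped linear-response equation and the eigenvalue problem are
reduced to the p–h manifold through the doubles resolvent (see the README
for the folded equations). No approximation is introduced by folding.

### Conventions pinned by an exact oracle

The literature states these blocks in several inequivalent sign/ordering
conventions, and the doubles-manifold phase depends on the operator order
chosen for the 2p–2h excitation operators. All conventions in this package
are fixed against a **determinant-space construction of the ISR**: on tiny
synthetic fermion systems (6 spin orbitals, 3 particles, random
antisymmetrized two-electron integrals with a canonical diagonal Fock
matrix) the test helper builds the many-body Hamiltonian in the full
determinant basis, forms the Møller–Plesset series by linear algebra,
orthogonalizes the precursor states class by class (Gram–Schmidt of the
doubles class against the singles intermediates, symmetric
orthonormalization within each class) carried as a power series in the
perturbation order, and reads off `M_ss` through second order, `M_sd` at
first, `M_dd` at zeroth, and the modified transition moments `F_s` through
second and `F_d` at first order. The production contractions must agree
with this construction to ~1e-12; they do (`test-isr-conventions.R`).
With the doubles excitation operators ordered as
`C = a_a^+ a_b^+ a_j a_i` (`i<j`, `a<b`), the oracle fixes `M_sd` with the
opposite overall sign to the form most often printed; since the folded
equations contain `M_sd` quadratically this changes no observable, but it
does fix the relative phase of `F_d` and the doubles parts of response
vectors, which enter observables linearly.

### Modified transition moments

For a one-electron operator with MO matrix `theta`, the singles block is

    F_ia = theta_ai                                   (order 0)
         + sum_jb theta_jb t_ijab                     (order 1)
         + 13 second-order terms

The second-order terms group naturally as: the second-order singles
amplitudes `ts2` contracted with `theta_vv` and `theta_oo` (2 x 2 = 4
terms, since `ts2` has two integral contributions), the second-order
doubles amplitudes `td2` contracted with `theta_ov` (particle ladder with
`<vv||vv>` integrals, hole ladder with `<oo||oo>`, and the four
antisymmetrized ring pieces: 6 terms), and three explicit `t2.t2`
contractions with `theta_vo` (a chain term with weight 1/2 and two
density-like terms with weight 1/4). The particle-ladder term — two nested
loops over occupied and virtual pairs with an energy denominator whose
indices mix free and summed labels — is the one that dominates cost at
scale (it is the only O(o²v⁴) term with its own denominator). The doubles
block is first order: `F_d = P(ab) theta_ac t_ijcb - P(ij) theta_ki t_kjab`.
`mtm_second_order_terms()` exposes the 13 terms individually; each is
checked against a naive nested-loop evaluation, and their sum against the
determinant-space ISR. Operator matrices for the linear-momentum,
angular-momentum and magnetic-dipole operators are imaginary-Hermitian
over real orbitals and are carried as complex matrices including their
factors of i (`p = -i∇`, `m = -L/2`); amplitudes and response values are
complex throughout.

## Solvers

### Damped response (CPP)

Each response function at frequency `w > 0` requires two reduced-space
solves (`+w` and `-w` branches; the second contributes as its complex
conjugate). The complex folded equation is solved in real algebra as the
symmetric coupled system for `(X^R, X^I)` shown in the README; the direct
complex solve against the dense matrix exists purely as an oracle.

Tunables (defaults chosen once, used everywhere):

* **Convergence**: relative residual `||r|| / ||B'||` per system,
  threshold `1e-4` (`threshold` of `folded_system()`); the folded
  right-hand side norm is the reference.
* **Trial vectors**: the initial block is the preconditioned real and
  imaginary parts of each folded right-hand side; new vectors are
  preconditioned residuals. The preconditioner is the real part of the
  diagonal folded resolvent, `(d0-w)/((d0-w)^2+gamma^2)` with `d0` the
  orbital-energy-difference diagonal — bounded through resonances, no
  level shifts.
* **Orthonormalization**: modified Gram–Schmidt with one
  re-orthogonalization pass; vectors with post-projection norm below
  `1e-8` are dropped.
* **Subspace strategies**: `"separate"` builds one subspace per distinct
  `(w, gamma)` handling all right-hand sides at that frequency;
  `"common"` pools trial vectors across all systems. Because the folded
  operator is frequency dependent, sigma pairs must be built per
  frequency; the solver counts them per construction. For the separate
  strategy the sigma-pair count equals the trial-vector count per
  frequency; for the common strategy each iteration costs
  (new vectors) x (unconverged frequencies) pairs. Whether the common
  pool should span operators as well as frequencies is not dictated by
  the formalism; both behaviors exist (`common_pool = "all"` (default) or
  `"per-operator"`).
* **Determinism**: there is no randomness anywhere in the solvers; runs
  are bit-reproducible from their configuration.

### Folded nonlinear eigensolver

`M_eff(w)` depends on the eigenvalue being sought, so the solver iterates:
Ritz extraction in the current subspace at the current `w`, a
Newton–Raphson update through `Theta(w) = y' M_eff(w) y` and its
(non-positive) derivative, and subspace expansion from the preconditioned
residuals of the current root and the next `block_width - 1` higher live
roots (default block width 5). Convergence requires **both** the residual
norm (default `1e-5`) and the Newton eigenvalue error (default `1e-6`
hartree) to pass. The initial subspace and eigenvalue guesses come from a
dense ADC(1) diagonalization.

Design choices the formalism leaves open, settled as follows:

* **Root tracking** across Newton updates is by maximal overlap with the
  previous iterate's vector.
* **Locking/deflation**: converged roots stay in the subspace. For
  selecting the *next* root, Ritz vectors are deflated against all locked
  roots (overlap-squared threshold 0.5), so remaining members of a
  degenerate multiplet are picked up before higher bands. The *iterate*
  itself is deflated only against locked roots degenerate with it (within
  1e-6 hartree): eigenvectors of the nonlinear family at distant
  eigenvalues are genuinely non-orthogonal, and projecting them out would
  corrupt the Ritz vector (this is visible as a residual floor if done).
* **Collapse** fires when the subspace reaches `max_subspace` (default
  200) or no candidate survives the linear-dependence filter; it keeps
  the locked eigenvectors plus the deflated Ritz vectors of the active
  window, and never changes converged eigenvalues.
* **Stalls** (no residual decrease over `stall_window` iterations) flag
  the root and move on; flagged states are returned with
  `converged = FALSE`, never silently.

Eigenvectors are reconstructed to the full space
(`Y_d = (w - d)^{-1} M_ds Y_s`) and normalized there, which is the
normalization under which transition amplitudes and the damped
sum-over-states closure hold.

## Spectra and units

* Absorption: `sigma(w) = (4 pi w / c) Im alpha_iso(w)` in atomic units,
  with `c = 137.036`.
* ECD: velocity gauge by default, matching the linear-momentum /
  magnetic-dipole structure of the mixed response; the length-gauge
  rotatory strength is also reported in stick tables but never mixed in
  silently. The broadened rotatory-strength density (au) converts to
  Delta-epsilon in L mol^-1 cm^-1 via R(au) -> 1e-40 esu^2 cm^2
  (x 471.4436) and the standard relation
  `Delta-eps(nu) = nu * rho_R(nu) / 22.97` on a cm^-1 grid.
  The velocity-form Delta-epsilon is origin independent only in a
  complete basis; the gauge origin defaults to the center of nuclear mass
  and is configurable. Length/velocity rotatory strengths agree in sign
  but differ in magnitude at the minimal-basis level, as expected.
* Stick spectra: `lorentzian_broadening(shape = "damped")` uses the exact
  line shape of the damped response (resonant and antiresonant branch,
  `w/w_n` weighting), so a window-complete stick list reproduces the CPP
  spectrum to machine precision; `shape = "lorentzian"` is the plain
  textbook superposition, which differs at the percent level near band
  edges. A common `gamma` is used for all states.
* One damping value everywhere: the demonstration value `1000 cm^-1`
  (4.556e-3 hartree) is used across tests and examples.

## The synthetic model generator

`generate_model_problem()` emulates exactly the *structure* the solvers
rely on: a symmetric singles block with controllable eigenvalue
clustering (a power-law transform of an even spectrum, so a `clustering`
exponent > 1 piles states toward the lower edge and raises the local
density of states), a dense random singles–doubles coupling of
controllable strength, and a diagonal doubles block placed **above** the
singles spectrum by default — as in the physical problem for valence
windows — with a configurable gap for stress tests. It is fully
reproducible from its seed.

What it does *not* emulate: integral sparsity and permutational symmetry,
point-group degeneracies, realistic intensity distributions, or any
relation between coupling strength and the singles spectrum. Passing
solver tests on model problems therefore demonstrates the linear algebra
(folding, subspace iteration, Newton refinement, collapse, accounting) —
not the electronic-structure content, which is covered by the molecular
fixtures and the determinant-space ISR oracle instead.

The documented qualitative behavior that response equations in spectrally
dense regions converge more slowly is reproduced as a statistical
property: over 20 seeds, problems with `clustering = 6` probed inside the
clustered region (measured DOS roughly 2.5x higher) need more separate-
subspace iterations on average than `clustering = 1` problems
(`test-model-problems.R`).

## Numerical choices and degenerate inputs

* Møller–Plesset denominators below `1e-8` hartree are a hard error
  naming the orbital quadruple — no silent level shifting, since the
  desk-scale fixtures are non-degenerate and regularization would corrupt
  the oracle tests.
* An undamped (`gamma = 0`) solve that hits a doubles-diagonal resonance
  is an error; with `gamma > 0` the folding weights are bounded.
* The reduced coupled system is solved directly; a reciprocal condition
  number below `1e-14` is an error carrying the estimate.
* `Theta(w)` evaluation refuses `w` within `1e-10` of a doubles-diagonal
  entry; Newton steps with `|Theta' - 1|` below `1e-12` fall back to the
  plain Ritz value.
* The dense oracle refuses above 5000 total dimension — it exists for
  validation, not production.

## Problem sizes used by the tests

The suite runs entirely on: H2, LiH, H2O, and the two skew-H2O2
enantiomers in STO-3G (7–12 AOs, up to 40 singles / 2295 doubles), H2 in
6-31G, 6-spin-orbital synthetic systems for the ISR oracle, and model
problems up to 150 singles / 200 doubles. These sizes keep every oracle
(dense diagonalization, dense complex solves, determinant-space ISR)
exact and fast while exercising all code paths; they are the package's
intended validation regime, not a performance statement.

## Known limitations

* Strict ADC(2) only; no ADC(2)-x/ADC(3), no core–valence separation, no
  excited-state properties beyond transition moments.
* Closed-shell RHF references; integral data shipped for s/p bases
  (STO-3G for H–Ne, 6-31G for H and O). Larger standard sets are present
  only in the counting registry. Minimal-basis spectra are qualitative.
* The progressive root search can misorder or skip roots when the folded
  shift is comparable to the level spacing (very strong synthetic
  coupling); every returned root is still a true eigenvalue, and the
  molecular fixtures recover complete lowest sets.
* Velocity-gauge ECD retains a (recorded) gauge-origin dependence in
  finite bases.
* Single-process only: the incremental batched MO transformation bounds
  memory, but no distributed storage or parallel execution is provided.
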