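---
title: "Density-matrix-converged VQE: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-matrix-converged VQE: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

The variational quantum eigensolver (VQE) minimizes the energy
$E(\theta) = \langle\Psi(\theta)|\hat H|\Psi(\theta)\rangle$ of a
parameterized quantum state.  Energy-only convergence does not guarantee that
the one-particle reduced density matrix (1-RDM),
$D_{pq} = \langle\Psi|a_p^\dagger a_q|\Psi\rangle$, has converged, and every
one-electron property — electron density, electrostatic potential, dipole
moment, Mulliken populations, density topology — is a functional of the
1-RDM.  `vqerdm` implements, as exact noiseless statevector simulations, the
two remedies this package is organized around:

* **VQE\***: the standard energy descent, but the run only terminates when
  both $|\Delta E| < E_\mathrm{tol}$ *and* the RMSD between consecutive
  1-RDMs,
  $$\Delta D = \sqrt{\tfrac{1}{N^2}\sum_{pq} |D^{(n)}_{pq} - D^{(n-1)}_{pq}|^2},$$
  falls below $D_\mathrm{tol}$ on the same iteration ($N$ = number of active
  orbitals).
* **VQE-LD**: a density-augmented loss
  $L(\theta) = E(\theta) + w_D\,\Delta D(\theta)$ with
  $w_D = f\,\lVert G_E\rVert / \lVert G_D\rVert$, where $G_E = \nabla_\theta E$
  and $G_D = \nabla_\theta \Delta D$ (the previous-iteration RDM is a constant
  reference).  The norm ratio puts both gradients on the same scale; the
  factor $f$ tunes how strongly the density term steers the update.

A determinant-based CASCI solver on the identical folded Hamiltonian is the
internal reference for both energies and density matrices, so every claim the
package makes is checkable against an independent in-repo oracle.

# The simulation stack and its assumptions

1. **Integrals and SCF.** A McMurchie–Davidson Gaussian integral engine
   (C++, s/p shells as packaged with STO-3G for H and C) produces overlap,
   kinetic, nuclear-attraction, dipole, point-charge and two-electron
   integrals; a closed-shell RHF with DIIS provides the orbital basis.
   Positions are Angstrom at the user surface and Bohr internally; energies
   are Hartree; dipoles are reported in Debye (1 a.u. = 2.541746473 D).
2. **Active space.** A frontier window: the $n_e/2$ highest occupied and
   $n_o - n_e/2$ lowest virtual canonical MOs; remaining occupied MOs are
   frozen at double occupation and folded into `h_eff`/`e_core` with the
   standard inactive-Fock expressions.  Ties at the window edge are broken by
   ascending orbital energy then index, with a warning below a 1e-8 Hartree
   gap.  Explicit index override is available.
3. **Qubit mapping.** Jordan–Wigner with *interleaved* spin-orbital ordering
   ($\alpha_1, \beta_1, \alpha_2, \dots$); qubit 0 is the leftmost tensor
   factor.  Occupied/virtual spin orbitals map to $|1\rangle/|0\rangle$.
   All Pauli coefficients are real after assembly (asserted), and terms below
   1e-12 are pruned.
4. **Ansaetze.**
   * *k-UpCCGSD*: per layer, all generalized spin-conserving singles
     (lexicographic in the spatial pair, $\alpha$ before $\beta$, one
     parameter per spin pair) followed by all paired doubles
     ($p\bar p \to q\bar q$, lexicographic).  The ordering changes the
     circuit, so it is frozen here.
   * *GateFabric*: a brick-wall of 4-qubit tiles over adjacent spatial
     orbital pairs (odd layers offset 0, even layers offset 2; a 4-qubit
     register holds one tile per layer).  Each tile applies a paired-double
     rotation then an orbital rotation ($\alpha$ and $\beta$ Givens rotations
     sharing one angle): 2 parameters per tile.  The identity-block
     convention is used, so $\theta = 0$ prepares exactly the Hartree–Fock
     reference — consistent with the zero-initialization protocol.  The
     alternative fixed orbital-swap ("pi block") convention was examined and
     rejected: it silently replaces the HF start by a doubly-excited
     determinant.
   * Gates are Givens-type: each generator satisfies $G^3 = -G$, so
     $e^{\theta G} v = v + \sin\theta\, Gv + (1-\cos\theta)\, G^2 v$ exactly.
5. **Gradients.** Adjoint-mode differentiation on the statevector — exact to
   machine precision and deterministic; the tests cross-check it against
   central finite differences on every circuit shape.  The $\Delta D$
   gradient uses the chain rule through the measured RDM: with
   $A = \sum_{pq} (D - D^{(n-1)})_{pq} \hat E_{pq}$ frozen at the current
   point, $\nabla \Delta D = \nabla\langle A\rangle / (\Delta D\, N^2)$.  At
   the non-differentiable point $\Delta D = 0$ (below 1e-14) the safeguarded
   subgradient $G_D = 0$ is used.
6. **1-RDM measurement.** Upper-triangle elements come from the Hermitian
   operator pairs $(a_p^\dagger a_q + a_q^\dagger a_p)/2$ and
   $(a_p^\dagger a_q - a_q^\dagger a_p)/2i$ (the $XX+YY$ / $XY-YX$ forms with
   Jordan–Wigner $Z$-strings); diagonals from $(I - \langle Z_p\rangle)/2$;
   the lower triangle by Hermitian conjugation.  Both parts are measured even
   though the packaged ansaetze are real-generator circuits (imaginary parts
   are machine-zero there), so complex-amplitude states remain representable.
7. **Optimization.** Deterministic full-batch gradient descent with a fixed
   step (default 0.4) from $\theta = 0$; there is no stochastic element
   anywhere, so identical configurations give bitwise-identical
   trajectories.  $E_\mathrm{tol} = D_\mathrm{tol} = 10^{-6}$ by default; the
   first iteration never terminates (no predecessor RDM) and uses $w_D = 0$.
   Reaching `max_iterations` (default 5000) flags the result instead of
   raising.
8. **Properties.** The active-space spatial RDM (spin-summed; the
   $\alpha\beta$ cross blocks are never read) is embedded into the full MO
   density — 2 on the frozen diagonal, the measured block on the active
   window, 0 elsewhere — and transformed to the AO basis, where the density,
   ESP, dipole, Mulliken populations and the QTAIM critical-point analysis
   are evaluated with analytic derivatives throughout.

# Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `e_tol` | energy convergence (Hartree) | 1e-6 | study protocol |
| `d_tol` | $\Delta D$ convergence (dimensionless) | 1e-6 | study protocol |
| `learning_rate` | gradient-descent step | 0.4 | study protocol |
| `f` | $w_D$ scale in VQE-LD | 0.05 | headline manifest (0.1 at R = 1.8; 0.7/0.9 for the GateFabric runs) |
| `delta_d_basis` | spatial vs spin-orbital $\Delta D$ | spatial | "number of active orbitals" reads most naturally as spatial; the spin-orbital variant differs only by a bounded factor ($\sqrt 2/4$ for spin-balanced real states) and is a config switch |
| `k` / `layers` | ansatz depth | 1 / 2 | k = 1 reproduces the study; GateFabric depth is not documented anywhere, so the packaged manifest uses 2 layers (distinct brick offsets); on a (2,2) space 1 and 2 layers reach the same variational floor |
| `resolution` | cube grid step (Bohr) | 0.10 | the "0.10" grid spec; the unit is taken as Bohr and is configurable |
| `padding` | cube box margin (Bohr) | 4.0 | keeps box-truncation error of the density integral below 0.1% |
| `pair_cutoff` | CP bond-seed distance (Bohr) | 4.5 | reaches the stretched C–H bond paths (4.03 Bohr at R = 2.1) that a 4.0 cutoff just misses |

# The packaged CH5+ series (synthetic stand-ins)

The dissociation study runs on protonated methane at
$R \in \{1.3, 1.4, 1.6, 1.8, 2.1\}$ Angstrom, where $R$ is the distance from
the carbon to the center of mass of the leaving H$_2$ pair.  The original
optimized coordinates are not redistributable here, so the packaged
geometries are **synthetic stand-ins**: Cs-symmetric structures (mirror plane
through C, H2, H3, H4; H5/H6 mirror-related) optimized at the RHF/STO-3G
level under the constraint that the C–(H3,H4 midpoint) distance equals $R$,
deposited in the nuclear center-of-mass frame.  `ch5_dissociation_coordinate()`
recomputes $R$ from the coordinates as a validation utility.

The mean-field optimization level is deliberate: it keeps the whole series in
the single-reference structural class that the study's own data display
(k-UpCCGSD energy errors of 1e-6 to 1e-4 at every $R$, intact H–H and C–H
bond paths at stretched geometries).  Optimizing the stand-ins with a
correlated surrogate (CASCI(4,4) was tried first) lets the stretched
structures drain into a strongly-correlated planar-CH3 basin that the
reference study never visits, with frontier-orbital degeneracies as the
visible symptom.

What the stand-ins do *not* reproduce: the exact deposited coordinates, hence
any property reported for them beyond its magnitude — the acceptance suite
asserts the equilibrium-region reference energy at the millihartree scale,
the dipole magnitude within 0.2 D and the carbon Mulliken charge within
0.06 e of the reported values.  Passing tests therefore demonstrate the *methods*
(oracle equivalence, convergence behaviour, property machinery, topology
recovery), and magnitude-level agreement with the printed study values, not
digit-level reproduction of coordinates we do not have.  The same applies to
shot noise and hardware noise: everything here is an exact expectation-value
simulation, so conclusions about noisy-device behaviour are out of scope.

# Numerical choices

* **Frozen-core fold**: `h_eff[pq] = h[pq] + sum_i (2 (pq|ii) - (pi|iq))`,
  `e_core = E_nuc + sum_i 2 h[ii] + sum_ij (2 (ii|jj) - (ij|ji))`.
* **Boys function**: downward-recursion series below x = 35, asymptotic +
  upward recursion above; verified against `pgamma`-based forms and
  quadrature in the tests.
* **SCF**: DIIS (8 vectors), symmetric orthogonalization, energy change
  below 1e-12 and error norm below 1e-10 at exit; deterministic orbital sign
  convention (largest-magnitude coefficient positive).
* **CASCI**: Slater–Condon rules over lexicographically ordered
  (alpha, beta) determinant pairs, alpha string before beta in the phase
  bookkeeping (validated against dense Jordan–Wigner sector
  diagonalization); dense eigensolve up to 2000 determinants, Davidson with
  diagonal preconditioning above; deterministic CI-vector sign.
* **Determinant-to-statevector loading** includes the fermionic reordering
  parity between the alpha-then-beta operator ordering and the interleaved
  qubit register.
* **Critical points**: Newton–Raphson on the analytic gradient/Hessian with
  a 0.5-Bohr step cap, seeded at nuclei and bonded-pair midpoints; converged
  roots (gradient norm < 1e-8) deduplicated within 1e-4 Bohr; roots with
  density below 1e-4 e/a0^3 are far-field numerical zeros and are discarded.
  Classification by Hessian signature: NCP = three negative eigenvalues
  (the standard local-maximum convention), BCP = two negative one positive.
  Attachment labels use the minimal-perimeter-excess nucleus pair — a
  heuristic, not gradient-path tracing — so cross-method comparisons match
  critical points by type and position, not by label.  Ring/cage-signature
  points are reported as `"other"` and not analyzed further.
* **Cube files**: positive-atom-count Gaussian layout, z-fastest value
  order, 6 values per line at 7 significant digits (round-trips to better
  than 1e-6 relative).
* **Dipole origin**: dipoles of the charged CH5+ depend on the gauge origin;
  the packaged convention is the coordinate origin of the deposited frame
  (the nuclear center of mass), exposed as an argument and recorded in every
  report.  An origin shift changes the dipole by exactly
  (total charge) x (shift), which the tests assert as an identity.

# Known limitations

* Only H and C STO-3G shells are packaged; the integral engine itself is
  general in angular momentum but nothing above p is exercised.
* Closed-shell RHF references only (multiplicity 1).
* Fixed-step gradient descent is the study protocol, not a robust optimizer:
  it can oscillate on stiff landscapes and plateaus trigger the energy-only
  stopping rule early — which is precisely the failure mode the dual
  criterion of VQE* / VQE-LD addresses.
* k-UpCCGSD from a zero start has a genuine expressiveness/local-minimum
  floor on strongly-correlated systems (measured: ~6e-3 Hartree above FCI
  for a 1.0-Angstrom H4 chain in a (4,4) space even at k = 3); oracle
  equivalence is therefore asserted on Hamiltonians whose CASCI ground state
  the ansatz can represent exactly.
* Problem sizes used throughout: at most 8 qubits (256 amplitudes), at most
  36 determinants in routine runs; the Davidson path extends the CI solver
  beyond the dense cutoff but full-molecule FCI of CH5+ (63504 determinants)
  is not part of any packaged workflow.

# Reproducing the study tables

```{r tables}
library(vqerdm)
t1 <- reproduce_table("t1")   # energies, errors, DeltaD, steps (k-UpCCGSD)
t6 <- reproduce_table("t6")   # the GateFabric (2,2) contrast
t8 <- reproduce_table("t8")   # Mulliken charge deltas (GateFabric)
```

`scripts/acceptance.R` reruns the full chain from geometry to topology and
writes every headline quantity to JSON; see the README for its interface.
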