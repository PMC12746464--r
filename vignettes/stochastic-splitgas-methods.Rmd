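---
title: "Stochastic SplitGAS: model, algorithm, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic SplitGAS: model, algorithm, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitgas)
```

## The problem

Strongly correlated electronic states (diradicals, exchange-coupled
transition-metal centers, low-lying spin ladders) need a multireference
description: a principal set of configurations treated exactly, plus a large
perturber set that supplies dynamic correlation. This package implements an
*uncontracted* second-order treatment of the perturber space built on three
ingredients:

1. **Generalized active spaces (GAS).** The orbitals are split into disjoint
   subspaces G1..Gk with user-chosen occupation windows. Intra-subspace
   excitations are free; inter-subspace excitations must keep the
   per-subspace electron counts `x_i` inside the windows, imposed either
   locally (`n_min[i] <= x_i <= n_max[i]`) or cumulatively (on running sums).
   A distribution of N electrons over the k subspaces is a *composition*;
   compositions satisfying the constraints are *supergroups*, indexed in
   decreasing lexicographic order (`enumerate_compositions()`,
   `enumerate_supergroups()`). Whether an excitation is admissible depends on
   the determinant only through its supergroup, which is what makes
   constrained stochastic sampling cheap.

2. **P/Q splitting and Löwdin downfolding.** Two disjoint supergroup sets
   define the principal space P and the perturber space Q over the total
   space T = P + Q. Exact downfolding replaces the eigenproblem by the
   energy-dependent P-block matrix

   H~_ij(E) = H_ij + sum_a H_ia H_aj / (E - H_aa) + (higher orders),

   and the SplitGAS approximation truncates after the second-order term, so
   only QQ *diagonals* enter. Equivalently — and this is the form the walker
   dynamics uses — one solves the full-dimension *effective* Hamiltonian
   whose QQ off-diagonals are set to zero (`build_effective_hamiltonian()`).
   Every effective eigenvector with nonzero P weight corresponds to a
   self-consistent solution of the downfolded problem (`downfold()`,
   `solve_self_consistent_downfold()`); the package tests this equivalence on
   random instances. The effective form needs no trial energy, no iteration,
   and can host several states at once, which is why it is preferred here.

3. **FCIQMC walker dynamics.** The CI vector is represented by signed real
   walker weights n_i on determinants and evolved by the linearized
   imaginary-time propagator: spawning along off-diagonal couplings K_ij
   (with K = H - E_ref I), death/cloning against K_jj - S, and annihilation
   by signed merging. The shift S is a population-control parameter whose
   stationary mean estimates the correlation energy; the projected energy
   <ref|H|Psi>/<ref|Psi> is the second estimator.

### Constrained heat-bath excitation generation

Proposals use precomputed heat-bath (PCHB) tables: double excitations
`AB <- IJ` between determinants have a determinant-independent magnitude
(`|g_AIBJ - g_AJBI|` same spin, `|g_AIBJ|` opposite spin), so categorical
distributions over particle pairs can be tabulated once per (supergroup,
hole pair) and sampled in O(1) with Walker alias tables. Singles use the
robust surrogate `S_I^A = |h_AI| + sum_R |g_AIRR - g_ARRI|`. GAS constraints
and the SplitGAS *OR-gate* (a spawn is allowed iff source or target
supergroup is in P, which suppresses exactly the QQ off-diagonals) are folded
into the tables by zeroing forbidden entries, so invalid moves are never
proposed rather than proposed-and-rejected. Instrumented runs count GAS
violations and Q-to-Q spawn events; both counters must be zero, and the test
suite asserts this.

Because the weights are determinant-independent, a drawn particle orbital can
collide with an occupied one; such draws are returned as explicit null moves
(not resampled), keeping the generation probability p_gen exactly equal to
the tabulated categorical probability. The proposal mass over all reachable
targets plus the rejection mass sums to one to machine precision — this
closure is tested exhaustively on a 6-orbital system and was instrumental in
catching an indexing defect during development.

## Slater determinant versus spin-adapted bases

The full Hamiltonian commutes with S^2, but the *effective* Hamiltonian does
not: zeroing QQ off-diagonals in the determinant basis couples the P-space
singlet to high-spin components of the perturbers. The package therefore
also supports a spin-adapted route at desk scale: per spatial occupation, S^2
is diagonalized exactly in the determinant sub-basis (the matrix elements
reduce to a Gram matrix of S+ images) and the downfolding is performed in the
resulting CSF basis (`spin_adapted_basis()`, `csf_transform()`), which keeps
the perturbative correction spin-pure by construction. Genealogical (GUGA)
coupling machinery is deliberately out of scope; explicit S^2 projection is
exact and simple at the space sizes this package targets.

Two facts about contamination that the tests pin down:

* With only **two** open shells (a CAS(2,2) model) the SD-basis effective
  Hamiltonian is still protected by spin-flip symmetry — its eigenvectors are
  exact S^2 eigenstates — yet the *energy* of the second-order correction
  differs between the SD and CSF treatments, because the SD form perturbs
  through the two open-shell determinants separately while the CSF form
  perturbs only through the singlet combination. Both closed forms are
  reproduced term-by-term by `downfold()` on 50 random integral sets.
* From **four** open shells on, flip-symmetric determinant mixtures span
  several total-spin sectors, and the SD-basis SplitGAS ground vector picks
  up genuine contamination (about 5e-4 in <S^2> on the shipped CAS(4,4)
  fixture); the CSF-constrained solution of the same fixture is pure to
  1e-10.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dtau` | auto | Imaginary time step (1/Ha). Auto = `0.5 / spread(H_jj)`, shrunk 5% whenever a single spawn exceeds weight 1 during equilibration. |
| `target_walkers` | 5e4 | Total walker weight at which shift control engages. |
| `shift_damping` | 0.05 | zeta in `S <- S - zeta/(A dtau) log(Nw/Nw')`. |
| `shift_period` | 5 | Steps A between shift updates. |
| `initiator_threshold` | 3 | Parent weight below which spawns may not open unoccupied determinants (core parents exempt). |
| `core_size` | 0 | Semistochastic core: that many lowest-diagonal determinants are propagated deterministically (exact core-to-core matrix action, stochastic core-to-core proposals suppressed, core entries never purged). |
| PCHB truncation | 1e-8 | Integral magnitudes below this carry zero proposal weight. |
| FCIDUMP write threshold | 1e-12 | Storage keeps more precision than sampling needs. |

Design choices where practice is genuinely open, and what this package does:

* **Walker granularity.** Real-valued weights with stochastic rounding of
  sub-unit spawns, the lower-variance modern practice; the update equations
  are weight-agnostic.
* **Single/double branching.** Proportional to the summed surviving single
  vs double table weight per supergroup, floored at 0.05 per branch when both
  are nonzero so neither channel starves.
* **Shift engagement.** When the population first crosses the target, the
  shift is seeded with the instantaneous projected correlation energy before
  the damped log-ratio update takes over. With the textbook cold start
  (S = 0) the population overshot the target 25-fold on the CAS(4,4) fixture
  while the damped update crawled down; seeding removes the overshoot
  without altering the stationary state.
* **Projected-energy estimator.** The summary reports the ratio of time
  averages `sum(num_t) / sum(den_t)`, not the average of per-step ratios:
  the per-step ratio estimator carries a textbook O(Var(n_ref)/n_ref^2) bias
  that was clearly visible (about two error bars) on the CAS(6,6) SplitGAS
  fixture. Error bars come from blocking the linearized series
  `(num_t - E den_t) / mean(den_t)`.
* **Self-consistency of the downfold.** Plain fixed-point iteration from the
  bare P eigenvalue, following the root of maximal overlap with the previous
  eigenvector (avoids root flipping near crossings), 0.5 damping on detected
  oscillation, tolerance 1e-9 Ha, at most 100 iterations.
* **Degenerate S^2 eigenvectors** within a spatial-occupation block are
  ordered by (and sign-fixed on) the coefficient of the lexicographically
  smallest determinant, making transforms reproducible across platforms.
* **Root matching between effective and downfolded spectra** (for degenerate
  roots with partial P projection) follows maximal overlap; no published
  prescription exists for this corner.

## What the synthetic generators emulate

`make_hubbard()` produces the standard half-filled Hubbard chain, the
textbook correctness fixture: the dimer's singlet ground energy
`(U - sqrt(U^2 + 16 t^2))/2` is asserted to machine precision
deterministically and to statistical precision stochastically.
`make_random_integrals()` produces 8-fold-symmetric random integral sets
with a spread one-electron diagonal (orbital i at `(i-1) * diag_spread`) so
an aufbau reference dominates, mimicking a molecular problem near
equilibrium; `scale` sets the correlation strength and `sparsity` thins the
off-diagonal tensor. What these fixtures do **not** emulate: point-group
symmetry, integral decay structure of real molecules (locality), size
extensivity across fragments, and near-degenerate open-shell manifolds of
real transition-metal systems. Passing tests therefore demonstrate
correctness of the machinery (constraints, matrix elements, sampling,
estimators), not chemical accuracy claims for any specific molecule.

The shipped study fixtures, chosen once:

* CAS(6,6)-sized random set (seed 5, scale 0.3) with three 2-orbital
  subspaces; T is the full CAS, P the MRCI-flavored window (at most one hole
  in G1, at most one particle in G3). The effective-Hamiltonian ground
  energy sits 0.43 Ha above full CI and 1.3 Ha below the bare P diagonal-
  ization, a comfortable margin against a stochastic error bar near 1e-2 Ha.
* CAS(4,4) random set (seed 31, scale 0.5), same layout minus the third
  subspace, as the spin-contamination demonstration (see above).
* 100 CAS-sized 5-orbital instances (seeds 1001..1100) for the
  wavefunction-deviation comparison: the effective-Hamiltonian eigenvector
  beats the P-only eigenvector in root-mean-square coefficient deviation
  from full CI, in both the P and Q blocks, on every instance at these
  conditions.

## Problem sizes and numerical tolerances

Deterministic reference solves use dense diagonalization to dimension 2000
and a Lanczos iteration with full reorthogonalization beyond (guarded at
2e5). Walker-dynamics validations run 2000-2500 steps with the population
settling near 5e4 walkers on spaces of dimension 16 to 400; burn-in is one
quarter of the trajectory. Blocking analysis uses pairwise halving with the
first-stable-level plateau rule (first level whose estimate is within one
estimated error of the next); stochastic energies are asserted within three
blocking sigmas, symmetry identities within 1e-12, the folded/unfolded
equivalence within 1e-9 Ha.

## Known limitations

* The downfold is second order only; third- and higher-order Löwdin terms
  are out of scope, as is state-specific trial-energy selection for excited
  states.
* Spin adaptation by explicit S^2 diagonalization scales with the size of a
  spatial-occupation block (at most `choose(n_open, n_open/2)`), fine at
  desk scale, not a GUGA replacement for large open-shell manifolds.
* The population-control feedback introduces the usual O(1/N_walkers) bias;
  at the shipped walker numbers it is below the statistical resolution of
  the tests, but very small target populations will show it.
* Sparse PCHB storage keeps only nonzero rows keyed by (supergroup, hole
  category); it reproduces the dense sampling stream bit-for-bit but is a
  simple associative fallback, not a compressed high-performance structure.
* Orbital indices are 1-based everywhere (R convention and FCIDUMP
  convention coincide), so there is no index translation layer at the I/O
  boundary.
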