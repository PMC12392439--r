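---
title: "Bond analysis by extended-transition-state decomposition and chemical-valence orbitals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond analysis by extended-transition-state decomposition and chemical-valence orbitals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etsnocv)
```

## The decomposition

`etsnocv` analyzes the bond between two fragments A and B of an adduct AB by
telescoping the supramolecular interaction energy through two intermediate
electronic states. Writing E[·] for the single-determinant energy functional
evaluated at a (not necessarily self-consistent) density:

| step | state | term |
|---|---|---|
| frozen densities juxtaposed | ρ_A + ρ_B | ΔE_elstat + ΔE_XC⁰ = E[ρ_A+ρ_B] − E[ρ_A] − E[ρ_B] |
| antisymmetrized promolecule | ρ⁰ | raw Pauli = E[ρ⁰] − E[ρ_A+ρ_B] |
| relaxed adduct | ρ | ΔE_orb = E[ρ] − E[ρ⁰] |

The three differences sum to E_AB − E_A − E_B *identically* — every
decomposition records this closure residual and the test suite asserts it
below 1e-9 Ha. The reported ΔE_Pauli is the raw antisymmetrization cost plus
the exchange nonadditivity ΔE_XC⁰, the convention in which the remaining
electrostatic term is purely quasi-classical. A geometric preparation term
(fragment SCF at frozen minus relaxed geometry) is added when relaxed
geometries are supplied; otherwise it is reported as zero with a flag, since
the interaction-energy table does not need it.

Both routes to the electrostatic term are implemented — the explicit
four-term contraction (nuclear attraction across fragments, cross nuclear
repulsion, Coulomb of the two densities) and the functional-difference route
above — and tested against each other; they agree to 1e-8 Ha, which checks
the bilinearity bookkeeping of the Coulomb terms.

## Promolecule construction

The promolecule is built by embedding the occupied fragment orbitals into
the supermolecule AO basis and orthonormalizing them sequentially in the
overlap metric (Schmidt orthogonalization), per spin channel. The package
keeps fragment A's occupieds unchanged and orthogonalizes B's against them;
this order is a pure bookkeeping choice — the occupied-span projector, hence
P⁰ and every downstream energy, is order-invariant (asserted to 1e-9), only
the per-orbital provenance labels differ. The linear-dependence threshold on
the residual S-norm is 1e-8, matching typical canonical-orthogonalization
cutoffs; a dependency failure names the offending orbital.

Fragment SCF calculations run in the fragment's own (monomer) AO basis and
are zero-padded into the supermolecule ordering. Because the supermolecule
basis is exactly the union of the fragment bases, the padded fragment energy
evaluated with supermolecule integrals reproduces the monomer SCF energy to
integral precision (a tested invariant), and the supramolecular ΔE uses
each fragment's own-basis energy. A ghost-augmented (counterpoise-style)
fragment basis would change the frozen-density reference; it is deliberately
not the default because the plain monomer basis keeps the telescoping
identity exact term by term.

## Transition-state Fock matrices and channel energies

ΔE_orb is linearized as a trace against ΔP = P − P⁰ using Fock matrices at
the half-sum transition-state density ρ^TS = ½(ρ + ρ⁰): first-order
Tr{F[ρ^TS] ΔP}, and the weighted combination
F̃ = ⅔F[ρ^TS] + ⅙F[ρ] + ⅙F[ρ⁰] that reduces the truncation error of the
first-order form. The per-channel energies use F̃, so the channel sum equals
Tr{F̃ ΔP} exactly (trace invariance under the orthonormal NOCV basis;
asserted to 1e-10 Ha).

A consequence of the built-in backend worth stating plainly: the
Hartree–Fock energy is *quadratic* in the density matrix, so its Fock matrix
is linear in P and both trace expressions coincide with the exact difference
E[ρ] − E[ρ⁰] to machine precision (F̃ = F^TS identically). The two
estimates only differ, and the weighted form only earns its keep, for
functionals with nonlinear exchange–correlation terms. The tables report
the exact difference — which is what guarantees closure — with the trace
value alongside as the channel-sum anchor.

## NOCV conventions

The deformation-density matrix is diagonalized as the symmetric eigenproblem
of S^{1/2} ΔP S^{1/2} (Löwdin transform) rather than with a generalized
solver: the spectrum is guaranteed real and the back-transformed
eigenvectors are S-orthonormal by construction. Conventions chosen for
reproducibility across linear-algebra backends:

* ordering by descending eigenvalue; each eigenvector's phase is fixed so
  its largest-magnitude coefficient is positive;
* restricted calculations use occupancy-2 spatial density matrices, so
  eigenvalues can reach 2 and are twice the per-spin values (a convention
  that differs across programs; the spin-resolved path on a closed shell
  reproduces the restricted energies and halves the eigenvalues, and this
  equivalence is tested);
* channels are formed by greedily matching +v with −v by magnitude; a
  mismatch above 1e-7 on idempotent-difference input is a hard error, and
  unmatched or sub-cutoff eigenvalues are carried as diagnostics rather than
  silently dropped;
* the printed-channel significance cutoff is v ≥ 0.001 (configurable);
  energy completeness is always verified against the full spectrum;
* degenerate channels (e.g. the π pair in the argon–lithium cation) are
  reported individually rather than summed, so their equal eigenvalues and
  energies remain visible.

Open-shell systems lose total-density pairing because ΔP is no longer a
difference of idempotent matrices; each spin channel individually still is,
so the analysis runs per spin and sums. Two open-shell fragments coupling to
a lower-multiplicity adduct need a spin orientation: by default fragment A
carries the excess α and fragment B the excess β electrons (configurable to
aligned coupling), a choice the underlying formalism leaves open.

For MP2-augmented calculations the correlated one-particle density is not
idempotent, which would break pairing; the channel analysis therefore runs
on the SCF part of ΔP only, while the MP2 correction enters as (i) a
separate a_C-scaled correlation line in the energy table and (ii) a
trace-free difference-density field Δρ_C^MP2(AB) − Δρ_C^MP2(A) −
Δρ_C^MP2(B) built from *unrelaxed* MP2 difference densities. Unrelaxed
rather than orbital-relaxed densities are the default because they need no
coupled-perturbed solver and the correction is analyzed visually and
energetically, not variationally; the relaxed variant would slot into the
same interface.

## The built-in backend

No external electronic-structure engine is required: the package carries its
own restricted/unrestricted Hartree–Fock solver (DIIS-accelerated, energy
convergence 1e-8 Ha and density RMS 1e-7 — tighter than single-point
practice because decomposition terms are small differences of large totals
printed to 0.01 kcal/mol), closed-shell MP2, and analytic
McMurchie–Davidson integrals over contracted s/p Gaussians. The minimal
basis is generated in code: the ζ = 1 radial Slater functions for the 1s,
2s/2p and 3s/3p shells are least-squares expanded in three Gaussians on a
radial grid (deterministic Nelder–Mead from fixed starts) and rescaled
analytically to per-element Slater exponents (Clementi–Raimondi values;
1.24 for H). For hydrogen and helium this reproduces published
minimal-basis Hartree–Fock energies to ~1e-5 Ha. Internal units are
Hartree and Bohr throughout; geometry input is Angstrom and reports use
1 Ha = 627.5094740631 kcal/mol.

The backend's scope sets the package's current limits: Hartree–Fock and
MP2-augmented Hartree–Fock only (the MP2-augmented path exercises the full
double-hybrid-style machinery — separate correlation line, density split,
SCF-part NOCV — with a_X = 1 and no semilocal exchange–correlation term),
one built-in minimal basis, and an in-core ERI guard of 48 AOs. Published
benchmark decompositions computed with GGA/hybrid/double-hybrid functionals
in quadruple-zeta bases are therefore *not* reproduced by the built-in
backend — the corresponding acceptance checks document that gap rather than
approximate it away — while every structural property of the scheme
(closure, pairing, completeness, spin resolution, order invariance,
non-interacting limits) is verified exactly on the bundled fixtures.

Dispersion is a provider interface (`register_dispersion_provider()`) with
a null default; pairwise empirical corrections with functional-specific
parameters plug in without touching the decomposition, and single atoms
always return zero. Composite-method corrections (geometric counterpoise,
short-range basis penalties) use the same pattern through
`register_correction_provider()`, grouped into one corrections line.

## Grids, fields and numerical tolerances

Deformation densities are evaluated on axis-aligned rectilinear grids
(default: bounding box + 4 Bohr padding, 0.2 Bohr spacing — fine enough to
resolve isosurfaces at the 1e-5 e/Bohr³ level) and exported as Gaussian
cube files in Bohr with z-fastest value order. Every exported field should
integrate to zero (paired depletion/accumulation); on grids that resolve
the basis functions this holds to ~1e-10 e, but for heavy atoms the
sharpest core Gaussians (widths well below 0.1 Bohr) are not resolved by
export-quality spacings and the Riemann sum carries a ~1e-4–1e-3 e error.
That is a property of rectilinear quadrature, not of the fields: the tests
assert 1e-4 on light-atom fixtures where the grid is converged and 1e-3 on
the water dimer at export spacing. Channel-density completeness (sum of
per-channel fields equals the direct ΔP-contracted density) is pointwise
exact and tested at 1e-8 e/Bohr³.

## Fixtures and what passing tests show

The bundled fixtures — He₂, HeH⁺, H₂ from two doublet atoms, Ar₂, Ar–Li⁺,
Be₂, (HF)₂, (H₂O)₂ — are generated from parameterized geometries (standard
hydrogen-bonded motifs, default separations chosen at typical equilibrium
distances) and cover the code paths: closed/open shell, charged fragments,
zero-electron fragments, degenerate channels, dimers with and without
virtual space. Problem sizes are 2–18 AOs, so every end-to-end test runs in
seconds on one CPU. Independent oracles are kept free of the production
energy-assembly routines: a brute-force Slater-determinant energy from
explicit MO-integral double sums (guarded to 8 AOs), loop-built Fock
matrices, closed-form minimal-basis Hartree–Fock and MP2 expressions, a
rank-1-projector eigenvalue formula, and hand-solved 2×2 eigenproblems.

What the passing suite does *not* show: agreement with correlated or DFT
reference decompositions, basis-set convergence of the terms (a minimal
basis exaggerates Pauli repulsion and underestimates polarization), or
behavior on transition-metal systems outside H–Ar. The decomposition
*structure* — which is what the package implements — is verified exactly;
the *level of theory* is what the backend adapter is for.
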