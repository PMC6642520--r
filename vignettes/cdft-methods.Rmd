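---
title: "Methods: conceptual-DFT descriptors and drug-likeness in cdftkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conceptual-DFT descriptors and drug-likeness in cdftkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdftkit)
```

## The model

Conceptual density-functional theory reads chemical reactivity off the
response of a molecule's energy to changes in its electron number N. With
the vertical ionization potential I and electron affinity A, the package
computes

- electronegativity χ = (I + A)/2 and chemical potential μ = −χ,
- global hardness η = I − A and softness S = 1/η,
- electrophilicity ω = χ²/2η,
- electrodonating power ω⁻ = (3I + A)²/16η and electroaccepting power
  ω⁺ = (I + 3A)²/16η, with net electrophilicity Δω± = ω⁻ + ω⁺,
- an absorption-wavelength estimate λ_max = hc/(ε_LUMO − ε_HOMO), using
  hc = 1239.841984 eV·nm.

Two conventions deserve a note. First, hardness is taken as the **full**
HOMO–LUMO gap, η = I − A, not the (I − A)/2 variant that is equally common
in the literature; the two differ by a factor of two in η, S and ω. Second,
all descriptors are carried unrounded and only rounded at the reporting
layer (three decimals for eV quantities, nearest integer for λ_max). The
algebraic identity ω⁻ − ω⁺ = χ holds exactly in this formulation and is
enforced as a property test.

### Where I and A come from

The default ("vertical") mode uses the Koopmans-in-DFT reading
I = −ε_HOMO, A = −ε_LUMO. This is only trustworthy for density functionals
whose orbital energies actually track the ΔSCF energy differences; the
package quantifies that with the compliance diagnostics

J_I = |ε_HOMO + E(N−1) − E(N)|,  J_A = |ε_LUMO + E(N) − E(N+1)|,
J_HL = √(J_I² + J_A²),

all in eV. Values of a few tenths of an eV or below justify the vertical
mode. An opt-in ΔSCF mode (`ia_mode = "delta_scf"`) instead computes
I = E(N−1) − E(N) and A = E(N) − E(N+1) from total energies of the three
charge states at fixed geometry. A negative A (unbound anion) is passed
through rather than clamped: it is physically meaningful for vertical
attachment.

A caution on a plausible-looking monotonicity claim: with A fixed, χ is
increasing in I everywhere, but ω⁻ and ω⁺ are **not** — their I-derivatives
change sign at I = 7A/3 and I = 5A respectively, so both powers decrease
with I in part of the I > A > 0 region. The property tests therefore check
monotonicity only above those thresholds.

## Local descriptors

Condensed Fukui functions are computed from partial charges of the N and
N±1 states at fixed geometry:

f⁻_k = q_k(N−1) − q_k(N),  f⁺_k = q_k(N) − q_k(N+1),  Δf_k = f⁺_k − f⁻_k.

The package uses the **charge-based** sign convention: because partial
charge is minus the electron population, f⁻_k is positive where ionization
removes density, i.e. at electron-donating (electrophile-susceptible)
sites. The literature mixes this with the population-based convention (the
two differ only in labeling, not magnitude); a worked two-atom example in
`?condensed_fukui` pins the choice down. When each charge set conserves its
own net charge exactly, Σf⁻ = Σf⁺ = 1 and ΣΔf = 0; the validation machinery
responds linearly to injected conservation noise, which is itself tested.

Grid-based Fukui fields are voxelwise density differences on congruent
Gaussian-cube grids (congruence tolerance 10⁻⁸ bohr on origin and axes; no
resampling is attempted — misaligned grids are an input error, not
something to paper over). The dual-descriptor grid equals the voxelwise
difference of the two Fukui grids by construction, and `grid_integral()`
(a Riemann sum times the voxel volume) verifies the one-electron
normalization. Condensed values are never derived from grids (no
Becke/Voronoi condensation): charge triplets are the only condensation
route, which keeps the two local-descriptor paths independent.

Site ranking sorts by descending descriptor value with ties broken by
ascending 1-based atom index. No per-atom reference values exist for the
Taltobulin case, so site ranking is validated purely by construction on
synthetic triplets.

## Quantum-chemistry artifact I/O

Orbital listings use a deliberately small line-oriented fixture dialect
(`unit eV|hartree`, one `orbital <energy> <occupation>` line per level)
so that every test runs without any vendor log; vendor-specific adapters
can be layered on `parse_orbital_energies()`'s `dialect` argument. Orbital
energies are stored in eV, total energies in hartree, with the single
conversion constant 27.211386 eV/hartree centralized in the package.

Cube files follow the standard Gaussian layout (lengths in bohr, values
z-fastest, `%13.5E` six-per-line emission, whitespace-tolerant parsing).
Two documented decisions: imaginary vibrational frequencies are encoded as
negative cm⁻¹ values (the common log convention), and negative atom counts
(the orbital-cube convention) are rejected — this reader handles scalar
fields only. Round-tripping reproduces the header exactly and values to
the 5-decimal mantissa, which is why value-level tests use a 10⁻⁵
tolerance.

Conformer bookkeeping mirrors standard practice: a structure counts as a
real minimum iff its frequency list is non-empty and strictly positive,
and `select_lowest_conformer()` takes the minimum total energy with exact
ties resolved to the earliest list position.

## Drug-likeness block

SMILES interpretation (including kekulization) is delegated to OpenBabel
via ChemmineOB; the package then works on an explicit molecular graph.
A syntax pre-check rejects strings OpenBabel would silently truncate
(unbalanced parentheses, unpaired ring closures). Aromaticity is perceived
with a Hückel-style rule on 5/6-membered rings (every ring atom sp2 or a
lone-pair donor, π count ≡ 2 mod 4), which covers benzenoid and common
heteroaromatic systems; exotic fused or charged aromatics are outside the
supported subset and fail loudly in the TPSA typer rather than silently.

The property block follows Molinspiration's definitions, chosen because
the reference property values were produced by that software:

- nON is the count of N plus O atoms; nOHNH the count of hydrogens **on**
  N or O — matching a reference value of 3 for a molecule with one COOH,
  one amine NH and one amide NH forces the H-count reading over the
  heteroatom-count one.
- nrotb counts single acyclic bonds between non-terminal heavy atoms,
  excluding amide C–N bonds.
- TPSA is Ertl's fragment sum over N/O environments (S/P extension
  available but off by default, matching the N/O-only convention).
- Rule-of-Five thresholds are boundary-inclusive: MW = 500, logP = 5,
  5 donors, 10 acceptors are compliant.

logP is an openly documented stand-in: a reduced Wildman–Crippen
atom-contribution scheme (published constants, coarser atom typing than
the original 68 SMARTS types) with per-hydrogen terms. It is additive and
auditable via `logp_atom_types()` + `crippen_table()`, and is expected to
track fragment-based references only to about one log unit — which is why
an externally supplied miLogP, when present, takes precedence in the
Rule-of-Five count. The proprietary miLogP and molecular-volume models are
deliberately not re-implemented; both are pass-through inputs.

Bioactivity scores are likewise pass-through (the predictive models behind
them are undisclosed). Classification bands: score > 0 active, −5.0 to 0.0
moderately active (both boundaries included — the source phrasing is
strict only about "> 0", so 0 and −5 are read as moderately active, a
documented choice rather than a claim about the original authors' intent),
below −5.0 inactive.

## Synthetic data: what it emulates and what it does not

The generators produce structurally faithful stand-ins for
electronic-structure outputs, not physically realistic ones:

- `make_spectrum()` places the HOMO and LUMO exactly at the requested
  energies with randomized level spacings elsewhere (0.2–2 eV), all
  occupied levels doubly filled.
- `make_charge_triplet()` splits one full electron across atoms with
  uniform random shares, so charge conservation — and hence the Fukui sum
  rules — holds to machine precision by construction.
- `make_grid_triplet()` builds densities on a fixed 16-bohr cubic box as a
  positive background plus/minus analytically normalized Gaussian blobs
  (σ between 1.0 and 1.6 bohr). Blob centers keep a 4σ margin from every
  face: a 3σ margin would already leak ≈0.1–1% of a blob's mass through
  the box faces, more than the 10⁻³ normalization tolerance, while at 4σ
  truncation (≈2·10⁻⁴) and grid aliasing (σ/h ≥ 2 even at the coarsest
  16³ resolution) are both comfortably below it. Counts below 16 per axis
  are rejected as too coarse.
- `taltobulin_fixture()` bundles the reference inputs: the transcribed
  structure (self-validated against MW 473.66 and 34 heavy atoms before
  use), a spectrum with the reference frontier, and ion-state total
  energies constructed to be Koopmans-consistent with it — the reference
  reports only E(N), so the ion energies are labelled synthetic and chosen
  to make the compliance diagnostics vanish, which is what a well-behaved
  functional would give.

Passing tests on these fixtures therefore demonstrates correctness of the
descriptor algebra, normalization and plumbing — not agreement of any
density functional with experiment, and not behavior on noisy or
basis-set-limited real logs.

All generators thread a single seed, restore the caller's RNG state, and
are bit-reproducible per seed.

## Numerical choices and degenerate inputs

- Degenerate frontier (gap ≤ 10⁻⁹ eV) is an error everywhere: η, S, ω and
  λ_max are undefined there, and silently returning infinities would
  poison downstream reports.
- Rounding is round-half-even (R's `round()`), applied only at rendering:
  3 decimals for eV quantities, 2 for MW/TPSA, nearest integer for λ_max.
- Problem sizes in the test suite are chosen for tightness-per-second:
  1,000 random frontiers for the χ identity, 50 seeded charge triplets
  against a subtraction oracle, 32³ grids for normalization (the error
  budget above makes 32³ as conclusive as larger grids), 48³ for the
  closed-form Gaussian integral check at 0.1%.
- The pipeline isolates stages: a corrupt input fails only its own block
  (recorded under `$errors` with the stage name) while the frontier-based
  core, which everything else interprets, is always fatal if absent or
  degenerate.

## Known limitations

- The Koopmans reading of I and A inherits the functional's quality; the
  J diagnostics flag, but cannot repair, a non-compliant functional.
- The aromaticity model does not attempt fused-ring Hückel counting;
  TPSA/logP typing on such systems errors out by design.
- The logP stand-in is a screening-grade estimate (±1 log unit), not a
  replacement for a full fragment model.
- Printed reference descriptors were themselves computed from rounded
  frontier energies; agreement is therefore asserted to ±0.005 eV, the
  slack that input rounding induces, rather than to machine precision.
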