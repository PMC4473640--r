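---
title: "Simulating transverse-current nanopore sequencing and correcting structural noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating transverse-current nanopore sequencing and correcting structural noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transverseq)
```

## The physical picture

In transverse-current nanopore sequencing a single-stranded DNA or RNA
molecule translocates between two electrodes mounted on the pore, and the
electron tunneling current *across* the strand is read out one nucleotide at
a time.  Because the current is set by the electronic structure of the
contacted base, it can in principle identify that base.  The complication
this package studies is *structural* (static) noise: the molecular orbitals
of a nucleotide hybridize with those of its neighbors along the chain, so
the current through a base depends on its sequence context even for a
perfectly still molecule.  The per-base current distributions overlap, and
naive calling makes errors.  Because that same noise is deterministic in the
neighbor identities, densities over *pairs and triples* of adjacent currents
carry the information needed to undo it.

`transverseq` implements the full loop: a multi-orbital tight-binding chain
model with per-base parameter blocks, projector-based model reduction,
Green's-function transport in the wide-band limit, non-parametric
calibration of single/pair/triple current densities, and maximum-likelihood
calling with iterative Bayesian refinement.

## The chain model

Each nucleotide is one site carrying `m` molecular orbitals (default
`m = 5`: four occupied levels and one unoccupied level around the transport
window).  A `fragment_params` object holds, in eV,

* one Hermitian `m x m` onsite block per base, `h_X`, and
* one `m x m` coupling block per ordered base pair, `V_XY`, with
  `V_YX = t(V_XY)`.

A concrete sequence becomes a block-tridiagonal Hamiltonian: the hopping
block between sites `i` and `i+1` is `V_{X_i X_{i+1}}` verbatim, and each
onsite block is renormalized by its existing neighbors,

```
eps_i = h_{X_i} + R(V_{X_i X_{i+1}}) + R(V_{X_i X_{i-1}}),   R(V) = (V + t(V))/2.
```

The symmetrization `R` deserves a note: the two-center onsite correction is
Hermitian in the full theory, but a raw reduced coupling block need not be
symmetric; adding it unsymmetrized would break Hermiticity of the chain
Hamiltonian.  `R` restores the property at the reduced level.  Couplings
beyond nearest neighbors are not part of the data model at all — in the
regime this model targets they are two orders of magnitude smaller than
first-neighbor terms.

## Where the blocks come from

In a first-principles workflow the blocks would be extracted from
fragment-molecular-orbital calculations of single nucleotides and nucleotide
pairs, then projected onto the orbitals in the active energy window.  No
such matrices are published, so the package provides two things.

**A projection module** that implements the reduction exactly.  For a full
system `(H, S)` with non-orthogonal overlap `S` and an active index set `P`,
`build_projectors()` returns the non-symmetric projectors, and
`effective_hamiltonian()` the energy-dependent reduced Hamiltonian.  Two
algebraically equivalent routes are implemented and cross-checked: the Schur
form

```
Heff(E) = H_PP + (E S_PQ - H_PQ) (E S_QQ - H_QQ)^-1 (E S_QP - H_QP)
```

and the resolvent form `Heff(E) = E S_PP + [G_PP(E)]^-1`.  A subtlety worth
recording: the two routes agree only with the resolvent convention
`G = (H - E S)^-1`; with the opposite sign convention the resolvent form
acquires a spurious `2 E S_PP` term.  The implementation uses the convention
that makes the routes identical, and the test suite verifies elementwise
agreement to 1e-8 eV.  The defining property of the reduction — every
generalized eigenvalue of the full pencil inside the active window is a
fixed point of `det(Heff(E) - E S_PP) = 0` — is verified on randomly
generated full systems to 1e-6 eV.  `Heff` diverges at the generalized
eigenvalues of `(H_QQ, S_QQ)`; evaluation within 1e-6 eV of such a
singularity is refused, because the inversion is ill-conditioned there.
Since the energy dependence inside the window is weak (tested), a single
evaluation at the mean valence energy (`linearize()`) serves as an
energy-independent reduced block.

**A synthetic generator** (`generate_parameter_set()`) that emulates the
gross features such a calculation would deliver, with every choice
configurable through `default_regime()`:

* HOMO levels inside [-6, -5] eV with ordering G > A ~ C > T
  (defaults G -5.15, A -5.45, C -5.55, T -5.78 eV) — the ordering that makes
  tunneling currents rank G > A > C > T, since the tunneling barrier is set
  by HOMO proximity to the electrode chemical potential;
* a LUMO 4.0 +/- 0.1 eV above the HOMO, deeper valence levels spaced
  0.55 eV below;
* onsite blocks that are diagonal in the level basis plus a +/-0.01 eV
  symmetric perturbation (fragment orbitals are near-eigenstates of the
  isolated fragment); the perturbation bound is chosen so a Gershgorin
  argument keeps every HOMO inside [-6, -5] and every gap inside
  [3.5, 4.5] eV for *every* seed, not just typically;
* coupling-block entries drawn N(0, 0.06 eV).  The magnitude scale
  (~0.01-0.1 eV, two orders below the valence spread) is the regime where
  first-neighbor hybridization is strong enough to matter but perturbative.
  The Gaussian (rather than bounded uniform) tails matter: neighbor-induced
  level shifts with hard-edged support narrower than the smallest HOMO
  separation would produce essentially zero calling ambiguity, i.e. no
  structural-noise problem to correct.  With these defaults the per-base
  log-current distributions genuinely overlap (A and C most strongly, as
  their HOMOs are nearest) while remaining far from degenerate;
* RNA: A/C/G blocks equal the DNA blocks plus a backbone perturbation of
  spectral norm at most 0.05 eV (the backbone states lie well below the
  frontier orbitals), while U is the T block shifted down by 0.12 eV — the
  chemical modification is in the base itself, so T and U differ
  significantly.

Parameter sets serialize to versioned JSON with matrix entries written at 17
significant digits, which round-trips IEEE doubles bit-exactly; plain JSON
numbers do not guarantee that.

## Transport

Electrodes are treated in the wide-band approximation: both contact the same
site `k`, with energy-independent self-energy `-i Gamma/2` on all `m`
orbitals of that site (default `Gamma = 1e-3 eV`, a weak, non-bonded
contact).  The electrode chemical potential is minus the metal work function
(defaults Al 4.08, Gr 4.60, Au 5.10, Pt 5.65 eV); with the level placement
above, Al and Gr land in the molecular gap (tunneling regime) while Au and
Pt align with the HOMO band (resonant regime).  The zero-temperature current
through base `k` is

```
I_k = (2e/h) * integral_{mu_R}^{mu_L} T(E) dE,
T(E) = Tr[Gamma_L G(E) Gamma_R G(E)^dagger],
```

with a symmetric bias drop `mu_{L/R} = mu +/- eV/2` (the drop convention is
configurable; symmetric is the standard default for a symmetric junction).
Currents are stored in `(2e/h) x eV` units; `current_unit_amperes()`
(the conductance quantum, 7.748e-5 S) converts to amperes.

Numerically, the chain is diagonalized once and the coupled Green's function
obtained by a low-rank update confined to the contacted block, so one energy
evaluation costs `O(n m^3)` instead of a dense `O((nm)^3)` inversion; the
dense inversion is retained as the oracle the fast route is tested against
(1e-8 relative).  Two guards matter in practice: (i) the bare-resolvent
denominators are clamped at 1e-12 eV so an energy exactly on a chain
eigenvalue stays finite (the electrode broadening makes the coupled result
finite there; the clamp error is of relative order `clamp/Gamma = 1e-9`);
(ii) the bias-window quadrature forces panel boundaries at every chain
eigenvalue within the window +/- 10 Gamma *and* at `lambda +/- {1,3,10}
Gamma`.  Resonances are Lorentzians of width ~1e-3 eV; a uniform rule misses
them entirely, and panels with peaks at both endpoints defeat the adaptive
integrator's extrapolation.  Each panel is integrated adaptively to 1e-6
relative tolerance, recursively subdivided on failure, and panels whose
absolute error estimate is below 1e-12 current units are accepted as
negligible.

## Calibration and base calling

Calibration follows a fixed protocol: 150 random sequences of 200 nt with
uniform base composition, 30 of which carry one poly(X) run (X cycling over
the alphabet, length uniform in 3-20, position uniform) so the densities see
repeat contexts.  That yields 30,000 single-current observations plus all
adjacent pairs and triples.  Pair and triple observations are pooled into
reading-direction symmetry classes — XY with YX read backwards, XYZ with ZYX
— giving 10 independent pair and 40 independent triple densities over a
4-letter alphabet (the class counts are `(k^n + k^ceil(n/2))/2`); palindromic
tuples contribute both readings so every class density is reversal
symmetric.  Boundary sites contribute to the lower orders only in the sense
that no pair or triple extends past the chain ends; all existing adjacent
windows are used.

Densities are fine histograms over log10 current (the structural noise
spreads currents over orders of magnitude), smoothed with a Gaussian kernel
and floored at 1e-12 so unobserved regions keep a nonzero likelihood.
Defaults, and why:

* grids of 200 (1-D), 200 (2-D) and 120 (3-D) bins per dimension spanning
  the observed range +/- 0.5 decades.  The joint grids must resolve the A-C
  current separation (~0.03 decades at default parameters); much coarser 3-D
  grids visibly degrade refinement.  120^3 keeps the 40-class library at
  ~0.5 GB, where 200^3 would be 2.6 GB;
* bandwidths by Scott's rule per dimension, `sigma * n^(-1/(d+4))`
  (Silverman's 1.06 factor for d = 1), with a one-bin floor for the joint
  densities: per-class joint samples are sparse collections of near-delta
  spikes (the currents are nearly deterministic given the local context),
  and without the floor a test observation from an unseen second-neighbor
  context evaluates at the density floor and carries no usable gradient;
* classes with fewer than `min_count = 25` observations are refused, with
  the offending classes named.

Calling proceeds in two stages.  `call_p1()` assigns each site the base
maximizing the single-current density, ties broken by alphabet order.
`refine()` then sweeps left to right, re-assigning each site to the base
maximizing the joint density of its local window — `(I_k, I_{k+1})` at order
2, `(I_{k-1}, I_k, I_{k+1})` at order 3, boundary sites falling back to the
highest order that fits — with neighbor identities fixed to the previous
sweep's guess.  A site whose new guess agrees with the previous sweep is
marked *certain* and frozen: the collapse rule, implemented as
hard-freezing.  (The alternative reading — renormalizing neighbors'
conditionals around the agreed base — is possible; hard-freezing is the
simpler operational form and is flagged as a choice, not established fact.)
Sweeps run to convergence or at most 10; the sweep count is recorded.  One
further rule: if every candidate base evaluates at the density floor, the
site keeps its current guess — an off-support observation carries no
information, and letting the alphabetical tie-break overwrite a
probably-correct call only destroys information.  Fidelity (`fidelity()`) is
the fraction of correctly called sites; a mask restricts it to a subset,
e.g. a planted repeat run (partial fidelity).

## What the tests do and do not show

The synthetic generator reproduces the *structure* of the problem — level
placement, weak nearest-neighbor hybridization, deterministic
context-dependent currents, the two transport regimes — but not real
nucleotide chemistry, finite temperature, conformational or environmental
noise, or ionic effects.  Passing tests therefore demonstrate the internal
consistency of the transport machinery (against closed forms and dense
oracles) and the statistical claim that correlation-aware refinement
corrects structural noise *within this model class*; they say nothing
quantitative about any laboratory device.  Absolute current scales are
likewise not meaningful: no published per-orbital matrix elements exist to
anchor them, so analyses work with log-current distributions and their
shapes (which is also why the escape rate Gamma, which only scales
currents, is tested as a shape-invariance property).

At the documented study scales (calibration 30 x 100 nt, 20 held-out 200-nt
sequences; chosen so a full run of the suite stays comfortable on one CPU)
the pipeline gives mean fidelities around 0.95 for single-current calling
and 0.98 for order-3 refinement in the tunneling regime, with the resonant
regime showing the expected several-fold larger overlap of standardized
current densities.  The numbers printed by `scripts/acceptance.R` are
recomputed from scratch on every run.

## Known limitations

* Single strand, single contact geometry; no base pairing, no geometry.
* Zero temperature and elastic transport only.
* The iterative refinement is a coordinate-ascent scheme on overlapping
  window densities, not exact inference; with very sparse calibration it can
  leave sites frozen on early wrong guesses.  Higher-order densities beyond
  triples are not implemented.
* Long homopolymer runs are only as well calibrated as the training
  insertions that cover them; the protocol's poly(X) insertions exist
  precisely because uniform random sequences underrepresent long repeats.
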