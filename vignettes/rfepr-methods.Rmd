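---
title: "Restrain-FEP-Release free energies on toy torsional systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrain-FEP-Release free energies on toy torsional systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfepr)
```

## The problem

Purine bases in DNA can pair in two modes: the canonical Watson-Crick
geometry with the base *anti* about its glycosyl bond
(chi = O4'-C1'-N9-C4, near -105 degrees), and the Hoogsteen geometry with
the base flipped to *syn* (near +64 degrees). The two conformers are
separated by a high effective barrier, so unbiased simulation essentially
never interconverts them, and the quantity of interest — the conformational
free-energy difference
$\Delta G = G_{syn} - G_{anti}$ — must be obtained by a method that does
not require sampling the transition path.

The restrain-FEP-release (R-FEP-R) approach does this alchemically. A
*dual topology* contains the changing fragment twice: a dual-RV copy (real
at the start, switched to a non-interacting "virtual" ghost) fixed in the
initial conformation, and a dual-VR copy (virtual to real) fixed in the
final conformation; the rest of the system is the shared set. Three staged
transformations connect the end states:

1. **Restrain** (\(\lambda_R: 0 \to 1\)): harmonic restraints on the
   initial-conformer copy are switched on. The final-conformer ghost is
   restrained throughout.
2. **FEP** (\(\lambda: 0 \to 1\)): the Lennard-Jones and Coulomb
   interactions of the initial copy are switched off while those of the
   final copy are switched on, both copies restrained. Proper dihedral
   terms of both copies stay on at all times (switching them off distorts
   ring-like fragments).
3. **Release** (\(\lambda_R: 1 \to 0\)): the restraints on the
   final-conformer copy are switched off.

The conformational free energy is the signed sum of the three stage values
exactly as estimated along the cycle (the release leg enters as its
1 -> 0 estimate). Because the restrained ghost fragments contribute
identically to the two cycle end states, the restraint work cancels in the
total; the package verifies this by doubling the force constants and
checking the total is unchanged.

Per-component lambda schedules are: restrain and release over
(0, 0.05, 0.25, 0.5, 0.75, 1) — the release stage traversed in reverse —
and FEP over (0, 0.01, 0.025, 0.05, 0.1, 0.2, 0.35, 0.5, 0.65, 0.8, 0.9,
0.95, 0.975, 0.99, 1), i.e. 6 + 15 + 6 states. End-point singularities of
the vanishing interactions are avoided with Beutler-type soft-core,
\(r_{eff}^6 = \alpha\,\sigma_{sc}^6\,\lambda^p + r^6\) applied to the
vanishing side of each pair term (both LJ and Coulomb share the same
effective radius), with sc-alpha 0.5, sc-power 1 and sc-sigma 0.3 nm.
Restraint force constants default to 1000 kJ mol^-1 rad^-2 (torsion,
angle, pseudodihedral) and 1000 kJ mol^-1 nm^-2 (distance).

## The toy system and why it admits an exact reference

All of the machinery above is exercised on a synthetic particle system
whose exact answer is computable by one-dimensional quadrature, so the
whole pipeline can be validated end to end.

The toy (`build_torsion_toy()`) consists of:

* a **scaffold chain** of `n_shared = 8` particles (harmonic bonds
  k = 2e4 kJ/mol/nm^2, r0 = 0.15 nm; harmonic angles k = 300
  kJ/mol/rad^2; cosine dihedral pins k = 100 kJ/mol along the chain that
  keep it semi-rigid so its bending modes stay fast under local Monte
  Carlo moves);
* a **conformer fragment** of `n_dual = 6` particles: two anchors bonded
  to the scaffold mid-chain and a rotor (hub + arms). The torsion of the
  rotor about the anchor-hub axis is the glycosyl-like coordinate chi,
  and the quadruple defining it lies entirely within the dual set;
* an **effective torsion profile** on chi: a sum of truncated periodic
  harmonic wells, well m contributing
  \(\frac{1}{2}c_m\Delta^2 - D_m\) for
  \(|\Delta| \le \sqrt{2D_m/c_m}\) (wrapped distance to the center).
  Defaults place the wells at -105 and +64 degrees — the anti and syn
  positions of the purine glycosyl torsion — with curvatures 56 and 114
  kJ/mol/rad^2 and depths 60 and 48 kJ/mol. Depths and curvatures are
  chosen jointly under three constraints: both basins must be strictly
  metastable over the default run length (the barrier equals the full
  well depth, at least 19 kT from either side, so neither an unrestrained
  anti nor an unrestrained syn state ever escapes during a cycle — the
  premise of the method, since the real systems never interconvert on
  simulation timescales); the truncated wells must not overlap, leaving a
  flat inter-well plateau; and the anti -> syn gap lands near +3 kcal/mol
  at 300 K, comparable to the purine systems the toy emulates. The
  resulting room-temperature fluctuation widths \(\sqrt{RT/c}\), about 12
  and 8.5 degrees, are somewhat narrower than real conformers'; that
  trade-off is forced by the well geometry once metastability from both
  sides is required.

Two design decisions make the toy's conformational free energy *exactly*
one-dimensional:

1. The profile term represents the conformer-environment interactions
   that create the anti/syn preference, so it is switched with the
   conformer's nonbonded coupling during FEP (the ghost copy has no
   torsional preference, only its restraint). The always-on proper
   dihedrals (scaffold pins, junction pins, rotor-internal term) are all
   invariant under rotation about the chi axis.
2. Explicit pair nonbonded interactions (LJ + Coulomb, Lorentz-Berthelot
   combination, 1-2 and 1-3 exclusions) act between the *anchor*
   particles and the shared set only; rotor particles carry zero LJ depth
   and zero charge. Anchor positions do not move when the rotor turns.

Consequently the Boltzmann measure factorizes as
\(p(\chi, \text{rest}) \propto e^{-\beta V(\chi)}\,p_0(\text{rest})\): the
chi marginal is exactly \(e^{-\beta V}\), and

\[
\Delta G \;=\; -RT\,\ln\frac{\int_{syn} e^{-V(\chi)/RT}\,d\chi}
                           {\int_{anti} e^{-V(\chi)/RT}\,d\chi},
\]

which `exact_free_energy_1d()` evaluates by composite trapezoid with grid
doubling to a relative tolerance of 1e-8 (basin boundaries at the
circular midpoints between the well centers — the natural convention when
no physical boundary is defined). Likewise, both conformer copies attach
to the same scaffold atoms with identical bonded terms and congruent
restraint sets (same force constants and equilibria, except the torsion
centers), so the two restrained-ghost end states have exactly equal free
energies and the cycle total telescopes to the quadrature value. The
restraint equilibria other than the torsion centers are measured from the
generator's reference geometry.

What the toy deliberately does **not** emulate: explicit solvent,
long-range electrostatics, force-field detail, base-pair hydrogen-bonding
networks, or the microsecond dynamics of real DNA. Passing tests
demonstrate that the estimation machinery is correct and internally
consistent at study scale; they do not certify force fields or sampling
adequacy for all-atom systems.

## Sampling

Each lambda state is sampled independently (no replica exchange, matching
per-state independent simulations) by Metropolis Monte Carlo
(`metropolis_sample()`): one sweep is a Gaussian trial displacement of
every particle plus one collective rotation of each conformer rotor about
its torsion axis. The estimand is configurational, so no forces or
integrator are needed — one reason the truncated-well profile (which has
C1 kinks at the well edges) is unproblematic. Acceptance uses the full
reduced potential; proposals producing degenerate geometry are rejected.

Defaults: 10,000 sweeps per state, the first 10% discarded as burn-in,
frames recorded every 10 sweeps. During burn-in the two step sizes adapt
every 50 sweeps toward 30-50% acceptance and are then frozen, so the
production chain satisfies detailed balance exactly (a logged-proposal
audit in the test suite checks the acceptance rule against independently
recomputed energy differences). Per-state seeds are drawn once from the
master seed, making entire cycle runs bit-reproducible. A
zero-acceptance calibration block with the step already at its lower
bound is reported as an adaptation failure.

All states start from the reference hybrid geometry, which is near the
restrained minima of every state in all three schedules; the burn-in
fraction is generous for this starting point.

## Estimation and uncertainties

Stage free energies are estimated by MBAR (`mbar_solve()`), written out
in full rather than delegated: self-consistent iteration on the
dimensionless \(f_k\) with a Newton refinement on the anchored subspace,
converged when \(\max_k |\Delta f_k| < 10^{-8}\) per iteration. Before
estimation, each state's samples are thinned to an effectively
independent subset using the statistical inefficiency
\(g = 1 + 2\sum_t C(t)\) (autocorrelation sum truncated at its first
nonpositive term, clamped to \(g \ge 1\); a constant series is flagged
and treated as fully correlated). Uncertainties are the MBAR asymptotic
covariance; stage errors combine in quadrature into the total. The
reported uncertainty is thus an asymptotic estimate on thinned samples —
the multi-seed spread observed in the test suite is the empirical check
that it is honest.

Two-state consistency checks: `bar()` solves the Bennett implicit
equation by bracketed root finding (widening the bracket before giving
up) with the classical Bennett variance, and `exp_averaging()` provides
the one-sided Zwanzig estimates that bracket BAR. On shared two-state
data BAR and MBAR agree to well under 0.01 kT.

Diagnostics mirror standard free-energy practice:

* **Overlap matrices** (`overlap_matrix()`): the MBAR-weighted
  \(O_{ij} = \sum_n W_{ni} W_{nj} N_j\), rows normalized to 1;
  nearest-neighbor entries are compared against the 0.03 reliability
  threshold.
* **Forward/reverse convergence** (`forward_reverse()`): the stage
  difference re-estimated on growing chronological and time-reversed
  prefixes; agreement within the combined asymptotic error at the final
  fraction declares convergence. "Time" for Monte Carlo data is the sweep
  index.

A stage failing either check flags the cycle report with a warning; the
total is still reported.

## Numerical choices and conventions

* Internal energies are kJ/mol (lengths nm, angles radians); reported
  free energies are kcal/mol with the fixed factor 4.184. The gas
  constant is 8.3144626e-3 kJ/mol/K internally and 1.98720425864e-3
  kcal/mol/K for population conversions, which reproduces conventional
  printed population ratios under nearest-ten rounding.
* Torsions follow the IUPAC sign convention, fixed operationally by the
  cis = 0 / trans = 180 tests; angular deviations in restraints are
  wrapped to the minimal image \((-180, 180]\) before squaring.
* Restraint lambda-coupling multiplies the harmonic energy linearly
  (the semantics of restraint-lambdas in GROMACS-style inputs); the
  hydrogen-bond-style distance and angle restraints are pure harmonic
  (no flat bottom).
* Pseudodihedral restraints act on mass-weighted group centers with an
  optional hydrogen-exclusion flag (mass below 2 amu).
* The release-stage value is reported as the signed 1 -> 0 estimate and
  summed as such; the cycle-closure and restraint-doubling tests pin this
  convention down observationally.
* Collinear torsion geometry raises an undefined-angle error rather than
  returning 0; non-finite energies name the offending term.

## Problem sizes

The study configuration used by the worked examples and the acceptance
checks is the default one: 27 lambda states (6 + 15 + 6), 10,000 sweeps
per state, frames every 10 sweeps, on the 20-particle hybrid toy at
300 K. These sizes were chosen as the smallest at which the stage
estimates are limited by statistics rather than equilibration and every
nearest-neighbor overlap clears 0.03 with margin.

## Known limitations

* The sampler is desk-scale Monte Carlo for toy Hamiltonians: no
  constraints, thermostats, cutoffs or periodic boundaries, and energy
  evaluation is full (not incremental), which is the right trade-off at
  ~20 particles but not beyond.
* MBAR asymptotic errors assume effectively independent samples after
  thinning; strongly multimodal states would require smarter moves, and
  the forward/reverse diagnostic — not the error bar — is the guard
  against that failure mode.
* The XVG reader targets the dialect written by common free-energy
  workflows (comment/metadata lines plus a numeric table with per-state
  legends); it is not a general-purpose Grace parser.
* `exact_free_energy_1d()` is exact only because the toy factorizes by
  construction; it is not an oracle for arbitrary topologies a user might
  assemble by hand.
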