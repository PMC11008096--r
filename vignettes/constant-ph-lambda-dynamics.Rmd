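---
title: "Constant-pH lambda-dynamics with polarizable multipoles: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constant-pH lambda-dynamics with polarizable multipoles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the package's scientific conventions and the design
choices made where several defensible options existed. It is the reference
for anyone extending the code or interpreting its output.

## The extended Hamiltonian

Each titratable site carries a titration variable $\lambda_k$ and, for
residues with two proton placements (His; the two carboxylate oxygens of
Asp/Glu), a tautomer variable $\zeta_k$. Both are mapped from unconstrained
angles by $\lambda = \sin^2\theta$, so no wall or reflection logic is ever
needed; the chain rule contributes a factor $\sin 2\theta$ to the
$\theta$-forces, which vanishes at the end states — end states are
stationary in $\theta$ even when $\partial U/\partial\lambda \neq 0$.
$\lambda = 1$ denotes the protonated state throughout.

Bonded terms are *never* scaled: a deprotonated site keeps the bonded
interactions of its alchemically decoupled proton (parameters of the
protonated topology), so bonded terms contribute nothing to the
$\theta$-forces. For carboxylates both oxygens permanently carry a bonded
"dummy" hydrogen; at most one of them has nonbonded weight at a time.

### State mixing conventions

With end-state parameter sets per atom, moments and polarizabilities mix
as:

| residue | form |
|---|---|
| Lys, Cys | $(1-\lambda)\,M^{(U)} + \lambda\,M^{(P)}$ |
| Asp, Glu | $(1-\lambda)\,M^{(U)} + \lambda[\zeta M^{(P1)} + (1-\zeta)M^{(P2)}]$ |
| His | $\lambda\,M^{(P)} + (1-\lambda)[\zeta M^{(U1)} + (1-\zeta)M^{(U2)}]$ |

The convention is $\zeta = 1 \leftrightarrow$ the $\varepsilon$/HE2 side
(His U1 = HIE; Asp/Glu P1 = proton on the first oxygen). The derivatives
are the exact analytic linears of these forms. Because the two carboxylate
oxygens are chemically equivalent, the shipped Asp/Glu parameter sets are
mirror images and the two protonated tautomers are degenerate; the PMF
fitting utility exposes a constraint that pins the fitted end-state
difference at zero.

Moments are stored as 13-vectors (charge, dipole, full 3×3 quadrupole).
The quadrupole is kept as the full Cartesian matrix with a fixed 1/3
contraction convention in every energy expression; all internal oracles
share that convention.

### Frames and torques

Dipoles and quadrupoles live in local frames (`zthenx`, `bisector`,
`zbisect`, `zonly`, `none`). All end states of a site are required — and
validated at construction — to share the frame convention *and* the
frame-defining atoms. That is what makes a single rotation per atom valid
for both the moments and their state derivatives, and hence a single
torque accumulation. Orientation forces are implemented as the exact chain
rule through the rotation matrix: the analytic Jacobians
$\partial R/\partial p$ of every frame type convert the accumulated
$dU/dM$ into forces on frame-defining atoms. An equivalent torque-based
route (`multipole_torques()` + `distribute_torques()`) is provided and
tested to agree with the chain rule to machine precision. `zonly` frames
require axially symmetric multipoles (validated), since only the axis
direction is geometrically defined.

## van der Waals

Buffered 14-7 with the literature buffering constants (0.07, 0.12),
cubic-mean $r_{min}$ and HHG $\varepsilon$ combining rules, hydrogen
reduction factors applied to interaction-site placement, and bonded mask
scales. One subtlety worth recording: with these buffering constants the
well depth at $r = r_{min}$ is exactly $-\varepsilon$, but the true
stationary point sits about 0.4% inside $r_{min}$; the tests assert the
exact depth and locate the stationary point rather than pretending the
slope vanishes at $r_{min}$.

Per-proton scale factors follow the residue table (non-titrating 1;
Lys/Cys $\lambda$; Asp/Glu $\lambda f^m(\zeta)$; His
$(1-\lambda)f^m(\zeta) + \lambda$), with $f^m(\zeta) = \zeta$ for a $+1$
tautomer direction tag (HE2) and $1-\zeta$ for $-1$ (HD1). Pair energies
scale as $f_i f_j$ and the state derivatives follow by the product rule.
No soft core is used on the titration path: each proton stays shielded by
its heavy atom's repulsion. A standalone soft-core form (finite at contact
for $\lambda < 1$, exactly the buffered 14-7 at $\lambda = 1$, default
constants $\alpha_{sc} = 0.7$, $n = 2$) is provided for completeness. The
pair energy is tapered to zero over a quintic switching window (production
default 10–12 Å; fixtures rescale the window to their cells).

## Permanent electrostatics

Real-space screened interactions, reciprocal-space PME, multipole
self-energy, and a uniform-background correction
$-\pi q_{tot}^2/(2\beta^2 V)$ whose state derivative follows
$\partial q_{tot}/\partial\lambda$ (each site's total charge is affine in
its $\lambda$ with slope $\pm 1\,e$).

All real-space pair interactions are generated from radial kernels obeying
the gradient recursion $\nabla F_n = -\mathbf{x}F_{n+1}$; masking is
applied as complementary-Coulomb corrections
($B_n - (1-s)C_n$, with the AMOEBA m-scales 0, 0, 0.4, 0.8 for 1-2
through 1-5 paths), so masked pairs remain correct even though the
reciprocal sum is unmasked. Masked bonded pairs are always processed,
whether or not they fall inside the real-space cutoff.

PME uses cardinal B-splines (production default: order 5, grid spacing
≤ 1 Å, $\beta = 0.545\,$Å⁻¹ with a 7 Å cutoff) on arbitrary triclinic
cells, spreading charge + dipole + quadrupole sources through spline
derivatives. Forces are the *exact* derivatives of the discrete energy —
including the spreading-weight derivatives — so finite-difference
consistency holds at any spline order; absolute PME accuracy (e.g.
translation invariance of the grid energy) improves with order and grid
density, and the accuracy-oracle tests run at order 8–10 with ~0.3 Å
spacing. The state derivative contracts $\partial M/\partial\lambda$
against the per-site reciprocal potential/field/field-gradient of the
already-computed grid: no second FFT pass.

Two boundary conventions are available: tinfoil (default) and `"vacuum"`,
which adds the spherical surface-dipole term $2\pi|P|^2/(3V)$; the latter
is what makes an isolated $\pm 1$ charge pair in a large cell reproduce
Coulomb's law to the stated tolerance.

Soft-core electrostatics (off by default, as on the main titration path
the titrating hydrogens are not soft-cored) is implemented for the
charge–charge component of designated pairs via
$f = r + \alpha_{sc}(1-\lambda_k\lambda_l)^2$; the higher moments of a
titrating hydrogen vanish at the decoupled end state, so no higher-order
soft core is needed. With soft core off, $f = r$ and the
$\partial f/\partial\lambda$ term of the state derivative vanishes
identically.

## Polarization

Induced dipoles solve $\mu = \alpha(E_d + T\mu)$ with isotropic
polarizabilities, exponential Thole damping ($a = 0.39$, width
$(\alpha_i\alpha_j)^{1/6}$), and AMOEBA-style channel masking: the direct
field $E_d$ excludes sources in the same polarization group; the energy
field $E_p$ uses the bonded p-scales (0, 0, 1, 1); mutual induction is
unmasked but damped. The energy is $U_{pol} = -\tfrac12\,\mu\cdot E_p$.
Damping widths of titrating atoms are frozen at the mean of their
end-state polarizabilities (nonzero ends) or at the single nonzero end
state (titrating hydrogens), so the damping carries no state derivative by
construction.

The solver is a diagonally preconditioned conjugate gradient on the
symmetric system, initialized from the direct dipoles, tolerance on the
maximum dipole-component change (default $10^{-6}\,e$Å; derivative tests
tighten this to $10^{-11}$). Under PBC each operator application costs one
dipole-source PME evaluation. Zero-polarizability sites carry exactly zero
dipole and are excluded from the Krylov space.

The exact gradient requires the auxiliary dipole set $\nu$ solved against
$E_p$ (in vacuum with equal masks $\nu = \mu$); both sets are obtained in
the one SCF pass of each step. The state derivative from that single pass
combines (i) the contraction of $\partial M/\partial\lambda$ with the
accumulated $dU_{pol}/dM$ over all field channels (real, reciprocal —
using the averaged $\mu/\nu$ grids — and self), and (ii) the diagonal
polarizability term, implemented as
$-\tfrac12\sum_i \dot\alpha_i\,F^p_i\cdot F^d_i/k_e$ with the *total*
fields, a form that stays finite as $\alpha\to 0$. Note the symmetric
$\mu/\nu$ structure of the diagonal term: with distinct masks it is the
exact derivative (the single-set expression is the equal-mask special
case), and the re-solved finite-difference oracle is the arbiter.

## Bias terms and propagation

The barrier is $4\beta_t\lambda(1-\lambda)$ per variable (maximum
$\beta_t$ at 0.5, zero at the ends; default $\beta_t = 2$ kcal/mol,
configurable), omitted in $\zeta$ for Lys/Cys. $U_{mod}$ is a polynomial
with zero constant term, default degree 4; His carries three surfaces —
titration polynomials at $\zeta = 1$ (HIE side) and $\zeta = 0$ (HID
side) mixed linearly in $\zeta$, plus a tautomer polynomial scaled by
$(1-\lambda)$. `fit_model_pmf()` returns the *negated* fitted PMF, i.e.
the bias that flattens the measured surface. The pH term is
$\ln(10)\,k_BT\,(pK_{a,ref} - pH)(1-\lambda)$.

Propagation is BAOAB Langevin over Cartesian and $\theta$ degrees of
freedom jointly, thermostatted at the same bath temperature (fictitious
$\theta$ mass default 5 amu·Å²; the toy titration studies use 2 amu·Å²
with a 2 fs step and 10 ps⁻¹ friction). With zero friction the integrator
reduces to velocity Verlet; energy conservation is verified on a relaxed
model compound at 0.5 fs. Sites start at $\lambda = \zeta = 0.5$.

Because the $\theta$-measure is symmetric under $\lambda\to 1-\lambda$,
end-state counting at $pH = pK_a$ gives exactly half deprotonated; away
from the midpoint the $\sin^2$ measure concentrates weight at the end
states and the fitted Hill coefficient of a flat-landscape site comes out
slightly below 1 (≈ 0.92 in the shipped study conditions), a property of
the mapping rather than of cooperativity.

## Sampling analysis

pH replica exchange swaps pH values between walkers with the Metropolis
probability on the pH-bias difference (the only pH-dependent term);
neighbour pairs alternate even/odd parity between attempts; the default
attempt interval is 500 steps. Records are tagged by pH, not by walker.
BAR is solved by bisection of the self-consistency equation to
$10^{-10}$ kcal/mol with the Bennett asymptotic variance. Fraction
counting discards a 10% burn-in by default and uses the 0.10/0.90
end-state thresholds. The Hill fit is unweighted nonlinear least squares
(sample counts per pH are similar by construction in the replica-exchange
protocol; weighting would change little and is not implemented).

Model parameterization runs 11 evenly spaced fixed-$\lambda$ windows,
collects potential-energy differences to neighbouring windows as
forward/reverse work, combines them with BAR, accumulates the PMF and
fits the bias polynomial. For His the same machinery runs twice in
$\lambda$ (at $\zeta \in \{0,1\}$) and once in $\zeta$.

## The synthetic-system generator

`make_fixture()` produces every test system deterministically from its
arguments: multipolar diatomics (axial frames, quadrupoles), small water
boxes (bisector/zthenx frames, polarizable), a cubic ±1 ionic lattice, the
five titratable model compounds as reduced fragments (thiol, ammonium,
carboxylate, imidazole) each solvated by one water in a small P1 cell, a
crystal toy pairing an imidazole with a carboxylate in one cell, and a
zero-atom "analytic site" whose synthetic environment polynomial stands in
for nonbonded interactions. The force-field numbers in these fixtures are
plausible transcriptions in the style of a polarizable protein force
field, *not* a published parameter distribution — with one deliberate
exception: the cysteine sulfur polarizability end states (4.0/2.8 Å³),
which are the literature values for the titrating thiol. Bonded terms are
generated harmonically from the constructed geometry.

What the fixtures do not emulate: solvated condensed-phase density (one
water molecule is not a hydration shell), conformational flexibility of
real capped peptides, crystal packing beyond a single small P1 cell, and
ionic strength. Passing tests therefore demonstrate correctness of the
energies, derivatives and statistical machinery — not force-field realism
or predictive pKa accuracy for real proteins.

## Numerical choices and problem sizes

- Fixture Ewald settings use reduced cutoffs (4–6.5 Å) with
  $\beta\,r_c \gtrsim 3.3$ so that real-space truncation stays below the
  tolerances of the invariance tests; accuracy-oracle tests raise the
  spline order to 8–10.
- Finite-difference audits use $h = 10^{-4}$ Å (Cartesian) and $10^{-5}$
  (state variables), SCF tolerance $10^{-11}$, and a 1e-3 kcal/mol floor
  in the relative-error denominator so exact zeros compare at absolute
  precision. The gradient suite covers ~23 random states across seven
  fixtures.
- The titration recovery study runs 11 BAR windows and a 7-point pH
  ladder (±1.5 around the reference pKa, 0.5 spacing) with 200 000 steps
  of 2 fs per replica, exchanges every 500 steps, samples every 20 steps
  and discards a 10% burn-in. These sizes give ~±0.05 pKa reproducibility
  on the analytic site.
- Degenerate inputs: overlapping atoms without soft core raise a domain
  error; unconverged SCF states are unusable (errors carry the residual
  history); fraction counting with no end-state samples and Hill fits on
  transition-free data are errors, not silent numbers.

## Known limitations

- Pure R: costs are fine for the shipped fixture scale (≤ ~30 atoms,
  grids ≤ 44³) but far from production MD speeds.
- Soft-core electrostatics covers the charge–charge component only.
- No RESPA/multiple-timestep integration, no constraints, NVT only.
- The His tautomer-PMF blending convention is fixed as documented above;
  other blends would require refitting the model bias.
- Space-group symmetry beyond P1, CIF import, and implicit solvent are
  out of scope.
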