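---
title: "Force-modified potential energy surfaces: models, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-modified potential energy surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmpes)
```

## The problem

A mechanophore is a molecular motif that reacts when mechanical force is
applied to it.  The standard computational question is how an external
mechanical perturbation shifts the activation energy
$V_A = E(\mathrm{TS}) - E(\mathrm{reactant})$ of the triggering reaction.
Two perturbations matter here:

* **Constant pulling force** (the classic force-modified potential energy
  surface, FMPES): a collinear force pair of magnitude $F$ applied across
  the two polymer attachment atoms, adding $-F\,d$ to the potential, where
  $d$ is the attachment-pair distance.  This models a mechanophore
  embedded in a stretched chain.
* **Uniaxial compression** (a generalized FMPES term): every atom is
  pushed toward the $xy$-plane of the working frame by a harmonic penalty

  $$V_\mathrm{ext} = \frac{k}{2}\sum_{i=1}^{N} z_i^2,$$

  where $z_i$ is the distance of atom $i$ to the plane and $k$ (N/m) sets
  the strength of the pressure.  The external force is the negative
  derivative, $(0, 0, -k z_i)$ on atom $i$.  This models the pressure
  load a collapsing polymer-microbubble shell exerts on motifs
  crosslinked into its network.

The distinction matters for *flex-activated* mechanophores, which react
through distortion of bond angles adjacent to the scissile bonds rather
than through elongation along the pulling axis: pulling barely activates
them, compression can.  The package's scan drivers tabulate $V_A(F)$ and
$V_A(k)$ so that exactly this contrast can be computed.

## Architecture

The electronic (base) potential is a pluggable contract
(`potential_backend()`): a function returning an energy in hartree, plus
optional analytic gradient and Hessian, with central finite differences
(steps $10^{-4}$ and $10^{-3}$ bohr, configurable) as the fallback.  Any
quantum-chemistry engine can be wrapped this way; the package itself
implements no electronic structure.  All results shown in the package's
own tests come from three built-in analytic surfaces:

* `quartic_double_well_backend()`: $V = a x^4 - b x^2$, with closed-form
  minima $\pm\sqrt{b/2a}$, saddle at 0, and barrier $b^2/4a$;
* `muller_brown_backend()`: the standard four-Gaussian two-dimensional
  benchmark with three minima and two saddles;
* `bead_spring_flex_backend()`: a five-bead flex-mechanophore toy,
  described below.

Units: hartree and bohr internally; Angstrom, kcal/mol, nN and N/m at
every user-facing boundary.  All conversion factors derive from CODATA
2018 constants and live in `fmpes_units` (1 hartree = 627.5095 kcal/mol,
1 bohr = 0.529177 Angstrom, 1 hartree/bohr = 82.387 nN, 1 N/m =
6.42310e-4 hartree/bohr$^2$), and the log-friendly constants are exported
so published numbers are auditable.

## Stationary points

Minima are located with a BFGS quasi-Newton minimizer with Armijo
backtracking (energy non-increasing across accepted steps; deterministic
for a fixed start and settings).  The convergence criterion is the
maximum absolute gradient component, default $10^{-4}$ hartree/bohr.

Transition states use the dimer method: two closely spaced replicas
(half-separation $10^{-3}$ bohr, central images) estimate the
lowest-curvature mode; the orientation is relaxed by Fourier-expansion
rotation steps on the rotational force, and the translation alternates a
Newton step along the dimer axis (using the measured curvature) with a
projected-BFGS relaxation of the transverse degrees of freedom.  The
rotation tolerance tightens automatically as the translation converges,
because a residual axis error otherwise re-injects parallel force into
the transverse relaxation and stalls the walk near the saddle.  The
initial orientation is the lowest Hessian eigenvector when a Hessian is
affordable (always, on analytic surfaces), otherwise a seeded random
vector.  The dimer needs a starting guess near the barrier region; scan
drivers warm-start each step from the previous converged structure for
exactly this reason.

Converged points are characterized by their Hessian eigenvalue signature:
positive definite over the non-zero modes for a minimum, exactly one
negative eigenvalue for a transition state.  Zero modes are handled by
projecting out the rigid-body motions the active external terms leave
symmetric before counting: all three translations and rotations for a
free molecule, only the in-plane translations and the rotation about the
plane normal when the compression term is active (pulling, which depends
on one interatomic distance, breaks nothing).  Projection rather than a
bare magnitude threshold makes classification robust at the default
gradient tolerance, where symmetry modes sit near zero only to second
order.  Eigenvalues with magnitude below $10^{-6}$ hartree/bohr$^2$
(configurable) are treated as zero in the final count.  A dimer search
that converges to something other than a first-order saddle reports that
classification honestly and warns; a scan row whose saddle collapses is
recorded as invalid rather than tabulated.

## Scan drivers

`scan_pulling_force()` defaults to 0 to 4 nN in 0.5 nN increments.
`scan_uniaxial_k()` defaults to $k \in \{0, 2.5, 5, 10, 15, 20, 30, 40,
50\}$ N/m — 10 N/m increments with a finer sub-grid below 20 N/m, where
the onset of the compression response needs resolution; the exact
sub-grid is a package choice and is configurable.  Both drivers re-optimize
reactant and transition state at every grid point on the composed surface,
warm-starting from the previous step (a cold-start mode exists for
auditing; it agrees with continuation to microcalorie accuracy on the
analytic surfaces while the saddle stays near the guess, which for the
flex toy means compressions up to roughly 15 N/m).

Because $V_\mathrm{ext}$ is frame-dependent, a compression scan aligns
the system once at the start and holds the frame fixed.  The default
alignment when an attachment pair exists rotates the attachment vector
into the compression plane, then pins the remaining rotation about that
axis by minimizing $\sum z_i^2$ — the orientation an infinitesimal
compression would select, which keeps the scan continuous as $k \to 0$.
(Without this second condition the orientation at $k = 0^+$ would jump
discontinuously, and continuation would hand the saddle search a
mis-oriented guess.)  Without an attachment pair, a principal-axes
alignment puts the thinnest direction along $z$.  Both are overridable.

## The bead-spring flex toy

The five-bead surface is a deliberately minimal caricature of a
flex-activated mechanophore, built so that its key properties hold *by
construction*:

* a wide triangular pad (atoms 1–3; atoms 1 and 2 are the attachment
  points) anchored by six harmonic springs pins the molecule's
  orientation against the compression plane — rigid rotation cannot hide
  the rest of the structure;
* an apex bead (4) rides 2.4 Angstrom above the pad; the payload bead (5)
  sits on the scissile bond 4–5, oriented parallel to the pad so that
  stretching the bond adds no height while compression couples maximally
  to its bend;
* the scissile bond carries a quartic double well in its length,
  $B(\delta)\,(u^2-1)^2$ with $u = (d_{45} - r_\mathrm{ts})/w$, whose
  barrier $B(\delta) = B_0 e^{-\alpha \delta^2}$ is gated by the bend
  angle 3–4–5: angular distortion $\delta$ switches the barrier off.
  That is flex activation in one line.

Because $B'(0) = 0$ and the double well is stationary exactly at
$u \in \{-1, 0, 1\}$, the unperturbed reactant and transition state sit
exactly at the reference internal coordinates and the unperturbed barrier
is exactly $B_0$ (default 0.05 hartree = 31.38 kcal/mol, a typical
mechanophore scale).  All terms are functions of internal coordinates, so
the energy is rigorously invariant under rigid motion.

Two construction constraints are worth recording.  First, the transition
state stays a *first-order* saddle only while the bend mode's elastic
stiffness exceeds $2 \alpha B_0$; the defaults keep a comfortable margin
(softest non-zero transition-state eigenvalue about 0.03 hartree/bohr²),
because a thin margin makes the saddle numerically ill-conditioned.
Second, the payload azimuth is offset 20 degrees from the pad's mirror
plane: a perfectly symmetric toy would put the compressed transition
state on a pitchfork bifurcation (the sideways tilt mode buckles at some
critical $k$), whereas the offset unfolds every branch into a smooth,
unique function of $k$ — as for a real, unsymmetric molecule.

With the default parameters the toy reproduces the qualitative physics of
flex activation: over the default grid, $V_A(k)$ falls strictly
monotonically from 31.4 to about 18.4 kcal/mol at $k = 50$ N/m, while
$V_A(F)$ changes by less than 0.001 kcal/mol out to 4 nN of
attachment-orthogonal pulling (the package documents and tests a 2 %
bound relative to the zero-force barrier).  The toy is a caricature: it
has no electronic structure, no zero-point or thermal corrections, a
single reactive coordinate, and spring constants chosen for numerical
transparency rather than fitted to any molecule.  Passing tests on it
demonstrate that the *machinery* — composition, optimization, saddle
tracking, continuation — behaves correctly, not that any specific
molecule has a particular barrier.  Quantitative barriers for a real
mechanophore require plugging a quantum-chemistry backend into the same
contract, whereupon identical scan code applies.  Reported activation
energies are bare potential-energy differences throughout (no zero-point
correction), matching what a $\Delta V_A$ on the modified surface means.

## Acoustic dosimetry

The acoustics module covers the desk-scale bookkeeping of sonication
experiments.  For probe sonication, intensity is spent energy over
on-time divided by probe face area, $I = (E/t)/(\pi r^2)$, with the
2 s on / 1 s off duty cycle handled by `duty_cycle_energy()`.  For
focused ultrasound in the linear sinusoidal approximation, $I = p^2/\rho
c$ with $p$ the RMS pressure; the peak pressure is $\sqrt{2}$ larger, and
the FDA mechanical index is $\mathrm{MI} = p_\mathrm{peak,neg}/\sqrt{f}$
(MPa, MHz).  Two conventions deserve a note: the printed relation
$I = p^2/\rho c$ reproduces the standard MI values of the HIFU operating
points only when $p$ in that relation is read as RMS pressure while the
MI uses peak pressure — so `"peak"` is the default convention, with
`"rms"` exposed.  In the linear approximation peak negative pressure is
taken equal to peak pressure magnitude.  Water properties default to
$\rho = 998$ kg/m³ and $c = 1482$ m/s (20 °C); across the 20–37 °C range
the MI changes only in the third decimal, far below the one-decimal
reporting precision.  No derating (tissue attenuation) is applied.

```{r acoustics}
round(mi_from_intensity(0.68, 75.5), 1)    # 0.68 MHz HIFU operating point
round(mi_from_intensity(1.52, 134.2), 1)   # 1.5 MHz band operating point
```

## Numerical choices, in one place

* Gradient convergence $10^{-4}$ hartree/bohr (max component); tests that
  inspect eigenvalue spectra or compare against closed forms tighten this
  to $10^{-7}$–$10^{-9}$, since position error at a stationary point
  scales as (residual gradient) / (softest eigenvalue).
* Finite differences: gradient step $10^{-4}$ bohr, Hessian step
  $10^{-3}$ bohr, both central, both configurable.
* Dimer: half-separation $10^{-3}$ bohr, central images; rotation stops
  at rotational force $10^{-4}$ (tightened adaptively to 0.1 × the
  current gradient, floored at $10^{-10}$); at most 25 rotations per
  translation; per-coordinate step cap 0.3 bohr.
* Curvature tolerance for zero-mode decisions: $10^{-6}$
  hartree/bohr$^2$.
* Degenerate inputs: coincident attachment atoms, negative $k$ or $F$,
  non-finite energies, and count/body mismatches in XYZ files all raise
  immediate, named errors; a non-converged optimization returns its
  diagnostics with `converged = FALSE` instead of failing silently.
* Low-dimensional benchmarks are single pseudo-atoms with unused
  coordinates ignored; their coordinates and energies are taken in the
  surface's own units.

Problem sizes throughout the test suite are the built-in surfaces (1 to 5
atoms) with scan grids of at most nine points — the whole suite and the
reproduction script run in seconds on one CPU.

## Known limitations

Beyond the toy-model caveats above: the compression frame is a fixed
plane (no hydrostatic pressure, no oscillating force); there is no
reaction-path discovery (transition-state guesses are inputs); no
zero-point or finite-temperature corrections; and the dimer implementation
assumes a smooth ($C^2$) surface, as all built-in backends provide.  How a
real molecule is oriented relative to the compression plane, and which
atoms carry the pulling force, are configuration inputs with documented
defaults — not claims about any particular experiment.
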