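---
title: "Steered self-assembly of FF peptide nanotubes and chirality indices: methods"
author: "pnthelix developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steered self-assembly of FF peptide nanotubes and chirality indices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Diphenylalanine (FF) dipeptides self-assemble into helical peptide nanotubes
(PNTs) whose screw sense inverts relative to the monomer: L-FF monomers tend
to give right-handed (D) tubes and D-FF monomers left-handed (L) tubes, an
instance of the general sign alternation of chirality across levels of
hierarchical organization.  `pnthelix` provides a desk-scale, fully
reproducible replica of the computational workflow behind that observation:

1. build a linear chain of FF units of chosen chirality;
2. steer it into a helical conformation with staged external Hooke springs
   under a collisional thermostat (an "MD manipulator");
3. quantify the handedness of the result with two mixed-product chirality
   indices; and
4. aggregate many stochastic realizations into sign statistics.

## The FF unit

Each unit is the complete zwitterionic diphenylalanine dipeptide,
C18H20N2O3 = 43 atoms: a protonated amino terminus (NH3+), a deprotonated
carboxylate (CO2−), a trans peptide bond, and two phenyl rings.  The
geometry is generated from an idealized internal-coordinate (z-matrix)
template with standard bond lengths and angles — it is a synthetic stand-in,
not a crystal structure.  Two deliberate choices:

* **No separate water.**  One common bookkeeping of the 43 atoms splits them
  into "40 dipeptide atoms + 3 water atoms".  Chemically, the complete
  zwitterionic dipeptide is itself exactly 43 atoms (condensation of two
  phenylalanines removes one water; zwitterionic protonation returns its two
  hydrogens and the extra oxygen to the termini).  The package implements
  the chemically complete 43-atom unit; every count the workflow relies on
  (43, 6 × 43 = 258, 24 × 43 = 1032) is unchanged.
* **L convention.**  The template is L at both alpha carbons in the sense
  `det[N−CA, C−CA, CB−CA] > 0`, a convention pinned against an independent
  cheminformatics embedding of L-phenylalanine and frozen in the test suite.
  The D unit is defined as the exact mirror image (x → −x), so enantiomer
  relations hold bitwise rather than approximately.

The default partial-charge set (+1 e spread over the NH3 group, −1 e over
the carboxylate, neutral pairs on the peptide bond) is a versioned fixture
for dipole work; quantum-chemical charges are out of scope and users can
supply their own table.

## The chirality indices

Both indices are built from the scalar triple (mixed) product
$(\mathbf a,\mathbf b,\mathbf c)=\mathbf a\cdot(\mathbf b\times\mathbf c)
=\det[\mathbf a\,|\,\mathbf b\,|\,\mathbf c]$, which is parity-odd and hence
a handedness detector.

**Calpha index.**  With $n$ alpha carbons ordered along the chain there are
$n-1$ support vectors $\mathbf V_i$ joining consecutive Calphas and $n-3$
consecutive triples:
$$X_{\mathrm{total}}=\sum_{i=1}^{n-3}(\mathbf V_i,\mathbf V_{i+1},\mathbf V_{i+2}),\qquad
\chi_{\mathrm{norm}}=\sum_{i=1}^{n-3}\frac{(\mathbf V_i,\mathbf V_{i+1},\mathbf V_{i+2})}{C_i},\quad
C_i=\tfrac13\sum_{j=0}^{2}\lVert\mathbf V_{i+j}\rVert^{k}.$$
Positive means right-handed (label D), negative left-handed (L), exactly
zero is reported as achiral with no tie-break.  The normalization is read
per term, each triple divided by its own $C_i$, with $k = 5$ by default and
configurable; note the resulting quantity is not dimensionless for
$k \neq 3$ — the formula is implemented as printed rather than silently
"fixed", and the scaling law $\chi_{\mathrm{norm}} \propto s^{\,3-k}$ under
coordinate scaling by $s$ is asserted in the tests.

**Dipole index.**  Each unit's dipole moment is
$\mathbf D_i=\sum_a q_a(\mathbf r_a-\mathbf r_{\mathrm{COM}})$ about the
unit's mass-weighted centre of mass (so it is translation invariant), in
e·Å (1 e·Å = 4.8032 D).  Then, for units in helix order and any $n \ge 3$
(not only one 6-unit coil),
$$c_{\mathrm{total}}=\sum_{i=1}^{n-2}(\mathbf D_i,\mathbf D_{i+1},\mathbf D_{i+2}),\qquad
c_{\mathrm{norm}}=c_{\mathrm{total}}/D_{\mathrm{av}}^3,\quad
D_{\mathrm{av}}=\tfrac1n\sum_i\lVert\mathbf D_i\rVert,$$
with the same sign convention.  $c_{\mathrm{norm}}$ is invariant under
uniform dipole scaling.  One consequence of the bundled charge set worth
knowing: units stack head-to-tail (the amino group of unit $i{+}1$ contacts
the carboxylate of unit $i$), so the simple end-group dipoles point
*against* the direction of progression, and a right-handed package-built
helix scores $c_{\mathrm{total}} < 0$ with the default charges.  The
package therefore asserts the dipole sign convention on dipole sets
constructed tangent to the helix, which is the construction the convention
is defined for; magnitudes from quantum-chemically derived charges are
explicitly out of scope.

**Profiles and mixed structures.**  A sliding window (default 12 Calphas)
yields per-window $X_{\mathrm{total}}$ values; a structure is labelled
`mixed` when both signs occupy at least 25% of windows (threshold
configurable).  `score_run()` turns the signed-window fractions into the
fractional left/right scores used in the run-statistics table, optionally
snapped to the display grid {0, 0.2, 0.5, 0.8, 1}.

## The MD manipulator

The engine is a velocity-Verlet integrator (time step 0.001 ps) in a
reduced intramolecular model: harmonic bonds and angles restrained to the
template geometry plus a soft short-range repulsion
$V=\varepsilon(1-r/r_c)^2$ between non-bonded atoms (cutoff 2.5 Å), purely
to prevent overlap.  A full biomolecular force field is deliberately **not**
reimplemented: the package exercises the manipulator protocol and the
chirality analysis, not quantitative dynamics.  Bond (2000 pN/Å) and angle
(500 pN·Å/rad²) stiffnesses are numerical-stability choices: stiff enough to
hold the geometry at 300 K, soft enough that the fastest hydrogen modes
satisfy $\omega\,\Delta t\approx 0.15$.  With these choices the integrator
shows the expected bounded energy oscillation (a few ×10⁻⁴ of E) and a
secular drift below 10⁻⁴ over 10⁴ steps; "drift" is measured as the
difference of windowed mean energies at the two ends of the run, the
meaningful quantity for a symplectic method.

**Scaffold.**  Four spring kinds guide the chain into a helix, mirroring
the published protocol: (1) contacts duplicating the NH3–CO2 salt bridges
between consecutive units; (2) inner-diameter springs from both Calphas of
each unit to a massless anchor on the z axis at the unit's target height,
rest length 2 Å *less* than the target inner radius; (3) outer-diameter
springs from the terminal ring atoms to the same anchors, rest length 2 Å
*more* than the target outer radius, with even and odd units as separately
tunable groups; (4) pitch springs connecting units one turn apart at the
target rise.  The scaffold is achiral — no spring encodes an azimuthal
direction — so nothing in the protocol predetermines the handedness of the
outcome.  The target inner/outer radii are never stated in the source
protocol; defaults derive from the target helix radius (±4 Å) and are
exposed in the config.  "Even/odd" is read as units (not residues).

**Schedule.**  Stage stiffnesses multiply per-spring nominal weights, so
the four kinds keep their relative strengths; the default schedule is
0.001 pN/Å for 5 ps, 0.01 for 15, 0.1 for 30, 1.1 for 30 (80 ps steered),
followed by a relaxation phase with all scaffold springs removed.  The
relaxation duration is not stated in the source protocol; 30 ps is the
package default.

**Thermostat.**  Temperature control is by random elastic collisions with
virtual particles: each atom collides as a Poisson process at rate λ
(default 5 ps⁻¹, the midpoint of the physically motivated 1..10 range);
the virtual particle has mass $m_0 = 1$ a.m.u. and Maxwell velocity at the
target temperature, and the atom's velocity updates as
$v' = \frac{m-m_0}{m+m_0}v + \frac{2m_0}{m+m_0}u$, which preserves the
Maxwell distribution at the target temperature for any mass ratio (asserted
by the equipartition test).  The update equations are the package's own,
since the source names the thermostat but not its equations.

**Reproducibility and parity.**  All randomness is counter-based: every
variate is a pure hash of (seed, step, atom, substream).  Trajectories are
therefore bitwise reproducible, stages continue one stream, and a mirrored
run can replay the *identical* collision sequence with the x components of
the virtual-particle velocities negated.  Because every force term is
parity-equivariant and the repulsion pair list is accumulated in sorted
order (making floating-point summation order reflection-invariant), a
mirrored run is the bitwise mirror of the original.  This is the desk-scale
form of the claim that L monomers and D monomers give mirror-image
outcomes: it holds here exactly, per run, by construction of the dynamics
rather than statistically.

## What the synthetic generators emulate — and what they do not

`build_linear_chain` reproduces the stated initial condition: 24 units,
10 Å gaps, 1032 atoms, first atom fixed.  `build_parametric_helix` is a
fixture generator for sign-convention and geometry tests: units are placed
on an ideal helix and tilted so the local Calpha axis follows the helix
tangent.  Two caveats: the tangential construction needs the circumference
per unit to accommodate the ~11 Å unit (at radius 9 Å and 6 units/turn it
does; at radius ≲ 5 Å the Calpha zigzag dominates and the sign convention
degenerates); and the left-handed branch is *defined* as the mirror of the
right-handed branch built from the mirrored template, so the enantiomer
relation is exact.

A green steering test here establishes that the protocol compacts and
twists the chain reproducibly and parity-equivariantly — not that the toy
engine reproduces the real success statistics.  Without cohesive
(attractive) interactions the assembled helix partially unwinds during the
spring-free relaxation; the published observation that structures stay
helical after release relies on a full force field.  Accordingly the ~80%
single-handedness rate is not asserted anywhere; it is replaced by the
parity property and by `stability_check` mechanics validated on frozen
(T → 0) and deliberately melted (T = 5000 K) fixtures.  The packaged
transcription of the published 32-run table ships as a checksummed TSV so
the aggregation arithmetic (sign totals, fractional expert sums, display
percentages with round-half-away-from-zero) is asserted against printed
values without any simulation.

## Geometry statistics

The nanotube axis is fit as the dominant principal component of the
coordinate covariance through the centroid — robust and deterministic for
near-cylindrical assemblies (a cylinder least-squares fit could be added
behind the same `AxisFit` interface).  Radial statistics (mean/min/max
atom-to-axis distance and layer thickness) use all atoms by default,
selectable by name.  `pair_fit` is a least-squares rigid superposition over
an explicit atom-pair list; the rotation determinant is forced to +1
because a reflecting fit would silently invert the very quantity this
package measures.  Cylindrical maps unwrap outer (max) and inner (min)
atom radii over (azimuth, z) bins, default 30 × 15, with the angular origin
at the first Calpha so maps are comparable across runs.

## Numerical choices and degenerate inputs

* Units: Å, a.m.u., ps, elementary charges; stiffnesses in pN/Å with one
  centralized conversion constant (1 a.m.u. Å/ps² = 0.166054 pN).
* Exactly-zero chirality values are labelled `achiral` and counted in their
  own bucket in statistics, never assigned a side.
* Zero-length support vectors raise an error naming the Calpha pair;
  $D_{\mathrm{av}} = 0$ reports $c_{\mathrm{total}}$ but flags the
  normalization as undefined.
* Angle forces vanish smoothly near θ = 0/π where the gradient is singular.
* Non-finite coordinates abort a run with the step number and maximum force.
* The config round-trips through JSON (the environment guarantees a JSON
  library; YAML would add a dependency for no structural gain).

## Known limitations

* The reduced force field has no attractions, no dihedrals and no
  electrostatics; assembled tubes are looser than experimental ones and
  partially unwind after release.
* Phenyl rings are held planar only by angle terms and can pucker at high
  temperature.
* The dipole index with the bundled end-group charges reflects backbone
  head-to-tail orientation, not quantum-chemical dipoles (see above).
* `chi_norm`'s printed normalization is dimensionful for k ≠ 3; compare
  values only at equal k and scale.
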