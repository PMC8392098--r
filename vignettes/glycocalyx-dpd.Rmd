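---
title: "Modelling interacting glycocalyx brushes with dissipative particle dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interacting glycocalyx brushes with dissipative particle dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`glycodpd` simulates two polymer brushes facing each other across a
solvent-filled gap: a lower brush of semiflexible bead-spring chains tethered
to a wall (the endothelial glycocalyx, EG) and an upper brush anchored to a
moving plane (the glycocalyx of a passing red blood cell, RBC). The two
brushes never touch the question of direct adhesion; the scientific question
is how momentum travels between them through the *near-field flow* of the
explicit solvent, deforming the lower brush and (much more weakly) propelling
the upper surface.

The solvent and chain beads interact by dissipative particle dynamics (DPD).
Each pair within the cutoff $r_c$ feels three central forces,

$$
\mathbf F^C_{ij} = a_{ij}\, w(r_{ij})\, \mathbf e_{ij}, \qquad
\mathbf F^D_{ij} = -\beta\, w^2(r_{ij})\, (\mathbf e_{ij}\!\cdot\!\mathbf
v_{ij})\, \mathbf e_{ij}, \qquad
\mathbf F^R_{ij} = \sqrt{2\beta k_BT/\Delta t}\; w(r_{ij})\, \alpha_{ij}\,
\mathbf e_{ij},
$$

with $w(r) = 1 - r/r_c$ inside the cutoff and zero beyond, and
$\alpha_{ij} = \alpha_{ji}$ a standard Gaussian drawn per pair per step. The
random amplitude is tied to the friction by fluctuation–dissipation, which is
what makes the pair an exact momentum-conserving thermostat. Repulsion maxima
are species-dependent: water–water 25, glycocalyx–water 26.3,
glycocalyx–glycocalyx 30 (both brushes count as glycocalyx); $\beta = 4.5$,
$k_BT = 1$, $\Delta t = 10^{-3}\,\tau$, number density $3\,r_c^{-3}$. All
quantities are in reduced units ($r_c = k_BT = m = 1$); the physical
anchoring ($r_c = 0.5$ nm, $\tau \sim 0.01$–$0.1\,\mu$s, one force unit
$\sim$ 1–10 pN) lives entirely in the analysis layer (`unit_map()`).

Chains add two bonded terms: a harmonic bond $E = k_s (r - b_0)^2$ (note: no
$\tfrac12$ prefactor; $k_s = 100$, $b_0 = 0.5$) and a harmonic bending energy
$E = \tfrac12 k_E (\varphi - \pi)^2$ about the straight angle. The bending
constant maps to an Euler–Bernoulli flexural rigidity via $EI = k_E b_0$;
the baseline $k_E/2 = 231$ gives $\approx 494$ pN nm at 310 K, the measured
stiffness class of heparan-sulfate-dominated brushes.

## Integration and reproducibility

The engine uses the Groot–Warren modified velocity-Verlet scheme
($\lambda = 0.65$, one force evaluation per step with the dissipative term
computed at the predicted velocity). The pair noise is *counter-based*: each
draw is a hash of (seed, step index, ordered pair), so $\alpha_{ij}$ is
symmetric by construction, trajectories are bit-reproducible for a seed on
any iteration order, and a run split at an arbitrary frame resumes
bit-identically (the final force evaluation is carried on the system object).
Tethered beads are pinned; driven beads move kinematically at their
prescribed velocity and are exempt from force integration.

The y axis is closed by soft repulsive walls, $F = a_{\rm wall}(1 - y/r_c)$
perpendicular to the wall inside one cutoff (mirrored at the top), with a
reflective backstop should a bead ever penetrate; x and z are periodic. A
fully periodic, wall-free mode exists for momentum-conservation and
pure-solvent checks.

Two deliberate estimator choices are worth stating. First, the per-bead
force stream used for lifting-force and wall-drag analyses accumulates the
conservative + dissipative pair terms every step; the random term is
excluded because its mean is exactly zero while its variance
($\propto 1/\sqrt{\Delta t}$) would dominate any time average. Second,
bonded-fluctuation statistics are sampled with probe molecules embedded in
an ideal "ghost" bath ($a_{ij}=0$, standard friction): an isolated molecule
under purely central pair friction is not ergodic (its angular momentum is
never damped, and the trimer's 1–3 pair lies beyond the cutoff), whereas the
ghost bath thermalises every mode without perturbing the bonded potentials.
The polar bending angle of a 3-D trimer is Rayleigh-distributed, so the
bending width is estimated as $\sqrt{\langle(\pi-\varphi)^2\rangle/2}$,
which recovers the per-component width $\sqrt{k_BT/k_E}$; the bond-length
standard deviation is compared directly with $\sqrt{k_BT/2k_s}$ (the radial
phase-space factor shifts the exact canonical value by under 2%).

## The case matrix

`glyco_cases()` tabulates the full study conditions: the baseline
three-compartment system (case A: 12 EG chains of 60 beads at spacing
$d_1 = 5$, upper anchors on the $d_0 = 32.5$ plane, drive $0.05\,r_c/\tau$,
domain $80 \times 45 \times 40$, 200 τ equilibration + 1600 τ production)
and its variants: drive speed (A1: 0.005, A2: 0.2), upper-brush shedding
(A3: one upper chain), grafting density (B: 24 chains at 2.5; C: 6 at 10),
chain length (D: 30 beads), stiffness (E1–E4), separation (F: $d_0 = 27.5$),
timed release of the central chain with a $+2\,r_c$ lift (G), and the
propulsion probe (H: five lower chains activated by a 5 τ tip velocity
pulse, three passive upper chains, no drive).

Interpretation choices where the published description is ambiguous:

* $d_0$ is read as the separation between the two *anchor planes* (a
  tip-to-tip reading would preclude any interaction);
* the upper-brush chain count is not printed for most cases and defaults to
  12, mirroring the baseline row, with anchors x-aligned to the lower row;
  case A3 uses exactly one, centred;
* the "upper moving ends" are the single anchor bead of each upper chain;
* bonded neighbours are *not* excluded from the non-bonded pair forces
  (common DPD practice; a flag exists). One visible consequence: soft
  repulsion between bonded neighbours stretches the working bond length to
  $\approx 0.565\,r_c$, so an equilibrated brush can stand slightly taller
  than the nominal contour $N_b b_0$ — height checks compare against the
  stretched contour;
* the case-H activation speed is not printed and defaults to the study's
  only printed drive magnitude, $0.05\,r_c/\tau$;
* the two-compartment case 0 drives the solvent with a uniform body force on
  water beads; "slow" and "fast" presets target mean solvent speeds of
  roughly 0.01 and 0.1 $r_c/\tau$. The published account of that case is
  qualitative, and so is ours.

## Problem scales

The full geometry (432,000 beads, $1.6\times10^6$ steps per case) is a
cluster workload. The package therefore ships geometrically similar
reductions as first-class configurations:

* **mini** — $20 \times 20 \times 10$, 20-bead chains, 4 + 4 chains,
  20 + 60 τ (~12,000 beads);
* **micro** — $10 \times 6 \times 4$, 8-bead chains, 4 + 4 chains,
  5 + 16 τ (720 beads), the scale used by the test suite and the
  acceptance script.

Similarity is enforced on dimensionless ratios: anchor separation
$d_0/l_0 \approx 1.1$, grafting spacings $d_1/l_0$, number density, printed
drive speeds, and — crucially — the persistence-to-contour ratio
$\ell_p/l_0 = k_E b_0/(k_BT\, l_0) \approx 7.8$. Keeping the *printed* $k_E$
at an 8-bead contour would give $\ell_p/l_0 = 66$: rigid rods that plough
through the opposing brush instead of interacting through the flow, which is
the wrong physical regime. The scaled baseline is $k_E/2 = 27$ at micro
scale; the stiffness multiples of E1–E4 and the halved chains of case D
carry over unchanged, as in the published matrix. At micro scale the anchor
spacings tile the periodic x axis exactly, so the brush has no seam at the
boundary.

What the reduced scales can and cannot show: the thermostat, momentum
conservation, equipartition, construction counts, drive kinematics and all
analysis algebra are scale-independent and are tested exactly. Emergent
*orderings* (denser brush → more flow disorder, faster drive → larger
deflection, shorter chains → larger relative deflection, …) survive
reduction only as far as their signal exceeds thermal averaging noise, which
is far larger at 720 beads × 16 τ than at the published scale (roughly 300×
less averaging volume). The checks therefore compare seed-averaged
statistics over five seeds. The strongly driven contrasts — drive speed,
chain length, separation, the rarefied-brush mobility excess, upper-brush
shedding, the released-chain height gain and the near-zero near-surface
shear — resolve at micro scale. The flow-*orientation* statistics do not:
a per-bin mean velocity at this scale carries sampling noise of about
0.06 $r_c/\tau$ against near-field flow means of 0.02–0.1, so the
orientation dispersion largely measures noise, and the density→disorder
ordering (and likewise the net upward "lifting" bias of the gap flow) only
becomes resolvable at the mini scale, whose 50-run sweep is hours of
compute rather than minutes. None of this bears on real biological data:
the generator emulates the published reduced-unit model, not measured
glycocalyx geometries, polydispersity, charge, or RBC membrane mechanics.

## Analysis conventions

* **Deflection**: tip displacement $\Delta x(t)$ relative to the final
  equilibration frame, unwrapped through the periodic boundary; relative
  deflection divides by the nominal contour $l_0$ and averages over chains
  (fast-drive comparisons restrict to the two central chains, as in the
  source analysis).
* **RMSD**: between two consecutive saved frames of a chain,
  $\sqrt{\sum_i w_i \lVert x_i - y_i \rVert^2 / (N_b \sum_i w_i)}$ — the
  printed normalisation, which carries an extra $N_b$ relative to the
  conventional form; `form = "standard"` provides the conventional one, and
  orderings between cases are identical under either. Windowed averages
  default to 100 τ at full scale and production/4 at reduced scales.
* **Flow fields**: bead velocities pooled over a time window onto an
  equal-cuboid mesh (16 × 9 × 1 over the full domain, i.e. 5 × 5 × 40
  $r_c$ bins; the same 16 × 9 × 1 proportions are reused at reduced scale);
  per-bin orientation $\theta = \mathrm{atan2}(v_y, v_x)$; dispersion is the
  circular standard deviation; two-sample comparisons use the
  Kolmogorov–Smirnov test (`stats::ks.test`), cross-checked in the test
  suite against a brute-force ECDF supremum.
* **Shear**: $v_x(y)$ slab profiles differentiated by central differences;
  the near-surface band for the propulsion question sits 7.7–23% of $d_0$
  below the upper anchor plane (25–30 $r_c$ in the full geometry).
* **Viscosity**: calibrated in-engine by a planar Couette micro-simulation —
  frozen bottom layer, driven top layer, $\gamma$ = time-averaged drag
  stress on the frozen layer divided by the measured bulk shear rate
  (about 0.9 in reduced units for the standard water parameters). A
  literature constant is deliberately not used, since the published source
  of $\gamma$ is unstated.
* **Propulsion**: the rigid-cylinder response uses the torque/inertia form
  $\dot\omega = R f_{AN} A / J_L$; the printed rearrangement
  ($J_L/R \times F_{AN}$) is dimensionally inconsistent and is exposed
  read-only for comparison. The outline area is kept as defined,
  $A = \pi R^2 d$, with a documented note that the expression has volume
  dimensions; neither choice affects the qualitative conclusion (the
  near-zero near-surface shear makes the propulsion marginal either way).
* **Settling time**: first time a deflection series stays within a tolerance
  band of its trailing-quarter plateau; with chains as cantilevers this
  scales as $l_0^2$, which is why halved chains (case D) equilibrate first.
  At micro scale the settling time of a 16 τ noisy series is
  ill-conditioned, so the suite asserts the deterministic synthetic-series
  oracle and the D-before-A ordering rather than the quadratic ratio, which
  is only reported.

## Numerical and degenerate-input choices

Coincident beads (r = 0) are counted and skipped with a warning rather than
propagating NaNs; the bending force at the straight angle uses the finite
$\varphi \to \pi$ limit; chains longer than the anchor height (case F) are
laid in at a tilt and relax freely; empty flow bins are flagged and excluded
from statistics rather than zero-filled; interface splines degrade below
four tips with a warning and reject non-monotone tip layouts. Trajectories,
configurations and metrics persist as plain text (extended XYZ, LAMMPS dump
dialect, YAML, CSV with a JSON provenance header); reduced units always, so
unit conversion stays an analysis-time concern.

## Known limitations

No electrostatics or ion transport; no RBC membrane mechanics, tumbling or
tank-treading (the upper anchor plane moves rigidly); no Lees–Edwards
shearing boundaries or lubrication corrections; monodisperse chains only.
The physical unit map is an order-of-magnitude anchoring, not a fitted
parameterisation — in particular the 60-bead, $b_0 = 0.5\,r_c$ chain spans
~15 nm of contour at $r_c = 0.5$ nm, shorter than the ~30 nm heparan sulfate
it represents; the reduced-unit model is implemented as published and the
mapping is left to the user.
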