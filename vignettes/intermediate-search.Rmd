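---
title: "Locating binding intermediates by ratchet-biased unbinding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating binding intermediates by ratchet-biased unbinding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratchetpath)
```

## The problem

Protein–ligand association frequently passes through metastable binding
intermediates: partially bound states in which the ligand is held at the
pocket entrance by a few anchoring contacts while most of its
interactions remain transient. The stability of such an intermediate
bears directly on the dissociation rate of the encounter species and
hence on affinity, so locating the intermediate and characterizing its
contacts is of direct interest for ligand design.

Unbinding is far too slow for unbiased simulation, so this package uses
*biased molecular dynamics* (BMD), a ratchet-and-pawl scheme: a reaction
coordinate `rho` (a ligand-anchor-to-protein-anchor distance) is
monitored, and a half-quadratic penalty

$$ E_\mathrm{bias}(\rho) = \begin{cases}
   \tfrac12\,\alpha\,(\rho_\mathrm{max}-\rho)^2 & \rho < \rho_\mathrm{max}\\
   0 & \rho \ge \rho_\mathrm{max}
 \end{cases} $$

opposes any *regression* of the coordinate below its running maximum
$\rho_\mathrm{max}$, while forward fluctuations advance the watermark
and feel no force at all. The scheme never pushes, it only forbids
return; unbinding therefore proceeds through the system's own thermal
fluctuations, which perturbs the pathway as little as any forced-
unbinding scheme can.

## The search protocol

The search proceeds in three steps, orchestrated by `run_protocol()`:

1. **Fast unbinding** (`step1_unbind()`). One biased run per start
   structure at a deliberately strong force constant
   (`alpha1 = 300` pN/Å, the value at which unbinding completes within
   the 5 ns time limit). Runs are monitored through a joint set of
   channels (`monitor_series()`): the reaction-coordinate distance, the
   pocket-to-moiety center-of-mass distances, per-moiety RMSDs and the
   non-loop protein RMSD. Metastable segments — intervals on which every
   channel is simultaneously stable (`detect_plateaus()`) — are pooled
   if they outlive 150 ps; shorter stable stretches only contribute
   restart structures.
2. **Lifetime extension** (`step2_extend()`). Each restart structure is
   re-run with the force constant walked down the schedule
   `250, 225, …, 50` pN/Å (`next_alpha()`, steps of 25 pN/Å). A plateau
   above 150 ps is pooled; a return of the ligand to the bound well for
   50 ps or more is discarded as a rebound ("alpha too low"); reaching
   the unbound threshold without a plateau triggers the next, lower
   alpha ("too high"); running out of schedule discards the restart.
3. **Clustering and acceptance** (`step3_cluster()`). Pooled segments
   are clustered by average-linkage agglomeration on their feature
   vector (per-moiety center-of-mass distance means and RMSD means) and
   a cluster is accepted only if (i) every member is internally stable,
   (ii) the protein core is not significantly distorted (mean non-loop
   RMSD ≤ 2 Å), (iii) the cluster is tight (every feature's ensemble SD
   ≤ 1 Å), and (iv) the cluster sits near the bound state (cluster-mean
   core distance within 5 Å of the bound-state value).

Two protocol details are choices of this implementation. First, the
plateau a run spends in the *bound* well before escaping satisfies every
stability gate, but it is not an unbinding intermediate; segments whose
mean reaction coordinate lies within the rebound tolerance (1 Å) of the
bound-well position are therefore excluded from the pool and from the
restart list. Second, restart structures are taken one stability window
*inside* a stable stretch rather than at its detected end: plateau
boundaries are only window-accurate, and the final frames of a detected
stretch are often already on the escape path, which would hand step 2 a
structure past the state it is meant to stabilize.

## Thresholds and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| `alpha1` | 300 | pN/Å | unbinds within the 5 ns limit |
| alpha schedule | 250 → 50 by 25 | pN/Å | lifetime-extension range |
| `min_lifetime` | 150 | ps | pooling rule for metastable states |
| `window` | 50 | ps | running-mean stability window |
| `drift_tol` | 0.5 | Å | accepted states drift less than this |
| `fluct_tol` | 1.0 | Å | accepted-state fluctuations stay below 1 Å |
| contact cutoff | 4 | Å | strict `<`; heavy atoms only |
| contact frequency | 0.5 | — | strict `>` in at least one simulation |
| permanent-contact SD | 0.25 | Å | strict `<`, pooled over all frames |
| friction | 60 | ps⁻¹ | implicit-solvent Langevin regime |
| temperature | 300 | K | |
| `dt` | 0.002 | ps | stable for unconstrained bead dynamics |

No numeric drift/fluctuation thresholds for plateau qualification are
dictated by the physics alone; the defaults above are inferred from the
statistics that accepted ensembles of this kind display (per-simulation
fluctuations below 1 Å, core channels near 0.5 Å) and are all exposed
as configuration. The tight-cluster threshold of 1 Å ensemble SD
separates consistent ensembles (SDs ≲ 0.7 Å) from inconsistent ones
(SDs above 2 Å) with a wide margin on both sides.

The integration time step deserves a note: implicit-solvent protein
simulations of this kind use femtosecond steps, and the toy simulator's
default is 0.002 ps. The step is a configuration parameter everywhere;
no component hard-codes it.

## The toy system

Everything downstream of the integrator is tested against a bead-scale
complex (`make_toy_complex()`) whose unbinding coordinate moves on a
prescribed radial landscape: a bound Gaussian well (5 Å, 6 kcal/mol,
width 0.9 Å), a metastable intermediate well (9 Å, 3.5 kcal/mol, width
0.5 Å) and a flat unbound region, with a repulsive wall closing the
funnel at short range. Four tethered pocket beads and a weakly tethered
mobile bead stand in for the protein (the mobile bead plays the
flexible-loop role); a core bead with three peripheral beads held by
vector bonds stands in for the ligand, and a transverse harmonic guide
on the core confines the exit path to a channel the way pocket walls
would.

The well parameters are chosen so that the study conditions hold
simultaneously: the bound well is deep enough (≈ 10 kT) that no escape
occurs in unbiased runs on the nanosecond scale, yet its maximal
restoring force (≈ 4.0 kcal/mol/Å) lies below the 300 pN/Å ratchet
spring so step-1 unbinding completes within the time limit; the
intermediate well's maximal restoring force (≈ 4.2 kcal/mol/Å) exceeds
the strongest step-2 spring (250 pN/Å ≈ 3.6 kcal/mol/Å), so its
residence time grows as the schedule walks down, crossing the 150 ps
pooling rule at intermediate alphas — the regime the protocol is built
to exploit. A narrow intermediate well also keeps the ratchet's
watermark creep small, so the plateau mean reports the well position to
a few tenths of an Ångström.

What the toy system does *not* emulate: real force-field energetics,
solvent structure (bridging waters in the toy analyses come from
hand-built fixtures), ligand conformational entropy, and free tumbling
of the ligand (the vector bonds fix its orientation, standing in for
the orientational persistence that real anchoring contacts provide).
Passing tests on the toy system therefore validate the *search and
analysis machinery* — ratchet bookkeeping, plateau logic, clustering,
contact statistics — not any force field.

`synth_series()` and `synth_contact_trajectory()` plant known plateaus
and known contact populations for the detector and census modules. The
series generator gives plateaus sharp shoulders (1 Å/ps immediately
outside a plateau, a slow drift further out) because barrier crossings
are fast compared to metastable residence; shallow exit ramps would be
absorbed into a plateau by any tolerance-based detector and would make
planted lifetimes ill-defined.

## Numerical choices

* **Integrator**: BAOAB splitting of Langevin dynamics, exact in the
  Ornstein–Uhlenbeck substep; accurate and stable in the high-friction
  regime (60 ps⁻¹) and reducing to velocity Verlet as friction and
  temperature vanish. Implemented in C++; all randomness flows through
  R's RNG, so every run is bit-reproducible from its seed.
* **Units**: Å, ps, amu, kcal/mol; 1 pN/Å = 1.439×10⁻² kcal mol⁻¹ Å⁻²;
  k_B = 1.987204×10⁻³ kcal mol⁻¹ K⁻¹; accelerations converted with
  418.4 amu Å² ps⁻² per kcal/mol.
* **Watermark bookkeeping**: `rho_max` starts at the first frame's
  reaction-coordinate value (zero bias at t = 0) and is updated after
  each step, so the recorded bias energy is identically zero whenever
  `rho ≥ rho_max` — asserted frame-by-frame in the tests.
* **Superposition**: Kabsch closed form via SVD with the reflection
  corrected to a proper rotation; degenerate (collinear) fit sets are
  rejected rather than silently resolved.
* **Plateau detection**: greedy maximal runs under three simultaneous
  gates per channel (head-vs-tail window drift, within-segment SD, and
  a sample-level outlier gate at twice the fluctuation tolerance); runs
  separated by less than a window are fused only when the fused span
  itself passes every gate. The sample gate is what pins boundaries to
  the frame on step-like series; without it a step is absorbed
  gradually and boundary error grows to a full window.
* **Ties and degenerate inputs**: altloc ties in PDB input resolve to
  the first (highest-occupancy) record; single-member clusters have
  ensemble SD 0 by definition (criterion iii is then decided by the
  other criteria); a single simulation yields `ensemble_sd = 0` in
  `summarize_series()`.
* **Sample SDs** use the n−1 denominator throughout: the ensembles are
  small (handfuls of simulations), where the distinction matters.

## Problem sizes

The shipped defaults run the full search at toy scale: 5 start
structures per master seed, a 5 ns time limit for step-1 runs (runs
stop at the unbound threshold long before) and 2.5 ns per step-2
attempt — an order of magnitude beyond the 150 ps pooling rule, which
is all a lifetime-extension attempt needs to decide — frames saved
every 0.5 ps, and up to 6 restart stubs pursued per seed. A full
10-seed recovery study plus a 10-seed barrierless control completes in
a few minutes on one core; the statistical-mechanics checks use
10⁶-step runs of one bead.

## Known limitations

* The plateau detector is tolerance-based, not a change-point model;
  boundaries are only window-accurate, and plateau means inherit a
  small outward bias from the ratchet's watermark creep (a few tenths
  of an Ångström at the default landscape).
* The clustering stand-in (average linkage with a fixed cutoff) is a
  reproducible substitute for what is, in practice, often a manual
  grouping step; the cutoff scales with the feature-space dimension but
  is otherwise a constant.
* Bias-work bookkeeping is first-order in the step and intended for
  diagnostics, not for free-energy estimation (no Jarzynski analysis is
  attempted).
* DCD I/O covers the common CHARMM single-precision layout without unit
  cells; XYZ covers the plain `element x y z` dialect.
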