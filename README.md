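# ratchetpath

Desk-scale toolkit for locating and characterizing metastable
intermediates on protein–ligand unbinding pathways, and for the contact
and geometry analysis that describes them.

Unbinding events are rare on simulation timescales, so the package
implements *biased molecular dynamics* (BMD), a ratchet-and-pawl scheme:
a reaction coordinate ρ (a ligand-anchor–protein-anchor distance) feels
a half-quadratic penalty only when it regresses below its running
maximum ρ_max,

    E_bias(ρ) = ½ α (ρ_max − ρ)²   if ρ < ρ_max,   0 otherwise,

with α quoted in pN/Å (1 pN/Å = 1.439×10⁻² kcal mol⁻¹ Å⁻²). Forward
fluctuations advance the watermark and feel no force, so unbinding is
driven by the system's own thermal motion. Candidate intermediates are
metastable plateaus — intervals on which the reaction coordinate, four
pocket-to-moiety center-of-mass distances and the RMSDs are
*simultaneously* stable for more than 150 ps — found first at a strong
force constant (α₁ = 300 pN/Å, unbinding within 5 ns) and then extended
by walking α down a 250→50 pN/Å schedule in steps of 25. Pooled
plateaus are clustered on their structural features, and a cluster is
accepted only if it is internally stable, leaves the protein core
intact, forms a tight cluster (ensemble SD ≤ 1 Å), and sits close to
the bound state.

The analysis layer provides Kabsch superposition RMSDs under all-Cα
(A1) and group-excluded (A2) alignments, mass-weighted center-of-mass
distances, per-atom RMSF, a contact census with the standard
permanent/transient classification (pair within 4 Å in >50% of frames
of at least one simulation; permanent iff within 4 Å in *every* frame
with pooled SD < 0.25 Å), moiety-by-residue contact maps with a
bridging-water layer, and hydrogen-bond distance/angle statistics.

A Langevin-dynamics toy simulator (BAOAB integrator in C++, friction
60 ps⁻¹, flat-bottom NOE-style restraints, prescribed multi-well
unbinding landscapes) makes every stage testable without any external
download: the planted landscape is the ground truth the search must
recover.

## Worked example

```r
library(ratchetpath)

# a bead-scale complex: bound well at rho = 5 A, planted metastable
# intermediate at rho = 9 A, flat unbound region
cx <- make_toy_complex()
res <- run_protocol(cx, seed = 2)
res
#> protocol_result: intermediate found
#>   sampled 5 start structures from 60 ps of bound-state LD
#>   step 1: 5 runs, 0 pooled, 8 stubs
#>   step 2 stub 1: rebound at alpha 200
#>   step 2 stub 2: pooled at alpha 125
#>   step 2 stub 3: exhausted at alpha 50
#>   step 2 stub 4: rebound at alpha 100
#>   step 2 stub 5: exhausted at alpha 50
#>   step 2 stub 6: pooled at alpha 75
#>   step 3: 2 segments, 1 cluster(s), accepted: 1
#> cluster_report: 1 cluster(s) over 2 segments
#>   cluster 1: n=2, mean rho 9.21 A, criteria [stable,integrity,tight,proximity] ACCEPTED
```

The accepted cluster's mean reaction coordinate (here 9.21 Å) recovers
the planted intermediate well at 9 Å to within a few tenths of an
Ångström — the residual offset is the ratchet watermark's outward
creep. A landscape without an intermediate well
(`make_toy_complex(inter_depth = 0)`) reports "no intermediate found".

Contact analysis on synthetic trajectories with planted contact
populations:

```r
plan <- data.frame(freq = c(1.0, 0.6), mean = c(3.2, 3.4),
                   sd = c(0.15, 0.2), resno = 1:2)
traj <- synth_contact_trajectory(plan, n_frames = 500, seed = 1)
candidate_contacts(traj)
#>   i j lig_name prot_name prot_resid prot_resno freq_max pooled_mean pooled_sd     class
#> 1 3 1       C1        CA        ALA          1    1.000    3.194929 0.1584677 permanent
#> 2 4 2       C2        CA        ALA          2    0.598    4.441751 1.2910120 transient
```

The frequency-1, low-SD pair classifies as permanent; the 60% pair is
transient. `contact_map()`, `bridging_waters()` and `hbond_stats()`
produce the corresponding map and geometry summaries, and
`report_tables()` writes them as TSV/JSON.

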