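---
title: "Event-driven coarse-grained dynamics and polymorph scoring with fibrildmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven coarse-grained dynamics and polymorph scoring with fibrildmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrildmd)
```

## The model

`fibrildmd` simulates peptide aggregation with discontinuous molecular
dynamics (DMD): every interaction is piecewise constant in the pair
distance, so particles fly ballistically between *events* — hard-core
collisions, square-well entries and escapes, bond-wall reflections,
hydrogen-bond formation and rupture — each resolved exactly from the
quadratic crossing time of straight-line relative motion.  There is no
integrator and no time step; the trajectory between events is exact.

Each residue is represented by four spheres: three united backbone atoms
(NH, CA, CO) and one side-chain centroid (SC).  Glycine carries no SC
sphere.  Covalent structure is imposed by hard walls: a bonded pair is
confined to `[l(1 - delta), l(1 + delta)]` around its ideal length `l`.
Besides the three covalent backbone bonds (N-CA 1.46 Å, CA-C 1.51 Å,
peptide C-N 1.33 Å), pseudo-bonds fix the backbone angles (N(i)-C(i)
2.45 Å, CA(i)-N(i+1) 2.41 Å, C(i)-CA(i+1) 2.45 Å, CA-CA 3.80 Å) and
anchor the side chain to its residue's NH, CA and CO.  The default wall
tolerance is `delta = 0.025` for all bonds; it is a configuration
parameter of the interaction table.

Non-bonded interactions:

* **Hard cores.**  Every bead pair repels below the arithmetic mean of
  its hard diameters.  Side-chain beads against backbone beads of the
  same or adjacent residue use a reduced *squeeze* distance
  (`squeeze_factor` x the full core, default 0.75), the coarse-grained
  stand-in for local sterics.
* **Side-chain square wells.**  A 20 x 20 symmetric matrix of well depths
  (in units of the hydrogen-bond energy, `eps_HB = 1`) and ranges.  The
  shipped defaults weight depths by a hydrophobicity product and add an
  attraction for oppositely charged pairs; ranges are 1.5 x the pair hard
  diameter.  The schema also admits an optional second (outer) well step
  per pair; the shipped tables use single wells.
* **Backbone hydrogen bonds.**  An NH and a CO bead within `hb_range`
  (4.5 Å) may form a bond worth `-eps_HB`, provided (i) neither partner
  is already bonded (single occupancy), (ii) same-chain partners are at
  least 4 residues apart, (iii) auxiliary neighbour distances (the
  partner bead against the CA and the flanking amide of the other
  residue) exceed `hb_aux_min` (4.5 Å), which orients the bond, and (iv)
  when the *parallel-preference* bias is on, the local strand directions
  CA(i-1) to CA(i+1) of the two residues are within 90 degrees of
  parallel.  Rupture is purely energetic: an outward crossing succeeds
  only when the radial kinetic energy exceeds `eps_HB`, otherwise the
  pair reflects.
* **Enhanced salt bridge.**  The well depth of the D23/K28 side-chain
  pair (by residue number, on any two chains or within one) is multiplied
  by `salt_bridge_factor` (default 2).  Setting the factor to 1 and the
  parallel bias off recovers the unbiased table exactly.

All parameters are configuration data: `load_forcefield()` reads two
YAML files (geometry and well matrices) with a versioned schema, and
`write_forcefield()` inverts it.  The shipped defaults are this package's
own convention-following parameter set — per-amino-acid values in the
published four-sphere tradition, not a transcription of any particular
published table — and every test depends on the structure and invariants
of the tables, never on specific default values.

### L-isomer preservation

The three side-chain anchor distances determine the SC position only up
to reflection through the backbone plane, and at the shallow side-chain
elevation used here (12 degrees, chosen so stacked sheets do not push
side chains into the next layer) the bond walls alone cannot block the
mirror flip.  The engine therefore enforces handedness directly: each
residue carries a *chirality wall* at a fraction (default 0.25) of the
ideal signed volume `det(NH-CA, CO-CA, SC-CA)`.  The event time is the
smallest positive root of a cubic (the determinant of linearly moving
vectors), and the wall reflects the velocity component along the
constraint gradient in mass-weighted coordinates — an impulse that
conserves energy exactly and momentum by construction (the four gradient
vectors sum to zero).

### Thermostat

Temperature is imposed by Andersen-style ghost collisions: each bead is
resampled from the Maxwell-Boltzmann distribution at the target `T*` at
exponentially distributed times.  The kick rate is specified per bead per
reduced time (default 0.05), not per event: the event rate varies by
orders of magnitude between a dilute gas of chains and a compact
aggregate, so an event-denominated rate would couple the thermostat
strength to the aggregation state.  Ghost kicks and neighbour-list
rebuilds are not counted against the collision budget; reported
collision counts are velocity-changing pair and chirality events only.

### Scheduling

Each bead stores the earliest event over its neighbour pairs; the
globally earliest pair event is necessarily the minimum of both of its
beads, so an indexed binary heap over beads (plus chirality groups)
keyed by `(time, id)` delivers the next event, with ties broken by id.
After every event all affected predictions are recomputed eagerly, so
the queue never holds stale entries.  Neighbour lists use a
`max range + skin` horizon with a displacement-budget rebuild ghost;
pair potentials are classified once per rebuild and cached.  Potential
energy is tracked through discrete shell occupancy (which side of each
discontinuity every pair is on), never through distances, so the energy
bookkeeping across events is exact up to the floating-point error of the
impulses — in practice total energy drifts by less than 1e-13 eps_HB
over 1e6 events without a thermostat.

## Experiment orchestration

`box_length(n, c)` gives the cubic box edge at molar concentration `c`
(`L^3 = n / (c N_A)`); at 1 mM the printed edges for 1..12 chains round
to the conventional values (118 Å for one chain, 237 Å for eight).
`run_schedule()` runs constant or *alternating* temperature protocols:
the thermostat target switches between `T1` and `T2` every `half_cycle`
collisions, the fluctuation-enhancement device used to shake aggregates
out of metastable traps.  The full-scale convention for the half cycle is
5e9 collisions; desk-scale runs in this package's tests use 1e4-1e5.
`scan_fibrillization()` locates the temperature above which a fibril
criterion stops being met, by bracketing on a temperature grid.

## Synthetic conformers

The generator module is the test bed standing in for unpublished
simulation structures.  Fibrillar templates are serpentine CA traces —
zigzag beta-strands (3.35 Å axial spacing, giving the physical
backbone-closure pleat) joined by circular-arc turns — stacked
in-register along z with a 4.9 Å rise.  Backbone beads are placed by
solving, per segment, a one-parameter azimuth equation so that every
pseudo-bond closes; side chains sit in the local residue frame at the
default elevation.  The class conventions (package conventions, chosen
once so the profiles are mutually distinguishable and every stack is
free of hard-core overlaps):

| class | turns | strand gaps | note |
|---|---|---|---|
| U  | 24-27 | 11.4 Å | hairpin; D23 side chain faces K28 (salt bridge in-well), F19 faces I32/L34 |
| S1 | 23-26, 33-36 | 11.4, 11.4 | three-strand serpentine |
| S2 | 21-24, 31-34 | 11.8, 11.4 | early-turn serpentine |
| S3 | 26-29, 35-38 | 11.4, 11.4 | late-turn serpentine |
| D1 | 22-25 | 13.4 | sheared hairpin (2-residue register shift) |
| D2 | 29-32 | 11.4 | late-turn hairpin |
| BH | — | — | single extended strands stacked with a 6 degree per-chain twist; all hydrogen bonds inter-chain |

In the stacked templates the amide of residue `i` donates to the
carbonyl of residue `i-1` on the neighbour chain — the geometric
signature of parallel in-register stacking in this representation — so
the in-register score counts inter-chain bonds with
`res(NH) - res(CO) = 1`; a stack shifted by one CA position scores 0.
All six fibrillar templates at zero jitter carry complete in-register
hydrogen-bond ladders (score 1.0) and strongly negative energies, and
the pairwise similarity between any two class templates stays below the
0.8 fibrillar threshold (largest observed: U vs D1 at 0.76).

Random coils grow step by step with closure-aware sampling: a CA step is
accepted only if the backbone azimuth equation still has a root and the
nascent side chain clears all earlier beads, so finished chains satisfy
every wall and hard-core constraint and can be handed to the engine
directly.  `make_random_config()` places such coils at random positions
and orientations in the concentration-determined box, rejection-sampling
inter-chain proximity, with Maxwell-Boltzmann velocities.

What the generator does *not* emulate: conformational heterogeneity
within a class (each template is a single geometry plus isotropic
jitter), chain-length polydispersity, out-of-register or twisted
protofilaments, and solvent effects.  Classification tests on these
fixtures therefore demonstrate that the similarity statistic separates
idealized classes under coordinate noise — not that it resolves every
structure a long simulation can produce.

## The analysis layer

The similarity measure is deliberately simple: for a structure, take all
intra-chain CA pairs separated by at least 5 residues (190 pairs over
residues 17-40, 231 over 17-42), average each pair distance over all
chains, and correlate the resulting profile with a reference profile
(Pearson r).  It is invariant under rigid motion of either structure and
symmetric in its arguments.  Classification assigns the best-matching
reference class when `r >= 0.8`, labels clusters below 3 chains as
monomer/small-oligomer, calls a cluster *hybrid* when its chains
individually match two different classes with at least 3 chains each,
and everything else disordered.  The secondary-structure rule is a
documented package convention for this bead representation: a residue is
helical when a CA(i)±3 window is below 6.5 Å, a strand when a CA(i)±2
window exceeds 6.0 Å *and* the residue holds a backbone hydrogen bond,
coil/turn otherwise; its acceptance is internal consistency on ideal
fixtures.  Population heat maps select the final 30% of frames per
trajectory by default and bin (r, energy) into a normalized density.

## Desk-scale study sizes

The tests and the acceptance script size every stochastic computation
for a single CPU: energy-conservation audits over 1e6 events,
thermostat statistics from ~1e5 velocity components, classification
recovery over 50 seeds per class at 0.5 Å jitter, and a two-body
square-well pair checked against the closed-form canonical bound
fraction at two temperatures.

The aggregation demonstration uses three chains of the seven-residue
amyloid-core fragment KLVFFAE at 1 mM (the same 171 Å box the full
26-residue fragment would occupy at that concentration).  At millimolar
concentration the mean chain separation is ~100 Å, so the rate-limiting
step is diffusive encounter; the short fragment diffuses several-fold
faster per collision than the 26-residue peptide and brings the complete
story — encounter, sticking, inter-chain hydrogen-bond growth, trimer
formation — inside a few times 1e6 collisions.  The demonstration runs
cold trajectories at `T* = 0.08` (well below this toy system's
aggregation threshold), a hot control at 0.5, a weak thermostat coupling
(0.003 per bead per tau, lengthening ballistic flights and hence
transport), and a bond tolerance of 0.06 so that less of the collision
budget is spent on intra-bond rattling.  These choices are the package's
desk-scale study conditions, stated here once; the generator's physical
defaults (1 mM, three chains, Maxwell-Boltzmann initial velocities) are
not tuned.

## Numerical choices

* Event times come from numerically stable quadratic roots, with the
  shell side taken from tracked occupancy (not from the instantaneous
  distance), and a floating-point guard that clamps tiny negative
  discriminant contributions at shell contact.
* At execution the pair is snapped exactly onto its discontinuity radius
  (a sub-1e-9 Å correction), which keeps constraint audits clean.
* Events closer than ~1e-9 tau are treated as simultaneous and resolved
  in (time, id) order; a zero-time cascade guard aborts with a
  diagnostic rather than spinning.
* Chirality-wall roots below 1e-9 tau are ignored (the wall has just
  reflected); a group found below its wall and still falling is
  reflected promptly.
* The minimum-image convention requires every interaction range to stay
  below half the box edge; the two-body fixtures use boxes respecting
  this.

## Known limitations

* The default parameter set is a convention-following stand-in, not a
  fitted force field; quantitative populations (percent U-shape and the
  like) are outside desk scale and outside this package's claims.
* Hydrogen-bond eligibility is evaluated at formation only; the
  auxiliary geometry is not re-checked while a bond persists.
* An NH-CO pair that drifts inside the bond range without forming (for
  example because a partner was occupied) does not retry until it exits
  and re-enters.
* Observables are recorded on collision-count cadence; their time
  averages are exact (time-weighted inside the engine), but the frames
  themselves are event-time samples.
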