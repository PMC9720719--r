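---
title: "tetragate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tetragate: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetragate)
```

# Scope

tetragate is the post-simulation half of a gating study on a homotetrameric
ion channel — the cardiac ryanodine receptor (RyR2) is the motivating case.
Molecular dynamics itself is out of scope: the package consumes structures
and trajectories that an MD engine (or the synthetic generator) produced, and
implements the structural analyses that turn them into gating statements:

* chimera construction (swapping a subunit, or a segment such as the S4-S5
  linker, between a closed- and an open-state tetramer),
* a gate-anchored pore-radius profile with an open/closed call,
* RMSD time series, last-N-frame average structures, and substructure RMSD
  under a best-aligned-chain-pair criterion,
* residue-pair contact percent occupancy with intra/inter-subunit
  classification and pooled per-residue count summaries,
* sequence-proximity scoring of a disease-mutation catalogue against
  high-occupancy interface sites.

# Coordinate model and numbering

Structures are atom tables grouped into subunits 1-4 (`structure_model`).
Chain-to-subunit assignment is explicit user configuration, because deposited
chain IDs vary between entries.  Two numbering schemes are tracked: deposited
(porcine RyR2 entries run one higher) and canonical (human isoform-1), with
`apply_numbering_offset()` converting between them; every downstream residue
selection assumes canonical numbers, so the conversion is enforced early and
loudly.

Reading policy, chosen for determinism:

* alternate locations: only `''`/`'A'` kept, so the atom set is unique;
* insertion codes: hard error.  RyR2 deposits do not need them, and silently
  accepting them risks an off-by-one in every residue-window analysis;
* `HETATM`, waters, lipids and ions: dropped (protein-only analyses), with a
  flag to retain non-water heteroatoms;
* hydrogens: kept on read, excluded downstream by element filter, since
  contacts and pore radii are defined over heavy atoms;
* on write, `TER` records are regenerated per subunit and serials renumbered.

The modeled channel-domain ranges (4099-4206 and 4485-4963, minus the
disordered segments 4524-4556 and 4672-4694, the open-state model further
lacking 4523) are shipped as `ryr2_regions()`; interval arithmetic on these
ranges reproduces the 531/530 residues-per-subunit accounting of the
closed/open systems.

# Superposition and chimera assembly

`superpose()` is a least-squares rigid-body (Kabsch) fit over alpha-carbons
paired by canonical residue number.  Pairing by number rather than sequence
alignment is deliberate: the systems being compared are the same protein, so
alignment could only introduce spurious pairings.  A proper rotation is
enforced by sign-correcting the SVD, and the returned record carries the
rotation, translation, RMSD and pair count.

Interactive aligners usually prune far pairs before quoting an RMSD, which
lowers the number.  `superpose(prune = TRUE)` reproduces that behaviour
(drop pairs more than 2 SD above the mean deviation, refit, at most 5
cycles) and additionally reports the all-pair RMSD under the final
transform, so both conventions are visible.  Published single-subunit
closed-vs-open RMSD values should be read as aligner-convention-dependent
anchors, not exact targets.

`build_chimera()` fits the donor's target subunit onto the acceptor's, then
replaces either the whole subunit or a residue segment.  Splices are made at
the peptide bond with no geometry regularization: in the workflow this
package supports, the assembled chimera is subsequently minimized and
equilibrated by the MD engine, which relaxes strained junctions.  What the
package does guarantee is visibility: junction C-N distances are reported,
and `clash_check()` lists any heavy-atom pair from different residues under
a separation threshold (1.0 Å default).  Point mutations are not built —
that is a modeling task, not an analysis task — but can be recorded as
labels.

# Pore profiling

The pore radius at height z is the radius of the largest probe sphere that
fits at some in-plane center: the maximum over probe positions of (3-D
distance to the nearest atom center minus that atom's van der Waals
radius), clamped at zero.  Classic profilers solve this with a stochastic
probe walk; tetragate instead uses a deterministic two-stage maximization
per slab — a vectorized coarse grid around a seed followed by Nelder-Mead
refinement — with each slab seeded from the previous slab's optimum.  On
tube-like pores this gives the same answer (the package tests it against an
exhaustive 0.05 Å grid oracle to within 0.1 Å) while being exactly
reproducible without a random seed.

Numerical choices:

* slab step 0.25 Å by default (coarser steps only blur the profile by the
  step-scale z discretization of the wall);
* the profile extends in both directions until the radius exceeds the
  cutoff radius (10 Å default; 12 Å for widely dilated pores whose radius
  passes 10 inside the channel), and the beyond-cutoff samples are not kept;
* the channel axis is laboratory z, the membrane normal of a standard
  membrane-embedded setup.  No principal-axis auto-detection: a
  mis-detected axis fails silently, a mis-oriented input fails visibly;
* vdW radii are Bondi (C 1.70, N 1.55, O 1.52, S 1.80 Å), configurable.
  Other software ships slightly different tables, so absolute radii can
  differ by ~0.1-0.2 Å between tools; cross-tool comparisons should be
  qualitative.

`locate_gate()` anchors z = 0 at the centroid of the four gate residues'
side-chain heavy atoms (I4867 in RyR2), and `normalize_profile()` applies
the shift plus a declared luminal orientation (auto-detecting which side is
luminal from coordinates alone is unreliable, so it is configuration).
`call_state()` reads the gate radius at the sample nearest z = 0 and calls
the state against a threshold of 1.5 Å — the midpoint between the closed
(≲0.8 Å) and open (≳2 Å) gate-radius clusters this kind of analysis
produces — with radii exactly at the threshold called open.  Because a
discrete profile can put its local constriction a sample off the anchor,
the local minimum within ±2 Å of the gate is reported alongside.

# Trajectory statistics

`rmsd_timeseries()` fits every frame to the first over the selected atoms
before computing RMSD, so the series reflects internal motion only.
`average_structure()` keeps the last N frames, fits each to the first
retained frame, and averages coordinates; flexible regions can look
distorted in such an average and are left as-is — the average exists to
compare well-ordered elements across systems with one structure each.

`substructure_rmsd()` reduces both tetramers to a region on all four
subunits, then for each of the 16 subunit pairings superposes that pair and
scores the whole four-subunit substructure under the single transform,
reporting the minimum.  Keeping all four subunits in their mutual
arrangement matters because the gate aperture — the quantity that encodes
the channel state — is a property of the assembly, not of one chain.  The
subunit correspondence implied by a pairing is cyclic (i+k against j+k mod
4), the only choice consistent with C4 architecture.  RMSD is over
alpha-carbons by default (robust to side-chain noise; a flag widens the
selection).

# Contact occupancy

Two residues are in contact in a frame when any pair of their heavy atoms
is within 3.0 Å (inclusive) — a cutoff near the mean donor-acceptor
distance of protein hydrogen bonds, applied to any heavy-atom pair.
Occupancy is the fraction of analyzed frames in which the contact is
present; interactions at or above 30% occupancy are "high percent
occupancy" and are the ones summarized.  Granularity is residue-level: the
underlying detection is atomic, but tallies collapse to residue pairs,
matching how such interactions are counted and discussed.

Two exclusions are applied by default, both configurable:

* same-subunit pairs within 2 sequence positions (backbone neighbours are
  trivially in contact and would swamp every summary);
* when a scope and a partner scope are both given, same-subunit pairs lying
  entirely inside both scopes — an element-vs-environment analysis counts
  element-to-element pairs only when they bridge adjacent subunits.

`summarize_counts()` pools records from several systems into named pools
(e.g. three closed-state systems against three open-state systems, all four
subunits each) and counts per residue position in three modes: at the
element-side residue, at the partner residue, or — for inter-subunit
records only — at both residues of each pair (the interface map).  A
minimum-appearance rule (3 in the interface summaries) keeps a position
when *any* pool reaches the minimum, so a position strong in one state and
absent in the other is retained, which is exactly the contrast of interest.

# Mutation proximity

Disease-mutation catalogues are scored against interaction-site lists by
pure sequence distance: the distance of a mutation to the nearest site in
residue numbers, and the fraction of mutations within k (inclusive).
Sequence, not 3-D, distance is the published criterion and keeps the
statistic independent of any particular frame.  Sites are the union of both
partners of every high-occupancy inter-subunit record of the designated
pool.  Each mutation counts once regardless of how many sites are near it.
Mutations outside the modeled ranges are removed first (with the retained
count reported), and `annotate_missing_adjacent()` flags entries near a
modeling gap, whose apparent remoteness from sites may be an artifact of
the gap.

# The synthetic generator

`make_tetramer()` builds a C4-symmetric pseudo-helical tetramer: one
residue per ring per subunit, carbon spheres for backbone (CA) and
side-chain (CB) positions, walls at a lumen radius and a gate ring of four
residues at a narrower gate radius.  The geometry is analytic on purpose —
the pore radius on the axis is exactly (center radius − vdW radius) — so
profiler output can be checked against arithmetic.  The shipped defaults
mimic the study conditions this package was built around: a gate-ring
center radius of 2.44 Å (gate radius 0.74 Å, the closed cluster) against
5.1 Å (3.4 Å, the open cluster), gate residue 4867, and trajectories of 100
analyzed frames.  `placement_jitter` adds Gaussian coordinate noise for
replicate-style runs; it defaults to 0 so the exact-geometry identities
hold.

`make_trajectory()` emits frames as base-plus-Gaussian-jitter, with
scheduled residue pairs placed exactly at a contact distance in a
Bernoulli(p) subset of frames and exactly at an apart distance otherwise,
so each scheduled pair's true occupancy is known.  An `exact` mode places
the contact in exactly round(p·n) frames, which is how the
30-of-100-frames threshold boundary is exercised.  `make_catalogue()`
constructs mutation catalogues whose within-k fraction is known by
construction (e.g. 36 of 49 within 5).

What the toys do *not* emulate — and hence what passing tests do not show
about real data: chemically valid polypeptides, side-chain packing,
correlated (non-isotropic) thermal motion, conformational transitions, and
contact lifetimes with temporal autocorrelation.  The generator validates
the measurement machinery, not the biology; conclusions about a real
channel require real trajectories.

# Problem sizes and determinism

The shipped tests run the pipeline at deliberately small scale: toy
tetramers of 21-61 residues per subunit, trajectories of 100 frames,
100-seed classification sweeps, 500-seed occupancy-recovery sweeps, and
exhaustive-oracle comparisons on channels of a few hundred atoms.  These
sizes make every oracle comparison exact or near-exact while keeping the
whole suite fast; all quantities scale to full-size channels (~2000
residues, 1000 frames) with cost linear in frames and near-quadratic in
atoms per frame.  Every stochastic component takes an explicit seed and is
bit-reproducible from (spec, seed); there is no hidden global RNG state.

# Known limitations

* The pore maximization is local per slab.  On pathological geometries
  (side channels wider than the main pore within the search half-width) the
  probe could jump basins; the seeded search plus bounded half-width makes
  this unlikely for tube-like channels, and the grid oracle tests guard the
  supported regime.
* Best-aligned-pair substructure RMSD assumes both inputs are C4 tetramers
  with compatible numbering; heteromeric channels would need an explicit
  correspondence.
* Published RMSD and pore-radius values produced by other tools are
  approximate anchors (aligner pruning conventions, vdW tables), not exact
  targets, and the package makes both conventions inspectable rather than
  guessing which one a given publication used.
* Contact detection treats all heavy atoms alike; hydrogen-bond geometry
  (donor-acceptor angles), salt-bridge typing and energy weighting are out
  of scope.
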