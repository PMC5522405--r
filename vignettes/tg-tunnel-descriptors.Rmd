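---
title: "Triglyceride orientation and protein descriptors in lipid-transfer tunnels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triglyceride orientation and protein descriptors in lipid-transfer tunnels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgtunnel)
```

## The problem

Cholesteryl ester transfer protein (CETP) is a banana-shaped plasma protein
with a continuous hydrophobic tunnel, roughly 60 Å long, through which it
shuttles neutral lipids — cholesteryl esters (CE) and triglycerides (TG) —
between lipoprotein particles. While CE-bound structures exist, the TG-bound
state is characterized only indirectly, largely through molecular-dynamics
trajectories. `tgtunnel` implements the descriptor layer of such an
analysis: given per-frame coordinates of a protein with two bound
triglycerides, it quantifies

* the conformation of each TG (tuning-fork-like, trident, random) from the
  angles between its three acyl-chain vectors,
* the orientation of each TG inside the tunnel (head-to-legs vs
  legs-to-head vs random) and the joint pair state of the two TGs
  (parallel N-N, antiparallel N-C, parallel C-C, antiparallel C-N, random),
* whole-protein bending and twisting angles built from domain centres of
  mass,
* superposition RMSDs and trajectory-average structures, and
* protein–lipid contact counts and residue-level contact comparisons.

Because the underlying microsecond trajectories of the motivating study are
not deposited anywhere, the package ships a synthetic-trajectory generator
that emulates their statistical structure with known per-frame ground
truth. Every descriptor is validated against that construction-time truth.

## Chain vectors and orientation states

A triolein molecule is glycerol esterified with three oleoyl chains. On
each TG we construct three vectors from the central glycerol site (the
central carbon in atomistic frames, the GLY bead in coarse-grained ones) to
each chain's C=C double-bond midpoint (atomistic; the unweighted midpoint
of the two carbons) or D-bead (coarse-grained). Roles are assigned by
projection on the tunnel's N→C axis: the chain pointing most C-ward is
`sn1`, the most N-ward is `sn2`, and the remainder is `sn3`. Roles are
re-assigned every frame by default because the third chain genuinely
migrates between tunnel ends; a `first_frame` locking mode exists for
sensitivity checks. Ties in the projection are broken toward the lower raw
chain index.

Orientation classification uses only the sn1–sn3 angle:

| sn1–sn3 angle        | label          |
|----------------------|----------------|
| `[0°, 75°)`          | `HEAD_TO_LEGS` |
| `[75°, 105°]`        | `RANDOM`       |
| `(105°, 180°]`       | `LEGS_TO_HEAD` |

The 75°/105° thresholds are the field's published criterion; the boundary
values themselves are assigned to `RANDOM` so the three labels partition
`[0°, 180°]` cleanly (the published phrasing — "less than 75°", "between
105° and 180°" — leaves the endpoints open; we resolve them to the random
band). A pair of lipids maps to a pair state via the obvious product
taxonomy, with any individually-random lipid making the pair `RANDOM`.

Conformation classification uses both angles: a fork-like lipid (tuning
fork or chair — the literature does not separate the two numerically, and
neither do we) has one small and one large inter-chain angle, a trident has
both small. The small/large thresholds default to 60° and 105°, chosen to
separate the reported signature peaks (30° vs 75–85° vs 135–150°) with
maximal margins; both are configurable.

## The synthetic generator

`generate_trajectory()` emits frames whose lipids sit at state signature
angles plus noise:

* head-to-legs lipids at (sn1–sn3, sn2–sn3) = (30°, 135°), the tuning-fork
  signature;
* legs-to-head lipids at (145°, 30°), its mirror image;
* random-state lipids with sn1–sn3 drawn uniformly inside the (76°, 104°)
  band and sn2–sn3 at 85°.

Geometrically, each lipid is realized in a canonical local frame — chain 1
along the tunnel axis, chains 3 and 2 at the target angles in a fixed
half-plane — then spun about the axis by a seeded random azimuth. This
realizes any target pair in `[0°, 180°]²` exactly (the implied sn1–sn2
angle is the folded sum of the two targets, which always satisfies the
spherical triangle inequality), so the generator's realized angles equal
the targets to floating-point precision.

Noise is applied as a rotation of each chain vector by `|N(0, σ)|` degrees
(optionally hard-truncated by rejection) about a uniformly random
perpendicular axis; chain lengths are untouched. Because *each* of the two
vectors entering an angle can rotate by up to the truncation bound, a
truncation of `t` bounds the angle perturbation by `2t`: with the default
head signature at 30° and truncation 20°, the sn1–sn3 angle stays below
70° < 75° and classification recovers the truth on every frame. Lipids in
the random state are built exactly at their sampled in-band angle with no
additional chain noise — otherwise a 1°-deep excursion could silently
invalidate the truth label; this is the one place where the generator
favours label consistency over noise realism.

State sequences are either explicit or simulated from a row-stochastic
Markov matrix (5 pair states or 3 single-lipid states); Markov runs start
from the chain's stationary distribution, computed as the unit left
eigenvector, so that empirical state frequencies are comparable to the
stationary probabilities without a burn-in.

Two-lipid arrangements place TG_N at the centre of the N-terminal half and
TG_C at the centre of the C-terminal half of a 60 Å axis (centres 30 Å
apart), mirroring how two lipids occupy the tunnel end to end.

What the generator deliberately does **not** emulate: force-field-realistic
lipid internal geometry (only the sites the descriptors consume are
placed), excluded-volume interactions between the lipids and the protein,
and correlated protein–lipid dynamics. Tests passing on synthetic data
therefore validate the *descriptor pipeline* — geometry, classification,
counting — not any claim about real molecular behaviour.

## Protein descriptors

With domain residue ranges for the N-terminal β-barrel, central β-sheet and
C-terminal β-barrel, the bending angle is

θ = arccos( m·n / |m||n| ),

where `m` and `n` run from the central-sheet COM to the N- and C-domain
COMs. The twist angle uses the protein axis — the vector between the COMs
of the central sheet's N-end and C-end sub-ranges (defaulting to its
first/last 10 residues) — and measures the signed angle between the normals
of the two planes spanned by the axis and each barrel COM. The sign follows
the right-hand rule about the N→C axis; the published semantics fix only
that negative means untwisting, so the geometric rule is our convention,
chosen so the twist of the reference crystal geometry comes out positive.
Mirror reflection flips the twist sign and preserves the bend, which the
test suite checks explicitly.

`build_scaffold()` inverts these definitions: given a bend β and twist t it
places the barrel COMs at polar angles 90° ± δ from the axis with
sin²δ = (cos t − cos β)/(1 + cos t) and azimuths ∓t/2, realizing the domains
as small zero-mean point clouds around the prescribed COMs. Recovery is
exact to well below 1e-6°. Two degenerate corners are handled explicitly:
|t| > β is unrealizable (you cannot twist more than you bend) and raises a
geometry error, and β = 180° forces both barrels into one axial plane — it
is constructed (via a central COM displaced off the axis) only for t = 0,
since any other twist is geometrically impossible there. For that reason
descriptor-recovery grids stop at β = 165° and the (180°, 0°) case is
tested separately.

Superposition uses the SVD-based Kabsch algorithm restricted to proper
rotations; the test suite cross-checks it against an independent
quaternion-method (Horn) implementation. RMSD selections default to Cα
sites when present. Average structures superpose every window frame onto
the window's first frame before averaging (an iterative mean-reference
variant is available); this removes global rigid motion so the average
reflects internal rearrangement only.

Domain boundaries matter: published bend/twist values for real structures
depend on residue ranges that are typically not printed, so
`cetp_default_domains()` ships approximate, user-verifiable ranges for the
CETP crystal structure but no test treats real-structure descriptor values
as targets.

## Contacts

Contacts are site pairs within a cutoff (default 5 Å, the usual
hydrophobic-contact criterion) under plain Euclidean distance — no periodic
minimum-imaging, consistent with the whole-molecule assumption made at
read time (a C=C pair more than 10 Å apart raises a broken-molecule error
instead of being silently re-imaged). "Sites" are heavy atoms in
united-atom frames and beads in CG frames. The implementation is a
vectorized distance matrix but is contract-tested for exact integer
agreement with an exhaustive double loop.

Residue-level sets follow the published procedure — computed on a single
(typically time-averaged) frame, a residue counting as in contact when any
of its sites is — with a per-frame occupancy variant (default 50%) for
robustness checks. `compare_contacts()` reports *both* percent-change
conventions (reference-count and query-count denominators) because
published percentages use each of them once; rather than guess a single
intent we label both. Hydrogen bonds use the standard geometric criterion:
donor–acceptor distance ≤ 3.5 Å and donor–H···acceptor angle ≥ 120°.

## Numerical choices

* All coordinates are Angstrom internally; GRO input is converted from nm
  on read. All angles are degrees at every interface.
* Angle histograms are probability-mass histograms over `[0°, 180°]` with
  half-open bins (the last closed), default width 5°; masses sum to 1
  within 1e-12.
* `xyzcsv` trajectories are written with 17 significant digits and
  round-trip bit-exactly; PDB round-trips to the format's 1e-3 Å.
* Site masses are inferred from site-name leading characters; unknown
  elements (e.g. CG bead names) get mass 0 with a warning, which forces
  geometric centre-of-mass weighting for any selection containing them.
* Everything stochastic flows from a single integer seed; identical specs
  produce bit-identical trajectories and report bundles.

## Worked example

```{r example}
ts <- trajectory_spec(2000, state_sequence = rep("PARALLEL_NN", 2000),
                      angular_noise_sigma = 10, noise_truncation = 20,
                      seed = 42)
gen <- generate_trajectory(ts)
cls <- classify_pair_trajectory(gen$trajectory, gen$topologies[[1]],
                                gen$topologies[[2]],
                                gen$axis_end - gen$axis_start)
pair_distribution(cls$pair)
classification_accuracy(cls$pair, gen$truth$state)
```

Problem sizes throughout the package's own validation are deliberately
modest — thousands to ten thousand frames, point-cloud proteins of ~100
sites — chosen as the scale at which every stochastic check (stationary
distributions within three standard errors, 100%-recovery margins) is
already decisive.

## Limitations

* The generator validates the pipeline, not molecular realism (see above).
* Descriptor values for real proteins depend on user-supplied domain
  boundaries; the shipped CETP defaults are a convenience, not a standard.
* No binary trajectory formats (xtc/dcd); converters should target
  multi-model PDB or the `xyzcsv` dialect documented in `read_trajectory()`.
* No kinetic modelling: label sequences are classified per frame, with no
  hidden-Markov smoothing or rate estimation.
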