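---
title: "Methods: trajectory statistics for membrane proteins in memtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory statistics for membrane proteins in memtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtraj)
```

memtraj computes the per-residue statistics with which membrane-protein
MD studies are usually summarized: α-helicity from backbone hydrogen-bond
geometry, contact statistics of protein residues against water, lipid
tails, ions and ligands, RMSD-based equilibration checks, and a
HOLE-style pore-radius profile. This vignette states the models and
conventions precisely, explains the tunable parameters and defaults, and
records the design choices where the design was genuinely open.

## Data model and units

All coordinates are in nanometres and times in picoseconds, the native
GRO/XTC conventions; PDB and DCD input (Ångström) is converted on read.
A `MolecularSystem` is an ordered atom table with residues derived from
runs of (chain, residue number, insertion code), and every atom carries a
group role: `protein`, `water`, `lipid_tail`, `lipid_other`, `ion`,
`ligand` or `other`. A `Trajectory` stores per-frame coordinates, a
triclinic box (row vectors) and strictly increasing, uniformly spaced
times; the frame interval `dt` is inferred from timestamps where the
format provides them (multi-frame GRO titles) and supplied by the caller
otherwise (multi-model PDB and DCD carry none; the default of 10 ps is
the customary save interval).

Distances are minimum-image distances. For orthorhombic boxes the wrap is
exact and closed-form; general reduced triclinic boxes are handled by
wrapping in fractional coordinates and minimizing over the 27 surrounding
lattice images. Large residue-to-group queries use a cell list with
expanding-shell certification, which is exact — tests assert equality
with the brute-force double loop.

### Group assignment

Roles are assigned by an ordered first-match-wins rule list over residue
name, atom name and element patterns. The default rules recognize
TIP3-style water, K+/Na+/Cl− ions and common PE/PG/PC/cardiolipin lipid
residues, and split lipids into `lipid_tail` — only the acyl-chain
carbons (atom names `C2x`/`C3x`), i.e. the aliphatic tail carbons — and
`lipid_other` for head-group, glycerol and hydrogen atoms; a switch
includes tail hydrogens if desired. Free amino acids are chemically
identical to in-chain residues, so ligand detection cannot rely on
residue names: any amino-acid residue with no peptide-bonded protein
neighbour (same chain and, when coordinates are available, C–N distance
below 0.2 nm) is reassigned to `ligand`. Distance calculations default to
all atoms, with a heavy-atoms-only switch, since published cutoffs are
typically applied to full atom sets.

## Helicity

For residue *n* with a residue *n*+4 in the same chain, the metric is the
mean over analyzed frames of the minimum-image distance between the
backbone carbonyl oxygen O(*n*) and the amide nitrogen N(*n*+4). This
heavy-atom pair is the standard proxy for the i→i+4 hydrogen bond — the
amide hydrogen is not required, so the metric works on heavy-atom-only
models. A residue is helical when the mean distance is strictly below the
threshold (default 0.35 nm, the usual O···N hydrogen-bond limit). In an
ideal α-helix the distance is ≈ 0.29 nm; in an extended chain ≈ 1.1 nm,
so the classification margin is wide. Replicas are aggregated as the mean
of per-run mean distances, which equals the pooled mean when runs have
equal frame counts.

Segment calling operationalizes "primarily helical": maximal runs of
helical residues merged across interruptions of at most `max_gap`
residues (default 2) and discarded below `min_length` residues (default
5). These two defaults are not physical constants; they are chosen so
that a clean transmembrane bundle yields one segment per helix while a
single noisy residue does not split a helix. Residues with missing
backbone atoms are reported as NA and treated as non-helical by the
segment caller rather than raising an error.

## Contact statistics

For each residue and particle group, the per-frame statistic is the
minimum distance between any residue atom and any group atom; a frame is
*in contact* when this distance is strictly below the cutoff (default
0.4 nm — the conventional heavy-contact cutoff; strict `<` because the
definition speaks of the distance *dropping under* the cutoff and ties
are measure-zero). Contacts are defined against the group as a whole, not
per molecule: a residue exchanging one water for another without a gap
remains in one contact stretch.

- **Proximity** P = in-contact frames / analyzed frames.
- **Binding events**: one event per out-of-contact → in-contact
  transition. A series that *starts* in contact contributes to P but not
  to events, because no preceding unbound frame was observed.
- **Residence time**: (number of consecutive in-contact frames) × dt,
  counting the triggering frame as one frame; the mean t̄ is over events.
  An event still bound at the final frame is *censored*: it is counted in
  N_b, but excluded from t̄ by default (its duration is only a lower
  bound); a flag includes it.

Over replicas, P and N_b are averaged per run (events can instead be
summed via `nb_mode = "sum"`) and t̄ is pooled over all events of all
runs. For a two-state Markov contact process with per-frame entry
probability *a* and exit probability *b*, the closed forms E[P] =
a/(a+b), E[t̄] = dt/b and E[N_b] ≈ N·a·b/(a+b) hold, and the test suite
checks recovery within three standard errors at a = 0.02, b = 0.2,
dt = 10 ps over 5 runs × 5000 frames.

## RMSD and equilibration

`rmsd_timeseries()` computes per-frame RMSD of a selection against a
reference frame, by default after least-squares (Kabsch) superposition —
both fitted and unfitted modes are exposed because reported RMSD curves
do not always state whether rotational fitting preceded the calculation.
The Kabsch solver excludes reflections and refuses degenerate (collinear)
point sets; it is cross-checked in the tests against an independent
implementation (bio3d) and against exact nulls under rigid motions.
Mass-weighting is not applied by default.

Production pipelines normally discard a fixed equilibration segment
(default trim 50 ns), because the discard point is a study-level choice
justified by an RMSD plateau. `detect_equilibration()` is provided as a
diagnostic: the earliest time after which every subsequent running-window
linear slope stays below a tolerance (defaults: 10 ns window,
0.005 nm/ns), returning the series end with a warning when the series
never settles.

For comparing alternative structural models of one protein,
`pairwise_model_rmsd()` superposes each pair on the backbone atoms (N,
CA, C, O — the standard backbone convention) of the residues present in
all models, matched by author residue number; the exact shared-residue
mapping between differently built homology models is otherwise
underdetermined, and this choice is deliberately simple and documented
rather than inferred.

## Pore-radius profile

At each grid position z along the pore axis (default: the z axis, the
membrane normal; spacing `dz`, default 0.05–0.1 nm), the profile reports
the radius of the largest sphere centred in that plane that overlaps no
protein atom: clearance(x, y) = min over atoms of (distance − vdW
radius), capped at `r_max` = 1 nm. The in-plane centre is found by
Nelder-Mead from the previous slab's centre plus seeded random restarts,
and accepted optima must lie within `max_shift` (default 0.25 nm) of the
previous centre — this keeps the centre line connected, so the search
cannot tunnel out of the pore into open solvent. This is a deterministic
simplification of the simulated-annealing walk of the original HOLE
algorithm; on analytic fixtures (cylinders, frustums) it recovers the
constructed radius within 0.02 nm of an exhaustive 0.01 nm in-plane grid
search, which is the accuracy the package claims. Van der Waals radii
come from a bundled Bondi-style element table; HOLE-format radius files
are importable for compatibility. Slabs with no atoms within reach
report the cap. With a fixed seed the profile is bit-reproducible.

A channel *spans the membrane* when one contiguous run of z bins with
radius ≥ `r_open` covers the whole membrane slab. The default `r_open` =
0.1 nm is the lower edge of the transient openings typically reported
for water-permeated proteins; it is a configuration field, not a
constant. Profiles over time are extracted at a stride (default 200 ps,
including the first analyzed frame), which must be a multiple of dt.

## Synthetic generators

The generators exist so that every statistic can be validated against
known ground truth without external simulation data; they emulate the
*geometry and statistics* of a membrane-protein simulation, not its
physics (no forces, no energetics, no lipid chemistry).

**Ideal helix.** Backbone atoms N, CA, C, O are placed on cylindrical
paths around the helix axis using a template (radius, phase offset and
axial offset per atom) derived once from a chain built at ideal α-helical
torsions (φ = −57°, ψ = −47°) with standard bond geometry; the natural
template has 99.4° twist and 0.156 nm rise per residue. Twist and rise
are free parameters, so the same constructor produces α-helices
(defaults 100°, 0.15 nm; O···N(i+4) ≈ 0.29 nm) and extended chains
(`make_extended_chain`: 180°, 0.347 nm; O···N(i+4) ≈ 1.1 nm). A
180° twist at the *helical* rise would merely loosen the helix without
breaking all i→i+4 contacts, which is why the extended preset also
raises the rise to the extended-chain value.

**Markov contact process.** A one-residue protein and a single group
particle whose separation alternates between a bound (0.25 nm) and an
unbound (0.8 nm) distance following the two-state chain (entry *a*, exit
*b* per frame), started from the stationary distribution. All
expectations are closed-form, making this the primary oracle for the
contact machinery.

**Helix-bundle pore.** `n_helices` (default 10, a common transmembrane
architecture) ideal helices of 30 residues (4.5 nm, spanning the slab
with solvent-exposed ends) stand on a ring around the z axis; the ring
radius is calibrated so the minimum atom-centre distance from the axis
equals `pore_radius` (default 0.45 nm) exactly. Lipid-tail particles are
confined to a 0.65 nm shell around the bundle within the membrane slab
(half-thickness 1.5 nm, a typical hydrophobic core), giving a
bilayer-like local tail density; water lives outside the slab and inside
the pore core; ions and ligands in the solvent. Default counts (250
water, 160 tails, 10 ions, 20 ligands) were chosen from those
compartment volumes so that solvent-exposed residues are hydrated in
most frames and membrane-embedded residues contact tails in most frames
— the qualitative water/tail complementarity the tests assert. All
mobile particles take seeded Gaussian random-walk steps (σ = 0.05
nm/frame) with rejection at compartment boundaries; the protein is
static, which makes channel profiles exactly reproducible. Ligand
particles can be given a harmonic drift toward designated residues
(loitering); biased ligands are placed on their target's side of the
membrane, since the slab is impermeable to them and a drift across it
would strand them at the far leaflet.

Because atoms are discrete, a bundle's per-slab free radius can exceed
the nominal `pore_radius − vdW` at z positions between atom rings; the
*minimum* over the slab — the constriction, which is what span detection
and channel dimensions depend on — matches the construction within
0.02 nm, and that is what the generator self-test asserts.

What passing these tests shows — and what it does not: the statistics,
event definitions, geometry and aggregation are demonstrably correct on
processes whose ground truth is known. The fixtures do not reproduce
force-field physics, water structure, lipid packing or conformational
dynamics, so agreement here says nothing about whether a particular
simulation is converged or its force field adequate.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes load → trim → RMSD → helicity → contacts →
channel, writing one TSV artifact per enabled stage plus a manifest of
MD5 hashes; stage gating leaves other artifacts byte-identical, and
identical config + seed reproduces every file byte for byte (numbers are
written rounded to six decimals precisely so that hashing is stable
across platforms). Any stage failure aborts with a stage-named error.

The test suite and the acceptance script run on deliberately modest
problem sizes — Markov recovery at 5 × 5000 frames, bundles of 3–10
helices with tens of frames, channel grids of 10–25 slabs — chosen so
the full suite completes in well under a minute on one CPU while keeping
every statistical check inside its three-standard-error band. All
fixtures are generated in code at run time; no binary data ships with
the package.

## Known limitations

- XTC/TRR readers are not provided; convert compressed GROMACS
  trajectories to multi-frame GRO (or DCD) first.
- The pore search is a local, connected walk: channels with strongly
  kinked centre lines (displacement > `max_shift` per `dz` step) would
  need a smaller `dz` or larger `max_shift`.
- Contacts are group-level by default; per-molecule exchange kinetics
  (which molecule is bound) are not tracked.
- RMSD assumes whole molecules; it applies no periodic wrapping to
  intramolecular displacements.
- Residue matching across models uses author numbering, not sequence
  alignment.
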