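---
title: "Mining allosteric communication pathways from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining allosteric communication pathways from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

## The problem

Allostery is conformational coupling: ligand binding at one site changes the
behaviour of a distal site through a chain of residue-residue interactions.
Given a conformational ensemble of a protein — typically frames saved from a
molecular dynamics run — `allopath` quantifies that coupling and extracts the
residue pathways most likely to carry it. The workflow is the standard
post-simulation battery for this question: backbone fluctuation metrics,
principal component analysis with a free-energy landscape, dynamic
cross-correlation and contact matrices, their fusion into a weighted residue
graph mined with shortest paths, and geometric detection of the non-covalent
interactions that hold candidate pathways together. The package targets
multi-chain assemblies (its residue renumbering exists precisely because, in
an antibody, "residue 55" is ambiguous across four chains), but nothing in
the machinery is specific to antibodies.

## Models and estimators

**Superposition.** All fluctuation analyses first remove global rotation and
translation by least-squares rigid-body superposition (Kabsch, via SVD, with
the determinant correction that excludes reflections). Fluctuation
quantities use one pass of iterated fitting: compute the time-average
structure, superpose every frame onto it, recompute the average.

**Backbone metrics.** RMSD(t) is the minimised deviation of frame t from a
reference frame over the selected atoms; Rg is the mass-weighted radius of
gyration; RMSF_i = sqrt(⟨|r_i(t) − ⟨r_i⟩|²⟩) is the per-residue fluctuation
amplitude. All computations are in Angstrom; series can be emitted in nm for
GROMACS-style plots.

**Covariance and DCCM.** With Δr_i(t) = r_i(t) − ⟨r_i⟩ the displacement
3-vector of residue i's Cα, the covariance is c(i,j) = ⟨Δr_i · Δr_j⟩ and the
dynamic cross-correlation matrix is the Pearson-style normalisation

C(i,j) = c(i,j) / sqrt(c(i,i) c(j,j)),

+1 for perfectly in-phase motion, −1 for anti-phase. We use denominator F
(not F−1) in the covariance; the choice cancels in C. The diagonal is set to
exactly 1.

**Contact matrix (RCM).** freq(i,j) is the fraction of frames in which the
pair distance is under a cutoff. The default distance is the minimum over
heavy-atom pairs (the smallest-distance convention of contact-map tools)
with a 10 Å cutoff; Cα–Cα distance and a mean-distance variant are available
behind flags. Frequency was chosen as the primary statistic because the
downstream graph needs a gating quantity in [0, 1]; the mean-distance
variant exists because contact maps are sometimes reported that way.

**PCA and free-energy landscape.** The 3n × 3n Cartesian covariance of the
superposed Cα coordinates is eigen-decomposed; projections of the centred
frames onto the leading eigenvectors give the conformational coordinates.
The landscape over (PC1, PC2) is the Boltzmann inversion of the sampled
density on a B × B grid:

G_b = −kT · ln(P_b / P_max),

so the most populated bin sits at exactly 0 and empty bins are unvisited
(G = ∞). Only probability *ratios* enter: rescaling all counts leaves G
unchanged. A dimensionally consistent inversion of this form is what
landscape plots in the MD literature mean even when stated loosely;
G = −kT·ln P plus any constant gives the same basins, and anchoring at
P_max fixes the constant so the global minimum is 0.

**Residue graph fusion and shortest-path map.** The contact matrix gates
edges (residues must actually touch to pass signal directly); the DCCM
weights them:

edge (i,j) exists iff freq(i,j) ≥ f_min and |C(i,j)| ≥ c_min, with weight
w(i,j) = −ln|C(i,j)|.

The negative log makes path weight additive in coupling: a path's total
weight is −ln of the product of its |C| values, so Dijkstra's algorithm
finds the chain of strongest cumulative coupling. A linear 1 − |C| weighting
is available as a config option. The shortest-path map (SPM) then counts,
over all residue pairs, how many shortest paths traverse each edge — all
co-optimal paths are counted when ties occur, so the result does not depend
on node enumeration order — normalises by the maximum count, and retains
edges above an importance threshold. Hotspot residues are the endpoints of
retained edges. Across several systems, `common_residues()` intersects
hotspot sets with an optional ±window tolerance in global residue numbering
(ties collapse to the smallest index).

**Interaction detection.** Four geometric criteria, applied per frame:

| type | criterion | default |
|---|---|---|
| hydrogen bond | donor–acceptor distance AND D–H···A angle | < 3.0 Å, > 150° |
| hydrophobic | Cα–Cα distance between hydrophobic residues, non-neighbours | < 4.0 Å |
| cation–π | min distance, aromatic ring atom to cationic N | < 6.0 Å |
| π–π | aromatic ring centroid distance | < 5.0 Å |

The hydrogen-bond angle is taken at the hydrogen (the standard D–H···A
convention for a 150° threshold). The Cα–Cα hydrophobic criterion is very
restrictive for non-bonded residues — genuinely hydrophobic packing is
usually scored on side-chain carbons — so a `mode = "sidechain"` switch uses
the minimum side-chain carbon distance instead; the Cα form stays the
default because it is the stated criterion this pipeline reproduces.
Histidine counts as aromatic and not as a cation (protonation unknown).
Occupancy of a site is the percentage of frames with at least one event of
the type touching the site, with per-frame pair-count minima/maxima/means
reported alongside. Periodic boundary conditions are not applied; inputs
are assumed whole and clustered.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| contact cutoff | 10 | Å | smallest-distance residue contact convention |
| f_min | 0.5 | fraction | edge must be a contact in half the frames |
| c_min | 0.05 | — | excludes |C| ≈ 0 edges whose −ln|C| weight diverges |
| importance threshold | 0.3 | fraction of max | retains the well-travelled core of the path map |
| FEL bins | 50 | per axis | resolution/occupancy balance at typical frame counts |
| temperature | 300 | K | sets kT for the landscape scale (kJ/mol) |
| timestep | 10 | ps/frame | common trajectory save interval |

f_min, c_min and the importance threshold stand in for thresholds that
published pathway analyses leave unstated; they are printed into every run
manifest so no default is silent.

## The synthetic-data generator

Real MD trajectories of a full protein are not desk-scale, so validation
runs on synthetic ensembles whose ground truth is analytic:

* **Geometry.** Residues sit on a wide helical Cα trace (radius 10 Å,
  20°/residue, consecutive spacing exactly 3.8 Å). Three properties
  motivated this curve: it is self-avoiding (adjacent turns ~28 Å apart);
  contacts at the default cutoff are banded in sequence (|i−j| ≤ 2), so a
  planted chain cannot be short-circuited through space; and the structure
  is wide in all directions, so rigid-body superposition is well conditioned.
* **Fluctuations.** Per-frame displacements are drawn from a multivariate
  Gaussian with covariance σ_i σ_j ρ_ij, independently and identically per
  axis. Isotropy makes the expectation of the dot-product correlation equal
  the generating ρ exactly, keeping ground truth analytic. The default
  σ = 1 Å is a typical Cα fluctuation scale.
* **Planted communication chains.** The chain carries a Gaussian hop-decay
  correlation ρ_on^(hops²) (positive definite by construction). The decay is
  deliberately super-multiplicative: under −ln|C| weights it makes two
  consecutive hops strictly cheaper than one double hop, so the optimal
  route visits every chain member rather than skipping alternate residues
  through i,i+2 contacts. The background is a Gaussian kernel in rest-trace
  distance (ρ_off at 3.8 Å, decaying with distance) — the way correlation
  actually falls off along a protein backbone — rather than unstructured
  noise, which would make entry into the chain's endpoints a coin flip
  between the endpoint and its i+2 neighbour.
* **Interaction fixtures.** Minimal atom groups placed at controlled
  distance/angle, just inside and just outside each criterion.

What the generator does **not** emulate: anharmonic basins and metastable
states (displacements are unimodal Gaussian), side-chain rotamer dynamics,
solvent, periodic-boundary artifacts, and time correlation between frames
(frames are i.i.d. draws). Passing tests therefore demonstrate that the
estimators and the graph mining recover known statistical structure — not
that any particular biological system behaves this way.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear selection atoms; degenerate
  selections raise a validation error rather than returning an arbitrary
  rotation.
* A residue with zero displacement variance cannot be normalised into the
  DCCM; the error names the residue.
* An all-identical projection set is a legal landscape (one occupied bin at
  G = 0), not an error; empty bins are ∞, not NA.
* PSD is enforced with an eigenvalue floor of −1e−8 relative to the largest
  eigenvalue (measurement noise tolerance), and generator correlation
  matrices are eigen-clipped and renormalised to unit diagonal after block
  edits.
* Matrix text output uses 17 significant digits, so write/read round-trips
  are bit-exact; run manifests carry MD5 hashes of every artifact, making
  determinism checkable byte-for-byte.
* All co-optimal shortest paths are counted in SPM importance, which is the
  only ordering-independent choice under exact ties.

One estimator property deserves emphasis: superposing frames onto the mean
removes six rigid-body degrees of freedom *of the fluctuations themselves*,
which shrinks recovered cross-correlations by O(1/n) (about 0.03–0.05 at
n = 50). On real trajectories this is unavoidable (and small at protein
sizes); on generator output, which is produced in a common reference frame
with no rigid-body motion, the unfitted estimator is the unbiased one, and
the correlation-recovery checks use it. Rigid-motion invariance of the
fitted estimator is tested separately.

## Scale of the shipped analyses

The analysis scripts and checks run on 30–50 residue systems with
3000–5000 frames, and 50 000 samples for the landscape inversion — sizes
chosen so every stage's estimator is deep in its convergence regime while
the whole battery runs in seconds. The free-energy regression check uses 15
bins per axis so that occupied bins remain well populated; with many more
bins the count noise in −ln P at the tails dominates the quadratic signal.

## Known limitations

* Contact gating uses a sharp cutoff; no smooth switching function.
* No periodic-boundary handling by default (a minimum-image option for
  orthorhombic boxes exists in the criteria config).
* The SPM importance normalisation follows the max-edge convention; count
  normalisation would change absolute importances but not their order.
* Ligand and glycan chains are excluded from the residue graph by default —
  pathway hotspots are protein residues.
* No basin clustering or representative-structure extraction on the FEL.
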