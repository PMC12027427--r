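# allopath

Post-simulation analysis of protein conformational ensembles, aimed at the
question structural biologists ask of long molecular-dynamics runs of
multi-chain assemblies: **how does a binding event at one site propagate to a
distal site, and through which residues?**

Given a structure (PDB) and a trajectory (multi-model PDB or multi-frame
XYZ), the package computes the standard post-MD battery and fuses it into an
allosteric pathway analysis:

* **Backbone metrics** — RMSD and radius-of-gyration time series, per-residue
  RMSF, after optimal (Kabsch) superposition.
* **Ensemble analysis** — PCA of Cα coordinates; free-energy landscape over
  (PC1, PC2) by Boltzmann inversion, `G = −kT·ln(P/P_max)`.
* **Correlation structure** — displacement covariance `c(i,j) = ⟨Δr_i·Δr_j⟩`,
  dynamic cross-correlation matrix `C(i,j) = c(i,j)/√(c(i,i)c(j,j))` (DCCM),
  and residue contact matrix (fraction of frames within a distance cutoff).
* **Pathway mining** — a weighted residue graph in which contacts gate edges
  and correlations weight them, `w(i,j) = −ln|C(i,j)|`; Dijkstra shortest
  paths; a shortest-path map that retains the edges most traversed over all
  residue pairs (counting co-optimal ties) and reports their endpoints as
  hotspot residues; intersection of hotspots across systems.
* **Non-covalent interactions** — per-frame geometric detection of hydrogen
  bonds (D–A < 3 Å, D–H···A > 150°), hydrophobic contacts (Cα–Cα < 4 Å),
  cation–π (< 6 Å) and π–π (centroids < 5 Å), with per-site occupancy
  statistics.
* **Multi-chain renumbering** — 1-based global residue indices continuous
  across chains in caller-declared order (for an IgG: L-H-L′-H′), so hotspot
  identities are unambiguous across four chains.

Because real trajectories at this scale are not shippable, the package also
ships a **synthetic-ensemble generator** with analytic ground truth: Gaussian
Cα ensembles with a prescribed residue–residue correlation matrix, planted
high-correlation communication chains between distal sites, and interaction
fixtures placed exactly at the geometric criteria. Every stage of the
pipeline is validated against that ground truth and against brute-force
oracles (exhaustive path enumeration, O(n²) interaction scans).

## Worked example

Simulate a 30-residue system with a planted 6-residue communication chain
(residues 13–18, on-chain correlation 0.9 decaying per hop, protein-like
background), then recover the chain from the trajectory alone:

```r
library(allopath)

ps  <- planted_path_spec(13:18, rho_on = 0.9, rho_off = 0.2)
gen <- generate_planted_path(ps, ensemble_spec(30, n_frames = 3000, seed = 404))

C   <- dccm(covariance_matrix(gen$trajectory))   # DCCM from the frames
rcm <- contact_matrix(gen$trajectory, cutoff = 10)
g   <- build_rdcm_graph(C, rcm, f_min = 0.5, c_min = 0.05)
spm <- extract_spm(g, importance_threshold = 0.3)

shortest_paths(g, 13, 18)
#>   source target    weight              path
#> 1     13     18 0.7721851 13-14-15-16-17-18
mean(gen$truth %in% spm$hotspots)
#> [1] 1
```

The shortest source→target route is exactly the planted chain (total weight
≈ 5 × −ln 0.9 plus sampling noise), and every chain residue appears among
the hotspot endpoints of the retained high-importance edges.

The same analysis as a one-config pipeline, with a manifest of MD5-hashed
artifacts (rerunning the same config + seed is byte-identical):

```r
cfg <- run_config(simulate = list(n_res = 30, n_frames = 3000, chain = 13:18),
                  sites = list(orthosteric = 1:4, allosteric = 27:30),
                  output_dir = "out_sys1", seed = 2)
man <- run_all(cfg)   # rmsd/rg/rmsf, dccm, rcm, pca, fel, edges, hotspots,
                      # events, occupancy + manifest.json
```

## Analysis workflow

`analysis/` holds the numbered drivers that reproduce the shipped study on
synthetic systems, writing tables under `results/`:

```
analysis/01_simulate_systems.R    # ground-truth ensembles (A: correlations; B, C: planted chains)
analysis/02_backbone_metrics.R    # RMSD / Rg / RMSF of system A
analysis/03_correlation_pca_fel.R # DCCM recovery, contact map, PCA, FEL
analysis/04_pathway.R             # residue graph, SPM, cross-system consensus
analysis/05_interactions.R        # detector threshold sweeps, occupancy
analysis/06_full_pipeline.R       # run_all() orchestration + determinism check
```

Run them in order from the repository root (`Rscript analysis/01_simulate_systems.R`, …).
Representative output from `04_pathway.R`:

```
system B: 56 edges, 19 retained; source->target path 13-14-15-16-17-18 (weight 0.772)
  planted chain recovery: 100%
common residues across systems: 6, 7, ..., 13, 14, 15, 16, 17, 18, ...
```

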