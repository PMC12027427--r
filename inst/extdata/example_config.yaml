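# Example single-system run configuration for run_all() /
# read_run_config(). A simulate block generates a synthetic system; replace
# it with `structure:` and `trajectory:` paths to analyse real files.
simulate:
  n_res: 30
  n_frames: 3000
  chain: [13, 14, 15, 16, 17, 18]   # planted communication chain
  rho_on: 0.9
  rho_off: 0.2
sites:
  orthosteric: [1, 2, 3, 4]
  allosteric: [27, 28, 29, 30]
contact_cutoff: 10        # Angstrom
contact_mode: min_heavy   # or "ca"
f_min: 0.5                # contact frequency gate
c_min: 0.05               # |C| floor for graph edges
importance_threshold: 0.3 # shortest-path-map edge retention
bins: 50                  # FEL grid per axis
temperature: 300          # K
criteria:
  hbond_max_dist: 3.0
  hbond_min_angle: 150
  hydrophobic_max_dist: 4.0
  cation_pi_max_dist: 6.0
  pi_pi_max_centroid_dist: 5.0
output_dir: allopath_out
seed: 1
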