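# Example analysis configuration for run_pipeline() /
# read_analysis_config(). Synthetic mode generates the desk-scale
# helix/coil pair with known ground truth; files mode instead takes
# helix_trajectory / coil_trajectory paths (columnar format) and an
# optional parameter_table / bulk_kb_table.
mode: synthetic
preset: tfe_like        # or urea_like
box: [6, 6, 6]          # nm
n_frames: 120
bin_width: 0.02         # nm, RDF histogram
r_max: 1.8              # nm, KB integration range (<= half-box)
cutoff: 1.0             # nm, real-space energy cutoff
probe_radius: 0.14      # nm, water-sized probe
grid_spacing: 0.02      # nm, excluded-volume grid
n_blocks: 5             # error blocks
temperature: 300        # K
a33: 1.0                # constant, or supply bulk_kb_table: <tsv>
seed: 20231001
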