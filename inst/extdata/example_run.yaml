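# Example ciliascreen run configuration (see ?run_config for all fields).
# Used as: Rscript inst/cli/ciliascreen.R run --config example_run.yaml
seed: 1
mode: induce_disassembly
sites_per_well: 9
profile_name: arl13b_low_bg
profile_overrides:
  cells_per_field: 60
dim:
- 1024
- 1024
pixel_size_um: 0.325
tf:
  min_size_um: 1.5
  max_size_um: 10.0
analysis_module: TF
qc: true
cell_loss_cutoff: 0.5
mad_k: 3.5
alpha: 0.05
denominator: control_ir1
images_dir: ciliascreen_images
out_dir: ciliascreen_results
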