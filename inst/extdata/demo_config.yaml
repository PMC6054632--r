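# Demo pipeline configuration: control vs case, planted ribosome/oxphos
# destabilization, spiked UGUGUG motif, coupled proteins with the
# ribosome set decoupled. Run with:
#   run_pipeline(system.file("extdata", "demo_config.yaml",
#                            package = "brustab"), "pipeline_out")
seed: 1
case: case
control: control
fold_change_min: 1.5
synthesis_fdr_max: 0.1
enrichment_fdr: 0.05
protein_min_change: 0.1
min_mean_rpkm: 0.5
min_length_bp: 300
pulse_min_rpkm: 0.5
simulation:
  n_genes: 2000
  planted_motif: UGUGUG
  protein:
    coupling_slope: 0.8
    noise_sd: 0.2
    decoupled_sets: ribosome
    n_replicates: 3
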