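# Demonstration pipeline configuration: simulated 4-tissue atlas with one
# ubiquitous 50-gene module and one 30-gene tissue-specific module per
# tissue; power 6, dynamic cut, Fisher overlap alpha 0.05.
output_dir: coexatlas_demo_out
seed: 1
power: 6
min_module_size: 20
deep_split: 2
alpha: 0.05
atlas_spec:
  n_tissues: 4
  n_genes: 600
  n_samples_per_tissue: 100
  noise_sd: 1
  modules:
    - module_id: M_shared
      size: 50
      loading: 0.9
      tissues: all
    - module_id: M_T01
      size: 30
      loading: 0.9
      tissues: [T01]
    - module_id: M_T02
      size: 30
      loading: 0.9
      tissues: [T02]
    - module_id: M_T03
      size: 30
      loading: 0.9
      tissues: [T03]
    - module_id: M_T04
      size: 30
      loading: 0.9
      tissues: [T04]
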