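# Demo configuration for the full synthetic pipeline.
# Defaults of sim_config()/cascade_config() apply to anything not set here.
seed: 11
simulate:
  n_per_cohort: {ref_normal: 200, adj_normal: 200, tumor: 400}
  n_genes: 400
  n_planted_hits: 5
  n_decoys: 200
cascade: {}
mr:
  all:    {causal_beta: -0.05}
  female: {causal_beta: -0.10}
  male:   {causal_beta: 0.0}
ssgsea_alpha: 0.25
horizon_days: 1826
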