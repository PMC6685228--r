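# Synthetic PAAD-like cohort spec: a pancreatic-adenocarcinoma-sized cohort
# (n = 177) whose WES TMB body is calibrated to median 0.92 Mut/Mb with
# IQR approximately 0.60-1.23, plus a ~1% ultra-hypermutator tail.
# Parameters are fixture data for the synthetic generator, not TCGA estimates.
cancer_types:
  - code: PAAD
    n_samples: 177
    tmb_log_mean: -0.08338161
    tmb_log_sd: 0.53
    hyper_fraction: 0.01
    hyper_multiplier: 40
    syn_ratio: 0.45
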