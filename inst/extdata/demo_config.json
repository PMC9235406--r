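{
  "seed": 1,
  "out_dir": "art_demo",
  "design": {
    "n_trials": 30, "p_start": 0.05, "p_increment": 0.05,
    "block_size": 5, "n_versions": 3
  },
  "groups": [
    {"label": "control", "n_subjects": 11, "gamma_mean": 1.39,
     "beta_mean": 0.25, "log_sd_gamma": 0.3, "log_sd_beta": 0.3},
    {"label": "dD", "n_subjects": 24, "gamma_mean": 3.65,
     "beta_mean": 0.07, "log_sd_gamma": 0.3, "log_sd_beta": 0.3}
  ],
  "covariates": [
    {"name": "reading_raw", "target_param": "beta", "correlation": 0.38,
     "mean": 30, "sd": 12},
    {"name": "right_caudate_tiv", "target_param": "gamma_plus",
     "correlation": -0.4, "mean": 0.0025, "sd": 3e-04}
  ],
  "inference": {
    "n_chains": 4, "n_warmup": 1000, "n_samples": 1000,
    "prior_mu_mean": 0, "prior_mu_sd": 1.5, "prior_sigma_scale": 1,
    "rhat_threshold": 1.05
  },
  "statistics": {"cauchy_scale": 0.7071068, "anova_scale": 0.5, "n_perm": 2000}
}
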