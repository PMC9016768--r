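{
  "comment": "Calibrated defaults for the direct-expression circuit (deGFP translated from the activated switches). Produced by scripts/calibrate_defaults.R; lysate composition values are calibration artifacts, not measurements.",
  "k_tx": 0.1,
  "k_tl": [0.00564391969734287, 0.00207892106856466, 0.00173078176818426],
  "theta": [
    [1, 0.0596287914519402, 0.061312015257791],
    [0.378094602237497, 1, 0.219789593317436],
    [0.104059127982702, 0.0483208548763464, 1]
  ],
  "k_hyb": 0.05,
  "k_leak": 0,
  "delta_rna": 0.1,
  "res_tx0": 1,
  "res_tl0": 1,
  "lambda_res": 0.003,
  "mu_res": 0.0001,
  "rnap_total": 0.1,
  "sigma70": 0.3,
  "K28": 0.1,
  "K70": 0.02,
  "k_tx_rep": 0,
  "k_tl_rep": 0,
  "kd_anti": 0.0005,
  "k_on_anti": 100
}
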