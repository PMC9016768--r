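{
  "comment": "Calibrated defaults for the sigma28-coupled circuit (switches translate sigma28; reporter template transcribed by sigma28 holoenzyme). Produced by scripts/calibrate_defaults.R; lysate composition values are calibration artifacts, not measurements.",
  "k_tx": 0.1,
  "k_tl": [0.00356403386347336, 0.00275674411321584, 0.00269541508866205],
  "theta": [
    [1, 0.0993081274358259, 0.0947424765005024],
    [0.274748132295677, 1, 0.263755539836506],
    [0.085874581442384, 0.088725995066488, 1]
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
  "k_tx_rep": 0.05,
  "k_tl_rep": 0.02,
  "kd_anti": 0.0005,
  "k_on_anti": 100
}
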