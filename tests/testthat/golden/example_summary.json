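{
  "n_snps": 10,
  "n_studies": 2,
  "max_causal": 3,
  "rho_star": 0.95,
  "tau_sq": 0.52,
  "ncp_scale": 5.2,
  "gamma": 0.01,
  "path": "lowrank",
  "set_size": 1,
  "set_prob": 0.984177896829702,
  "runtime_sec": 0.017,
  "timestamp": "2026-09-20T13:41:42+0000",
  "package_version": "0.1.0"
}
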