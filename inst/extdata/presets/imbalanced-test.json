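{
  "preset": "imbalanced-test",
  "n_sites": 100000,
  "depth_mean_tumor": 30,
  "depth_mean_normal": 30,
  "depth_dispersion": 8,
  "error_rate": 0.01,
  "bqv_true": [36, 3],
  "bqv_error": [22, 8],
  "mqv_true": [55, 5],
  "mqv_error": [30, 12],
  "strand_bias_frac": 0.3,
  "error_end_bias": 0.4,
  "read_length": 100,
  "n_somatic": 50,
  "n_germline": 100,
  "somatic_vaf": [0.10, 0.60],
  "germline_vaf": 0.5,
  "chrom": "chr1",
  "seed": 1
}
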