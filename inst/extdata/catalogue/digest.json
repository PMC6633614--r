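{
  "baseline_utilities.csv": {
    "rows": 101,
    "md5": "9962df8035f1dc6b65ceea44dd47b11e"
  },
  "disease_costs.csv": {
    "rows": 11,
    "md5": "382d3a97ec8a914241902b1394b81c6d"
  },
  "intermediate_effects.csv": {
    "rows": 7,
    "md5": "e84e5cad01ec88cc04f273b86415b7f8"
  },
  "mediation_factors.csv": {
    "rows": 10,
    "md5": "1285a800db2c76d325ab3afb742f203d"
  },
  "relative_risks.csv": {
    "rows": 61,
    "md5": "133efc8b979e1b80066314148e2ca18b"
  },
  "social_care.csv": {
    "rows": 2,
    "md5": "d59e0bc161516959204c05b0e5f6bc75"
  },
  "theoretical_minima.csv": {
    "rows": 9,
    "md5": "4b36b018f809a6b8014181bd7cd9edf3"
  },
  "unrelated_costs_synthetic.csv": {
    "rows": 202,
    "md5": "4c73e18c42d15ecdc270a9a31104c201"
  },
  "utility_decrements.csv": {
    "rows": 13,
    "md5": "1680ec4ea663a976f19f02222e8ae568"
  }
}
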