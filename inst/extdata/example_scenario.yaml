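# Example scenario configuration for `cvdsim scenario`.
# The treatment-effect numbers below are illustrative user-supplied
# placeholders: the package ships no default statin effect sizes, and these
# values must be replaced with the user's own evidence-based inputs.
scenario:
  cohort: cohort.csv
  coefficients: coefficients.json
  seed: 1
  replicates: 10
  rule:
    ten_year_risk_threshold: 10
    egfr_threshold: 60
  effect:
    ldl_reduction_fraction:
      atorva20: 0.40   # placeholder
      atorva80: 0.50   # placeholder
    rate_ratio_per_mmol:
      mi: 0.80         # placeholder
      stroke: 0.85     # placeholder
      crv: 0.80        # placeholder
      vascular_death: 0.90  # placeholder
  uptake:
    "1": 0.40
    "2": 0.41
    "3": 0.42
    "4": 0.44
    "5": 0.45
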