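# Cut-off rules for micronutrient status classification.
# Convention: a boundary value belongs to the better category
# (pathology is strictly below the cut-off).
rbp:
  unit: umol/l
  deficient_below: 0.83
  insufficient_below: 1.17
vitd_total:
  unit: nmol/l
  insufficient_below: 50
folate_rbc:
  unit: nmol/l
  reference_range: [208, 972]
b12:
  unit: pmol/l
  detection_limit: 128
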