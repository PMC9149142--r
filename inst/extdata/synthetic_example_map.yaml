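site_id: example
column_bindings:
  subject_id: SubjID
  gender: Sex
  sans_item_01: SANS01
  sans_item_02: SANS02
  sans_item_03: SANS03
  sans_item_04: SANS04
  sans_item_05: SANS05
  sans_item_06: SANS06
  sans_item_07: SANS07
  sans_item_08: SANS08
  sans_item_09: SANS09
  sans_item_10: SANS10
  sans_item_11: SANS11
  sans_item_12: SANS12
  sans_item_13: SANS13
  sans_item_14: SANS14
  sans_item_15: SANS15
  sans_item_16: SANS16
  sans_item_17: SANS17
  sans_item_18: SANS18
  sans_item_19: SANS19
  sans_item_20: SANS20
  sans_item_21: SANS21
  sans_item_22: SANS22
  sans_item_23: SANS23
  sans_item_24: SANS24
  sans_item_25: SANS25
  age: AgeinYears
  duration_illness: IllnessYears
gender_value_bindings:
  male: M
  female: F
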