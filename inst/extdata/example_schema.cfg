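# Example column mapping for the bundled synthetic extract
time: tod
cause: icd_group
age: age_y
sex: gender
cause_map.CA: cancer
cause_map.IHD: ischemic_heart_disease
cause_map.PN: pneumonia
cause_map.OTH: other
sex_map.1: male
sex_map.2: female
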