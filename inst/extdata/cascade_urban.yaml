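# Urban India cascade parameters (adults above 20 years).
high_risk_frac: 0.218
htn_given_risk: 0.53
stage1_given_htn: 0.70
lipid_given_htn: 0.30
single_lipid_given_lipid: 0.64
chd_prevalence: 0.105
sector_label: urban
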