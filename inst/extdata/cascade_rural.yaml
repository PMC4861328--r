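# Rural India cascade parameters (adults above 20 years).
high_risk_frac: 0.12            # 10-year CVD risk > 10%
htn_given_risk: 0.53            # hypertension among high-risk adults
stage1_given_htn: 0.70          # stage 1 hypertension among hypertensives
lipid_given_htn: 0.30           # hyperlipidemia among hypertensives
single_lipid_given_lipid: 0.64  # single lipid disorder among hyperlipidemics
chd_prevalence: 0.045           # coronary heart disease prevalence (step 6)
sector_label: rural
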