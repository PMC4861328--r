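name,dose_label,therapeutic_class,daily_cost_incl_tax,rr,rr_ci_low,rr_ci_high
aspirin,75mg,anti-platelet,0.13,0.68,0.60,0.77
atorvastatin,5mg,anti-hyperlipidemic,4.04,,,
atorvastatin,10mg,anti-hyperlipidemic,6.26,0.73,0.67,0.80
atorvastatin,40mg,anti-hyperlipidemic,25.04,,,
atenolol,50mg,beta blocker,2.19,,,
atenolol,100mg,beta blocker,3.94,,,
metoprolol,25mg,beta blocker,11.86,,,
losartan,25mg,ACE/ARB,2.65,0.66,0.60,0.77
losartan,50mg,ACE/ARB,4.55,,,
enalapril,2.5mg,ACE/ARB,3.77,,,
enalapril,5mg,ACE/ARB,6.27,,,
hydrochlorothiazide,12.5mg,anti-hypertensive,1.03,0.75,0.63,0.87
amlodipine,5mg,anti-hypertensive,3.24,,,
nifedipine SR,30mg,anti-hypertensive,3.52,,,
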