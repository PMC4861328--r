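# Default step-up regimen recipe.
# Drug keys are "<name> <dose_label>" as in the shipped catalog.
# Steps 1-5 are primary prevention; step 6 is secondary prevention
# (adds a beta blocker, swaps out the second anti-hypertensive).
steps:
  - label: "Step 1"
    purpose: primary
    drugs: ["aspirin 75mg"]
  - label: "Step 2"
    purpose: primary
    drugs: ["aspirin 75mg", "hydrochlorothiazide 12.5mg"]
  - label: "Step 3"
    purpose: primary
    drugs: ["aspirin 75mg", "hydrochlorothiazide 12.5mg", "losartan 25mg"]
  - label: "Step 4"
    purpose: primary
    drugs: ["aspirin 75mg", "hydrochlorothiazide 12.5mg", "losartan 25mg", "atorvastatin 10mg"]
  - label: "Step 5"
    purpose: primary
    drugs: ["aspirin 75mg", "hydrochlorothiazide 12.5mg", "losartan 25mg", "atorvastatin 40mg"]
  - label: "Step 6"
    purpose: secondary
    drugs: ["aspirin 75mg", "hydrochlorothiazide 12.5mg", "atenolol 50mg", "atorvastatin 40mg"]
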