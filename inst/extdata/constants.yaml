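# Default constants of the capillary oxygen transport model.
# Units are declared in the key names; see ?oef_constants.
alpha_H: 3.1e-5     # oxygen solubility (mL O2 / mL / mmHg)
P50_mmHg: 26        # half-saturation oxygen tension
B: 0.1943           # hemoglobin-bound oxygen capacity (mL O2 / mL blood)
hill_h: 2.8         # Hill coefficient
S_a: 0.95           # arterial oxygen saturation fraction
PtO2_mmHg: 21.8     # tissue oxygen tension (calibrated: OEF ceiling 0.6)
k_per_s: 68         # oxygen transfer rate constant (cohort-calibrated mean)
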