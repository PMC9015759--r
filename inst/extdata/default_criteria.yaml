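# Default cohort inclusion criteria over the shipped synthetic vocabulary.
# Code sets are configuration: swap in institutional value sets for real use.
asthma_dx_codes: [ASTHMA]
respiratory_dx_codes: [BRONCHITIS, WHEEZING, COPD, URI]
pulmonary_dx_codes: [PULM_FIBROSIS, SARCOIDOSIS, BRONCHIECTASIS]
asthma_med_codes: [ALBUTEROL, FLUTICASONE, MONTELUKAST, BUDESONIDE]
asthma_proc_codes: [SPIROMETRY, PEAK_FLOW, FENO]
nebulizer_med_codes: [ALBUTEROL_NEB]
frequent_ed_threshold: 2
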