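cohort,initial_n,rule,n_removed
discovery,153426,prevalent_cancer,3972
discovery,153426,no_followup_information,1447
discovery,153426,no_lifestyle_or_diet_data,2916
discovery,153426,extreme_energy_ratio,2850
discovery,153426,missing_confounders,19243
replication,2411,prevalent_cancer,75
replication,2411,incomplete_dietary_data,279
replication,2411,missing_confounders,96
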