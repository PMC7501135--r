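factor,outcome,label,hr,ci_low,ci_high
dry_cakes_biscuits,low_grade,discovery,1.07,1.03,1.11
dry_cakes_biscuits,low_grade,replication,1.09,1.02,1.16
butter,aggressive,discovery,1.08,1.04,1.13
butter,aggressive,replication,1.03,0.96,1.11
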