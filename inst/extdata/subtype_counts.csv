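cohort,quantity,count
discovery,total_cases,5916
discovery,stage_known,3465
discovery,localized,2321
discovery,advanced,1144
discovery,grade_known,3742
discovery,low_grade,3164
discovery,high_grade,578
discovery,aggressive,1770
discovery,fatal,709
replication,total_cases,3842
replication,stage_known,3563
replication,localized,2312
replication,advanced,1251
replication,grade_known,3446
replication,low_grade,2593
replication,high_grade,853
replication,aggressive,1667
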