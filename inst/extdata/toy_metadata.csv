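sample_id,chronological_age,group,braak_stage
s1,30,control,1
s2,45,control,2
s3,70,case,5
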