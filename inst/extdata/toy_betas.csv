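probe_id,s1,s2,s3
cgA,0.50,0.80,0.95
cgB,0.40,0.30,0.10
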