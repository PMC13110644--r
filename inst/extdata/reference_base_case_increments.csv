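fracture_type,intervention,comparator,delta_cost,delta_qaly,icer_reported,nmb15_reported,nmb20_reported,nmb30_reported
MOF,S2,S1,-7.23,0.0028,-2568,49,64,92
MOF,S3,S1,8.81,0.0052,1678,70,96,149
HF,S2,S1,37.76,0.0012,32116,-20,-14,-2
HF,S3,S1,75.68,0.0015,49536,-53,-45,-30
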