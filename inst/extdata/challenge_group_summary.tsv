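group	rtle_mean	rtle_sd	n_assigned	n_phenotyped
G1	318.7	14.1	187	194
G2	394.9	23.2	196	202
G3	424.8	24.4	192	204
G4	424.9	34.2	195	200
G5	446.8	34.0	199	207
G6	407.4	30.3	196	202
G7	473.8	61.6	162	173
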