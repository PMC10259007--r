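trait	n	mean	sd	min	max
rTLE	1327	412.2	56.1	261.1	564.4
TLE	1327	0.0	1.0	-4.5	2.7
BW1	1327	87.4	12.2	51.5	139.1
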