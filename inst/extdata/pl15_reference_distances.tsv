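enzyme	base_res	acid_res	d_his_m	d_his_g	d_tyr_m	d_tyr_g	specificity
VBAly15A	H226	Y280	5.1	2.8	2.1	4.4	polyM
VSAly15A	H282	Y337	4.6	2.4	1.6	3.9	polyM
VSAly15B	H226	Y280	5.0	2.7	2.1	4.5	polyM
A1-IV	H296	Y350	4.5	2.3	1.6	4.0	polyM
A1-IV'	H240	Y293	4.0	1.8	1.6	1.8	polyM
Atu3025	H311	Y365	4.3	2.2	1.9	4.3	polyM
OalA	H226	Y280	4.8	2.6	2.3	4.7	polyM
AlyPB2	H214	Y268	4.6	2.3	2.0	4.6	polyM
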