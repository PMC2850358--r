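probe_id	Acc1	Acc2	Acc3	Acc4
S01	0	0	1	1
S02	0	0	0	1
S03	1	1	1	0
S04	1	1	0	0
S05	0	0	0	1
S06	0	1	0	0
S07	1	0	1	1
S08	1	1	1	0
S09	0	0	1	0
S10	0	1	0	0
S11	1	1	0	1
S12	1	0	1	1
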