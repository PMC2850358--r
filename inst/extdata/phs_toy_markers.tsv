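chrom	bp	cm
Chr1	0	0
Chr1	1000	0.4
Chr1	2000	0.8
Chr1	3000	1.2
Chr1	4000	1.6
Chr1	5000	2.0
Chr1	6000	2.4
Chr1	7000	2.8
Chr1	8000	3.2
Chr1	9000	3.6
Chr1	10000	4.0
Chr1	11000	4.4
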