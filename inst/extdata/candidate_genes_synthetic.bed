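chr2	115000000	116500000	DPP10	0	+
chr7	18100000	19000000	HDAC9	0	+
chr7	139400000	139700000	TBXAS1	0	+
chr5	15500000	16000000	FBXL7	0	-
chr17	38000000	38150000	GSDMB_ORMDL3	0	-
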