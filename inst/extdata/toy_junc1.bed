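track name=junctions description="toy group 1"
chrA	100	200	JUNC1	5	+
chrA	300	450	JUNC2	3	-
chrB	50	120	JUNC3	7	+
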