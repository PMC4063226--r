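track name=junctions description="toy group 2"
chrA	100	200	JUNC1	9	+
chrB	10	80	JUNC4	2	+
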