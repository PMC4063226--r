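@HD	VN:1.6	SO:unsorted
@SQ	SN:chrA	LN:1000
@SQ	SN:chrB	LN:500
r1	0	chrA	10	255	50M	*	0	0	*	*
r2	0	chrA	60	255	50M	*	0	0	*	*
r3	0	chrB	5	255	50M	*	0	0	*	*
r4	0	chrA	100	255	50M	*	0	0	*	*
r5	0	chrB	200	255	50M	*	0	0	*	*
r6	0	chrA	300	255	50M	*	0	0	*	*
r7	4	*	0	0	*	*	0	0	*	*
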