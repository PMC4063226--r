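chrA	1000	6	60	61
chrB	500	1030	60	61
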