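chrI	1900	2000	repeat_1
chrII	5000	6000	repeat_2
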