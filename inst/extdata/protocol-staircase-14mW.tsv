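segment	duration_ms	intensity
1	1000	14
2	150	14
3	300	0
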