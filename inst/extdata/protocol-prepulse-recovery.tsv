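segment	duration_ms	intensity
1	500	50
2	200	0
3	30	50
4	200	0
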