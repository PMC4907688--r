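segment	duration_ms	intensity
1	20	50
2	80	0
3	20	50
4	80	0
5	20	50
6	80	0
7	20	50
8	80	0
9	20	50
10	80	0
11	20	50
12	80	0
13	20	50
14	80	0
15	20	50
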