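plant	synth002_a1	synth002_a2	synth002_a3	synth002_a4	synth002_a5	synth002_a6	synth002_a7	synth002_a8	synth002_a9	synth002_a10	synth002_a11
synth002_p1	8	1	0	0	0	8	5	0	0	0	0
synth002_p2	4	6	0	0	0	0	1	0	0	2	0
synth002_p3	0	1	0	4	9	0	0	11	3	0	5
synth002_p4	0	0	0	8	2	0	0	2	0	0	0
synth002_p5	0	0	0	0	1	0	0	6	6	1	5
synth002_p6	1	0	3	0	0	9	5	0	0	0	0
synth002_p7	4	9	0	0	0	3	2	0	1	3	0
synth002_p8	0	7	0	0	0	0	0	1	5	8	7
synth002_p9	1	13	0	0	0	0	0	0	1	6	2
synth002_p10	0	11	0	0	0	0	0	0	1	4	1
synth002_p11	0	0	0	2	8	0	0	4	8	0	7
synth002_p12	0	0	0	9	11	0	0	5	3	0	2
synth002_p13	0	0	0	7	3	0	0	0	0	0	0
synth002_p14	9	0	0	0	0	5	6	0	0	0	0
synth002_p15	0	9	0	0	0	0	0	0	1	6	4
synth002_p16	0	0	0	6	6	0	0	3	4	0	3
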