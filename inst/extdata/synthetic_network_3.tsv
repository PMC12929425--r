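plant	synth003_a1	synth003_a2	synth003_a3	synth003_a4	synth003_a5	synth003_a6	synth003_a7	synth003_a8	synth003_a9	synth003_a10	synth003_a11	synth003_a12	synth003_a13	synth003_a14	synth003_a15	synth003_a16	synth003_a17	synth003_a18	synth003_a19	synth003_a20	synth003_a21
synth003_p1	3	0	5	3	12	0	0	0	5	0	10	0	7	0	0	1	0	0	4	7	0
synth003_p2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	6	0	1	4	0	0	6
synth003_p3	1	5	1	2	0	2	7	7	2	0	0	9	0	12	0	8	0	0	3	0	0
synth003_p4	4	0	10	9	11	0	0	0	11	0	9	0	5	0	0	1	0	0	3	6	0
synth003_p5	2	5	4	1	1	0	3	2	10	0	2	5	3	5	0	7	0	0	6	0	0
synth003_p6	0	2	0	0	0	8	6	2	0	6	0	4	0	6	0	5	10	1	0	0	2
synth003_p7	10	4	4	5	5	0	5	2	4	0	10	3	2	5	0	4	1	0	6	0	0
synth003_p8	5	1	13	2	7	0	0	0	4	0	7	0	3	0	0	0	0	0	2	2	0
synth003_p9	0	0	0	0	0	6	0	0	0	6	0	0	0	0	2	0	6	9	0	0	8
synth003_p10	10	2	5	8	4	0	0	0	13	0	11	1	3	0	0	0	0	0	4	1	0
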