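plant	synth001_a1	synth001_a2	synth001_a3	synth001_a4	synth001_a5	synth001_a6	synth001_a7	synth001_a8	synth001_a9	synth001_a10	synth001_a11	synth001_a12	synth001_a13	synth001_a14	synth001_a15	synth001_a16	synth001_a17	synth001_a18	synth001_a19	synth001_a20	synth001_a21	synth001_a22	synth001_a23	synth001_a24	synth001_a25	synth001_a26	synth001_a27	synth001_a28	synth001_a29	synth001_a30	synth001_a31	synth001_a32
synth001_p1	0	3	0	8	11	7	0	0	0	0	0	10	0	3	0	1	1	0	0	0	0	6	0	0	0	0	2	0	0	0	0	0
synth001_p2	8	0	0	0	0	0	0	2	3	2	4	0	5	0	0	0	0	0	0	2	2	0	6	0	5	10	0	7	0	3	3	0
synth001_p3	6	0	0	0	0	0	0	7	5	3	2	0	1	0	0	0	0	0	0	10	0	0	4	0	9	3	0	5	0	0	7	0
synth001_p4	9	0	0	0	0	0	0	6	10	6	0	0	2	0	0	0	0	0	0	7	0	0	2	0	3	4	0	3	0	1	4	0
synth001_p5	6	0	0	0	0	0	0	3	9	0	1	0	1	0	0	1	0	0	0	0	2	0	10	0	8	7	0	9	0	4	3	0
synth001_p6	1	8	0	9	12	0	0	0	0	0	1	4	0	2	3	0	0	0	0	0	1	2	0	0	0	0	0	0	0	1	0	1
synth001_p7	1	2	0	1	0	0	0	0	0	0	7	0	13	1	4	7	0	0	0	1	12	0	8	0	2	4	0	4	0	9	0	0
synth001_p8	0	4	0	3	12	1	0	0	0	0	0	3	0	5	2	3	1	0	0	0	0	2	0	0	0	0	0	0	0	0	0	0
synth001_p9	12	0	0	0	0	0	0	1	9	3	5	0	10	0	3	2	0	0	0	0	3	0	14	0	3	8	0	8	0	6	0	0
synth001_p10	2	5	0	2	2	0	0	0	0	0	14	0	5	11	12	3	0	0	0	0	6	0	5	0	0	0	0	2	0	3	0	0
synth001_p11	4	0	0	0	0	0	0	2	3	2	4	0	2	0	2	3	0	0	0	2	2	0	7	0	7	3	0	7	0	3	2	0
synth001_p12	5	0	0	0	0	0	0	2	10	4	7	0	7	0	1	3	0	0	0	1	2	0	6	0	8	8	0	10	0	12	3	0
synth001_p13	10	0	0	0	0	0	0	0	4	4	4	0	3	0	1	1	0	0	0	2	4	0	6	0	7	7	0	8	0	7	6	0
synth001_p14	0	5	0	4	8	0	1	0	0	0	1	2	0	6	1	2	2	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0
synth001_p15	0	7	0	5	2	0	0	0	0	0	2	0	1	10	4	3	0	0	0	0	5	1	0	0	0	1	0	0	0	6	0	0
synth001_p16	0	7	0	10	3	0	0	0	0	0	2	2	2	11	3	2	0	0	0	0	1	0	0	0	0	0	0	0	0	2	0	0
synth001_p17	0	0	4	0	0	11	5	0	0	0	0	2	0	0	0	0	4	7	6	0	0	7	0	2	0	0	7	0	6	0	0	7
synth001_p18	0	0	8	0	0	7	9	0	0	0	0	3	0	0	0	0	0	5	1	0	0	5	0	6	0	0	5	0	8	0	0	6
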