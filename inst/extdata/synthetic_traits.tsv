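species	ploidy	mating	restrictiveness
synth001_p1	unknown	self_compatible	unknown
synth001_p2	diploid	unknown	low
synth001_p3	unknown	unknown	low
synth001_p4	polyploid	unknown	unrestrictive
synth001_p5	polyploid	self_incompatible	unrestrictive
synth001_p6	diploid	unknown	unknown
synth001_p7	diploid	unknown	unknown
synth001_p8	unknown	self_compatible	unknown
synth001_p9	polyploid	self_incompatible	unknown
synth001_p10	unknown	unknown	unrestrictive
synth001_p11	unknown	unknown	moderate
synth001_p12	polyploid	self_incompatible	low
synth001_p13	polyploid	unknown	moderate
synth001_p14	diploid	unknown	moderate
synth001_p15	diploid	unknown	unknown
synth001_p16	unknown	unknown	unrestrictive
synth001_p17	unknown	unknown	high
synth001_p18	unknown	unknown	unrestrictive
synth002_p1	diploid	unknown	unknown
synth002_p2	polyploid	unknown	unrestrictive
synth002_p3	diploid	self_compatible	low
synth002_p4	unknown	unknown	unrestrictive
synth002_p5	polyploid	self_compatible	unrestrictive
synth002_p6	unknown	unknown	low
synth002_p7	unknown	unknown	high
synth002_p8	diploid	unknown	unrestrictive
synth002_p9	polyploid	unknown	high
synth002_p10	diploid	self_compatible	unknown
synth002_p11	polyploid	unknown	unknown
synth002_p12	diploid	unknown	low
synth002_p13	diploid	unknown	high
synth002_p14	unknown	unknown	moderate
synth002_p15	diploid	unknown	high
synth002_p16	diploid	unknown	moderate
synth003_p1	diploid	unknown	unrestrictive
synth003_p2	polyploid	unknown	unknown
synth003_p3	polyploid	unknown	low
synth003_p4	diploid	unknown	unknown
synth003_p5	polyploid	unknown	unknown
synth003_p6	diploid	unknown	low
synth003_p7	polyploid	unknown	high
synth003_p8	polyploid	self_incompatible	unrestrictive
synth003_p9	unknown	self_incompatible	unrestrictive
synth003_p10	polyploid	unknown	unknown
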