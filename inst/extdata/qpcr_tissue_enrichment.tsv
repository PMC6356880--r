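mirna	tissue	ddct	enrichment
ssa-miR-9a-5p	brain	-11.13	2241
ssa-miR-9b-3p	brain	-10.21	1184
ssa-miR-96-5p	brain	-5.18	36
ssa-miR-129-5p	brain	-3.56	12
ssa-miR-132-5p	brain	-7.46	176
ssa-miR-135c-5p	brain	-7.05	133
ssa-miR-153a-3p	brain	-10.08	1082
ssa-miR-212ab-3p	brain	-7.29	156
ssa-miR-219a-3p	brain	-7.66	202
ssa-miR-723-5p	brain	-6.83	114
ssa-miR-734a-3p	brain	-4.68	26
ssa-miR-122-5p	liver	-12.3	5043
ssa-miR-8163-3p	liver	-8.6	388
ssa-miR-192a-5p	liver	-7.96	249
ssa-miR-499a-5p	heart	-9.7	832
ssa-miR-736-3p	heart	-14.7	26616
ssa-miR-192a-5p	intestine	-11.9	3822
ssa-miR-459-5p	intestine	-12.9	7643
ssa-miR-194b-5p	intestine	-10.8	1783
ssa-miR-140-3p	gills	-3.7	13
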