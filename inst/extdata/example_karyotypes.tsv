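species	2n	NF1	polyploid	meiosis_only	sex_difference	female_2n	female_NF1
Astyanax_demo1	48	72	0	0	0	NA	NA
Astyanax_demo1	48	74	0	0	0	NA	NA
Danio_demo2	50	78	0	0	0	NA	NA
Oryzias_demo3	48	48	0	0	0	NA	NA
Poecilia_demo4	46	92	0	0	1	46	90
Salmo_demo5	80	100	1	0	0	NA	NA
Cobitis_demo6	49	66	0	0	0	NA	NA
Barbus_demo7	48	96	0	1	0	NA	NA
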