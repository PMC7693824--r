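name	parent	start	end	species	note
ocellatin-S(1-16)	ocellatin-S	1	16	Leptodactylus syphax
ocellatin-S(1-22)	ocellatin-S	1	22	Leptodactylus syphax
ocellatin-S(1-23)	ocellatin-S	1	23	Leptodactylus syphax
ocellatin-S(1-24)	ocellatin-S	1	24	Leptodactylus syphax
ocellatin-S(16-25)	ocellatin-S	16	25	Leptodactylus syphax
ocellatin-K1(1-16)	ocellatin-K1	1	16	Leptodactylus vastus
ocellatin-K1(1-21)	ocellatin-K1	1	21	Leptodactylus vastus
ocellatin-F(1-22)	ocellatin-F	1	22	Leptodactylus fallax	also reported as ocellatin-LB1 in L. labyrinticus
ocellatin-F(1-23)	ocellatin-F	1	23	Leptodactylus labyrinticus	also reported as ocellatin-LB2 / Des-Lys24-Leu25-ocellatin-F1
ocellatin-L1(1-22)	ocellatin-L1	1	22	Leptodactylus laticeps
ocellatin-1(1-16)	ocellatin-1	1	16	Leptodactylus latrans
ocellatin-2(1-15)	ocellatin-2	1	15	Leptodactylus latrans
ocellatin-3(1-15)	ocellatin-3	1	15	Leptodactylus latrans
ocellatin-5(1-14)	ocellatin-5	1	14	Leptodactylus latrans
ocellatin-6(1-18)	ocellatin-6	1	18	Leptodactylus latrans
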