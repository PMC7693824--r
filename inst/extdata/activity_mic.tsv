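name	ecoli_ug_ml	ecoli_um	saureus_ug_ml	saureus_um	note
ocellatin-1	*	*	NT	NT
ocellatin-2	*	*	NT	NT
ocellatin-3	*	*	NT	NT
ocellatin-4	145	64	145	64
ocellatin-5	64	28	128	56
ocellatin-6	32	14	64	28
ocellatin-F	106	40	>60	>160	order-of-magnitude discrepancy between authors
ocellatin-F1	1060	397	293	110	order-of-magnitude discrepancy between authors
ocellatin-P	64	25	508	200
ocellatin-PT1	800	300	>800	>300
ocellatin-PT2	>800	>310	>800	>310
ocellatin-PT3	800	320	>800	>320
ocellatin-PT4	200	80	>800	>310
ocellatin-PT5	800	300	>800	>300
ocellatin-PT6	400	120	>800	>240
ocellatin-PT7	200	60	800	245
ocellatin-PT8	200	60	800	245
ocellatin-L1	128	50	512	>200
ocellatin-L2	I	I	I	I
ocellatin-S	NT	NT	I	I
ocellatin-V1	512	>200	512	>200
ocellatin-V2	514	>200	514	>200
ocellatin-V3	I	I	I	I
ocellatin-K1	NI	NI	NI	NI
P3-Lla-2085	31	15	31	15
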