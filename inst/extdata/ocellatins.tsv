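name	species	sequence	amidated	group	printed_mw	printed_charge	source
ocellatin-F	Leptodactylus fallax	GVVDILKGAAKDIAGHLASKVMNKL	TRUE	family_member			fallaxin
ocellatin-K1	Leptodactylus knudseni	GVVDILKGAAKDLAGHLASKVMNKI	TRUE	family_member
ocellatin-L1	Leptodactylus laticeps	GVVDILKGAAKDLAGHLATKVMNKL	TRUE	family_member			laticeptin
ocellatin-L2	Leptodactylus laticeps	GVVDILKGAAKDLAGHLATKVMDKL	TRUE	family_member
ocellatin-S	Leptodactylus syphax	GVLDILKGAAKDLAGHVATKVINKI	TRUE	family_member			syphaxin
ocellatin-P	Leptodactylus pentadactylus	GLLDTLKGAAKNVVGSLASKVMEKL	TRUE	family_member			pentadactylin
ocellatin-7	Leptodactylus latrans	GVVDILKDTGKKLLSHLMEKI	TRUE	family_member	2336.87	2	this work
ocellatin-8	Leptodactylus latrans	GVVDILKDTGKKLLSHLMEKV	TRUE	family_member	2322.84	2	this work
ocellatin-9	Leptodactylus latrans	GVLDIFKDTGKKLLSHLMEKV	TRUE	family_member	2370.89	1	this work
ocellatin-5	Leptodactylus latrans	AVLDILKDVGKGLLSHFMEKV	TRUE	family_member	2311.82	1
ocellatin-10	Leptodactylus latrans	GLLDFLKAAGKGLVSNLIEKV	TRUE	family_member	2184.65	2	this work
ocellatin-6	Leptodactylus latrans	AVLDFIKAAGKGLVTNIMEKVG	TRUE	family_member	2273.77	2
ocellatin-PT6	Leptodactylus pustullatus	GVFDIIKGAGKQLIAHAMEKIAEKVGLNKDGN	FALSE	family_member
ocellatin-PT8	Leptodactylus pustullatus	GVFDIIKGAGKQLIARAMGKIAEKVGLNKDGN	FALSE	family_member
ocellatin-PT7	Leptodactylus pustullatus	GVFDIIKGAGKQLIAHAMGKIAEKVGLNKDGN	FALSE	family_member
ocellatin-PT4	Leptodactylus pustullatus	GVFDIIKGAGKQLIAHAMGKIAEKV	TRUE	family_member
ocellatin-PT1	Leptodactylus pustullatus	GVFDIIKDAGKQLVAHAMGKIAEKV	TRUE	family_member
ocellatin-PT5	Leptodactylus pustullatus	GVFDIIKDAGRQLVAHAMGKIAEKV	TRUE	family_member
ocellatin-PT2	Leptodactylus pustullatus	GVFDIIKDAGKQLVAHATGKIAEKV	TRUE	family_member
ocellatin-PT3	Leptodactylus pustullatus	GVIDIIKGAGKDLIAHAIGKLAEKV	TRUE	family_member
ocellatin-V1	Leptodactylus validus	GVVDILKGAGKDLLAHALSKLSEKV	TRUE	family_member
ocellatin-V3	Leptodactylus validus	GVLDILTGAGKDLLAHALSKLSEKV	TRUE	family_member
ocellatin-V2	Leptodactylus validus	GVLDILKGAGKDLLAHALSKISEKV	TRUE	family_member
ocellatin-1	Leptodactylus latrans	GVVDILKGAGKDLLAHLVGKISEKV	TRUE	family_member
ocellatin-11	Leptodactylus latrans	GVLDIFKDAAKQILAHAAEKI	TRUE	family_member	2250.67	1	this work
ocellatin-2	Leptodactylus latrans	GVLDIFKDAAKQILAHAAEQI	TRUE	family_member	2250.63	0
ocellatin-4	Leptodactylus latrans	GLLDFVTGVGKDIFAQLIKQI	TRUE	family_member
ocellatin-3	Leptodactylus latrans	GVLDILKNAAKNILAHAAEQI	TRUE	family_member
P3-Lla-2085	synthetic (hybrid analog)	GLLDFLKAAGKGLVSNLLEK	TRUE	analog	2085.52	2	hybrid of ocellatin-5* N-terminus and P2-Ll-1298
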