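clade	parent	mean_age	hpd_upper	hpd_lower	stem_length	posterior
L5'7	L2'3'4'5'6'7	99960	111909	87700	11833	1.000
L7	L5'7	91476	104169	78614	8485	1.000
L7a	L7	79365	93730	65749	12111	1.000
L7a*	L7a	0	NA	NA	79365	NA
L7a1	L7a	16333	23350	9683	63032	1.000
L7b	L7	54409	67795	41528	37067	1.000
L7b1	L7b	22081	30890	14007	32328	1.000
L7b2	L7b	26435	36356	16851	27974	1.000
L5	L5'7	90636	103698	77497	9324	1.000
L5a	L5	32665	39890	25777	57972	1.000
L5a1	L5a	22045	27833	16613	10619	1.000
L5a2	L5a	28133	34677	21847	4532	0.998
L5b	L5	39969	51726	28445	50667	1.000
L5b1	L5b	22885	30103	16074	17085	1.000
L5b*	L5b	0	NA	NA	39969	NA
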