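motif	condor_cnes	shark_cnes	vista_eb_all	vista_eb_hb_ba_cn	vista_eb_hb	cnebrowser_all	cnebrowser_hb
TGATNNATKR	562	666	609	161	131	17	7
TGTANNATKR	171	188	388	65	52	12	3
GTATNNATKR	150	168	279	54	39	9	2
GTTANNATKR	150	178	325	79	65	8	2
TTGANNATKR	200	245	447	80	64	9	1
TTAGNNATKR	167	238	398	74	55	7	0
ATGTNNATKR	259	297	452	86	72	20	1
ATTGNNATKR	233	297	436	74	61	20	2
AGTTNNATKR	215	254	431	85	68	9	0
TAGTNNATKR	147	154	297	54	42	10	4
TATGNNATKR	176	198	365	74	60	10	3
GATTNNATKR	274	315	419	97	74	11	0
TGATNNTAKR	106	143	314	65	50	6	1
TGTANNTAKR	142	151	421	82	60	14	1
GTATNNTAKR	59	73	195	41	34	1	0
GTTANNTAKR	105	108	253	50	33	5	0
TTGANNTAKR	162	205	385	72	62	10	0
TTAGNNTAKR	73	97	235	41	31	0	0
ATGTNNTAKR	103	124	376	64	55	3	0
ATTGNNTAKR	136	158	305	57	42	6	1
AGTTNNTAKR	85	121	320	64	50	5	1
TAGTNNTAKR	66	69	198	37	27	1	0
TATGNNTAKR	84	94	345	80	62	5	1
GATTNNTAKR	144	177	292	58	42	2	0
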