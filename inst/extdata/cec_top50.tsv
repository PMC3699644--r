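gene_id	cec_young	cec_old	cec_culture	stroma	fold_young_stroma	fold_young_old
ENO1	35,947	25,205	19,318	14,237	2.5	1.4
GAPDH	8,083	6,649	6,598	2,401	3.4	1.2
CA3	7,804	6,267	166	207	37.7	1.2
MYOC	6,780	10,193	8,272	915	7.4	0.7
SLC2A1	5,598	4,593	3,491	1,921	2.9	1.2
PTGDS	5,547	6,416	184	2,522	2.2	0.9
IER3	5,311	5,829	1,353	1,779	3.0	0.9
ATP5B	4,762	4,413	3,095	1,330	3.6	1.1
TSPAN6	3,860	3,668	1,617	137	28.2	1.1
MGP	3,598	3,419	3,813	345	10.4	1.1
ALDOA	3,421	2,425	2,812	1,557	2.2	1.4
HERPUD1	3,138	2,367	649	862	3.6	1.3
ATP1A1	2,616	1,627	858	368	7.1	1.6
ATP5A1	2,586	1,737	1,640	979	2.6	1.5
GNAS	2,574	2,550	2,112	1,165	2.2	1.0
PGK1	2,469	2,878	2,239	906	2.7	0.9
CA12	2,322	1,756	1,721	123	18.8	1.3
SLC4A11	2,312	2,940	366	90	25.7	0.8
COX4I1	2,265	2,232	1,011	815	2.8	1.0
TSC22D1	2,070	2,038	2,978	865	2.4	1.0
SCD	1,928	1,108	252	54	35.8	1.7
COL8A2	1,821	1,743	859	107	17.0	1.0
PFKP	1,577	1,220	433	158	10.0	1.3
ADM	1,287	1,712	314	491	2.6	0.8
NDUFB8	1,167	997	664	553	2.1	1.2
SFRP1	1,134	1,592	38	125	9.0	0.7
EIF3K	1,070	1,292	648	385	2.8	0.8
RPL15	1,063	1,033	674	451	2.4	1.0
GHITM	1,042	1,081	747	224	4.6	1.0
C5orf62	970	971	472	57	17.1	1.0
AKR1C1	953	729	678	180	5.3	1.3
AKR1B1	892	777	988	229	3.9	1.1
LAMB1	890	825	753	73	12.2	1.1
ID3	834	1,744	1,337	133	6.3	0.5
TUBA4A	831	934	191	390	2.1	0.9
TUFM	767	561	496	302	2.5	1.4
CD83	750	678	72	81	9.3	1.1
SULF2	749	470	791	29	25.5	1.6
NPC2	744	488	1,963	366	2.0	1.5
TMEM66	632	517	844	321	2.0	1.2
MIF	628	773	450	314	2.0	0.8
RGS5	608	930	139	22	27.4	0.7
C6orf48	603	589	652	290	2.1	1.0
NDUFB9	589	869	405	234	2.5	0.7
NDUFB10	583	323	235	98	6.0	1.8
VDAC3	582	393	299	250	2.3	1.5
P4HA2	572	286	603	104	5.5	2.0
ITGB5	571	613	1,333	137	4.2	0.9
NDUFV1	570	554	104	77	7.4	1.0
GRHPR	569	667	768	123	4.6	0.9
ANKH	569	444	687	123	4.6	1.3
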