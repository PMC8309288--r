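##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-24
GsRf_TT8_1	fleshmark	gene	1	3430	.	+	.	tss_pos=1001;atg_pos=1021
GsRf_TT8_1	fleshmark	promoter	1	1000	.	+	.	feature_index=1;
GsRf_TT8_1	fleshmark	exon	1001	1240	.	+	.	feature_index=1;
GsRf_TT8_1	fleshmark	intron	1241	1390	.	+	.	feature_index=1;
GsRf_TT8_1	fleshmark	exon	1391	1540	.	+	.	feature_index=2;
GsRf_TT8_1	fleshmark	intron	1541	1890	.	+	.	feature_index=2;
GsRf_TT8_1	fleshmark	exon	1891	2010	.	+	.	feature_index=3;
GsRf_TT8_1	fleshmark	intron	2011	2160	.	+	.	feature_index=3;
GsRf_TT8_1	fleshmark	exon	2161	2270	.	+	.	feature_index=4;
GsRf_TT8_1	fleshmark	intron	2271	2420	.	+	.	feature_index=4;
GsRf_TT8_1	fleshmark	exon	2421	2580	.	+	.	feature_index=5;
GsRf_TT8_1	fleshmark	intron	2581	2780	.	+	.	feature_index=5;
GsRf_TT8_1	fleshmark	exon	2781	3060	.	+	.	feature_index=6;
GsRf_TT8_1	fleshmark	intron	3061	3210	.	+	.	feature_index=6;
GsRf_TT8_1	fleshmark	exon	3211	3430	.	+	.	feature_index=7;
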