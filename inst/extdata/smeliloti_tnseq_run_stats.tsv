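replicate	condition	total_reads	pct_no_tn	reads_too_short	reads_used	alignment_rate	nf	norm_total	reads_per_site
1	input	21652251	5.20	36631	20489022	80.40	0.844	18274500	129
1	nontreated	20304098	6.94	29769	18865247	80.09	0.920	18679770	119
1	NCR247	20121669	8.14	34245	18450409	80.80	0.921	18532057	116
1	PMB	18401067	7.18	30931	17049767	80.66	0.998	18364265	107
2	input	20153000	12.72	30042	17560139	81.50	0.943	19004279	111
2	nontreated	22731094	7.97	33510	20885738	80.66	0.811	18434917	132
2	NCR247	18798923	7.77	30051	17307732	80.11	1.000	18798923	109
2	PMB	18906038	8.75	28138	17224367	79.88	0.994	18792602	109
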