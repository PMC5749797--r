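motif_id	name	variants	p_eriq	rank_eriq	p_senescence	rank_senescence	fold_published	flag_sam	flag_pca
M00516	V$E2F_03	MA0469.1 (E2F3)	0.0002	11	0.5325	86	2200	TRUE	TRUE
MA0506.1	NRF1		0.0003	30	0.6401	198	2070	TRUE	FALSE
MA0006.1	Ahr::Arnt	M00237 (V$AHRARNT_02)	0.0002	23	0.3247	125	2020	TRUE	TRUE
M00245	V$EGR3_01	MA0732.1 (EGR3)	0.0002	10	0.2649	49	1460	TRUE	TRUE
M00185	V$NFY_Q6	M00287 (V$NFY_01); M00288 (F$HAP234_01)	0.0011	20	0.9841	93	923	TRUE	TRUE
M00246	V$EGR2_01		0.0005	17	0.2694	50	554	TRUE	TRUE
M00005	V$AP4_01		0.0204	34	0.8207	115	40.2	FALSE	TRUE
MA0018.1	CREB1	M00114 (V$TAXCREB_01)	0.0498	85	0.8563	258	17.1	TRUE	TRUE
MA0106.2	TP53		0.9909	279	0.0002	1	4260	TRUE	FALSE
MA0914.1	ISL2		0.9058	225	0.0117	7	77.6	FALSE	TRUE
MA0474.1	Erg		0.9082	229	0.0192	15	47.3	TRUE	FALSE
M00280	V$RFX1_01		0.6231	90	0.0189	4	32.9	FALSE	TRUE
MA0479.1	FOXH1		0.9602	252	0.0321	23	29.9	TRUE	TRUE
MA0861.1	TP73		0.8834	216	0.0479	30	18.4	FALSE	TRUE
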