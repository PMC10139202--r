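matrix_id	tf_name	relative_score	sequence_id	start	end	strand	site
MA1535.1	NR2C1	0.98463	DEAluS	8	16	+	TGAGGTCAG
MA1535.1	NR2C1	0.81979	DEAluS	16	24	+	GGAGTTCAA
MA0018.2	CREB1	0.9342	DEAluS	8	15	+	TGAGGTCA
MA0018.2	CREB1	0.86424	DEAluS	8	15	-	TGACCTCA
MA0018.4	CREB1	0.85236	DEAluS	5	17	+	ACTTGAGGTCAGG
MA0018.3	CREB1	0.84877	DEAluS	6	17	+	CTTGAGGTCAGG
MA0018.3	CREB1	0.84877	DEAluS	6	17	-	CCTGACCTCAAG
MA0684.2	RUNX3	0.92281	DEAluS	5	16	-	CTGACCTCAAGT
MA0684.1	RUNX3	0.80775	DEAluS	6	15	-	TGACCTCAAG
MA1534.1	NR1I3	0.92153	DEAluS	16	24	-	TTGAACTCC
MA1534.1	NR1I3	0.85571	DEAluS	8	16	-	CTGACCTCA
MA0017.2	NR2F1	0.91535	DEAluS	7	19	+	TTGAGGTCAGGAG
MA0693.2	VDR	0.90919	DEAluS	16	23	+	GGAGTTCA
MA0693.2	VDR	0.89944	DEAluS	8	15	+	TGAGGTCA
MA0160.1	NR4A2	0.90185	DEAluS	9	16	+	GAGGTCAG
MA0160.1	NR4A2	0.82039	DEAluS	23	30	+	AAGACCAG
MA0160.2	NR4A2	0.80399	DEAluS	6	15	+	CTTGAGGTCA
MA0672.1	NKX2-3	0.89714	DEAluS	2	11	+	ATCACTTGAG
MA1111.1	NR2F2	0.87947	DEAluS	7	17	+	TTGAGGTCAGG
MA1587.1	ZNF135	0.87829	DEAluS	13	26	-	TCTTGAACTCCTGA
MA1531.1	NR1D1	0.87418	DEAluS	10	24	+	AGGTCAGGAGTTCAA
MA0909.1	HOXD13	0.86899	DEAluS	58	67	+	CTACTAAAAA
MA0093.2	USF1	0.8659	DEAluS	1	11	-	CTCAAGTGATT
MA0093.1	USF1	0.82827	DEAluS	3	9	-	CAAGTGA
MA0093.1	USF1	0.8266	DEAluS	4	10	+	CACTTGA
MA0093.2	USF1	0.82641	DEAluS	11	21	-	AACTCCTGACC
MA1532.1	NR1D2	0.86489	DEAluS	10	24	+	AGGTCAGGAGTTCAA
MA1532.2	NR1D2	0.84991	DEAluS	9	23	+	GAGGTCAGGAGTTCA
MA0871.1	TFEC	0.86383	DEAluS	2	11	+	ATCACTTGAG
MA0871.1	TFEC	0.85006	DEAluS	2	11	-	CTCAAGTGAT
MA0871.2	TFEC	0.8011	DEAluS	1	11	-	CTCAAGTGATT
MA0154.2	EBF1	0.8628	DEAluS	3	13	-	ACCTCAAGTGA
MA0154.2	EBF1	0.84908	DEAluS	2	12	+	ATCACTTGAGG
MA0154.1	EBF1	0.84704	DEAluS	3	12	-	CCTCAAGTGA
MA1632.1	ATF2	0.86072	DEAluS	5	17	+	ACTTGAGGTCAGG
MA0901.1	HOXB13	0.85918	DEAluS	58	67	+	CTACTAAAAA
MA0158.1	HOXA5	0.85801	DEAluS	4	11	-	CTCAAGTG
MA0158.1	HOXA5	0.82169	DEAluS	14	21	+	CAGGAGTT
MA0650.1	HOXA13	0.85681	DEAluS	58	67	+	CTACTAAAAA
MA1649.1	ZBTB12	0.85649	DEAluS	17	27	-	GTCTTGAACTC
MA0058.1	MAX	0.85576	DEAluS	1	10	+	AATCACTTGA
MA0831.2	TFE3	0.85542	DEAluS	2	9	-	CAAGTGAT
MA0831.1	TFE3	0.83464	DEAluS	12	21	-	AACTCCTGAC
MA0831.2	TFE3	0.83003	DEAluS	12	19	-	CTCCTGAC
MA0831.3	TFE3	0.81998	DEAluS	2	11	-	CTCAAGTGAT
MA0831.3	TFE3	0.81998	DEAluS	2	11	+	ATCACTTGAG
MA0511.2	RUNX2	0.85286	DEAluS	7	15	-	TGACCTCAA
MA0899.1	HOXA10	0.85	DEAluS	57	67	+	TCTACTAAAAA
MA0071.1	RORA	0.84916	DEAluS	6	15	+	CTTGAGGTCA
MA0828.1	SREBF2	0.84851	DEAluS	2	11	-	CTCAAGTGAT
MA0828.1	SREBF2	0.83605	DEAluS	2	11	+	ATCACTTGAG
MA0828.1	SREBF2	0.81121	DEAluS	12	21	-	AACTCCTGAC
MA0036.1	GATA2	0.84608	DEAluS	1	5	-	TGATT
MA0464.2	BHLHE40	0.84575	DEAluS	2	11	-	CTCAAGTGAT
MA0464.2	BHLHE40	0.82176	DEAluS	2	11	+	ATCACTTGAG
MA0745.1	SNAI2	0.84549	DEAluS	3	11	-	CTCAAGTGA
MA0745.1	SNAI2	0.8117	DEAluS	24	32	-	GGCTGGTCT
MA0636.1	BHLHE41	0.84511	DEAluS	2	11	+	ATCACTTGAG
MA0636.1	BHLHE41	0.83972	DEAluS	2	11	-	CTCAAGTGAT
MA0729.1	RARA	0.83842	DEAluS	9	26	+	GAGGTCAGGAGTTCAAGA
MA1112.1	NR4A1	0.83437	DEAluS	7	16	+	TTGAGGTCAG
MA1902.1	NFkb	0.83413	DEAluS	37	58	+	CAACATGGTGAAACCCCGTCTC
MA0913.2	HOXD9	0.8321	DEAluS	58	67	+	CTACTAAAAA
MA0122.2	NKX3-2	0.83136	DEAluS	2	10	+	ATCACTTGA
MA1655.1	ZNF341	0.8311	DEAluS	23	34	+	AAGACCAGCCTG
MA0833.2	ATF4	0.83022	DEAluS	39	52	+	ACATGGTGAAACCC
MA1656.1	ZNF449	0.82761	DEAluS	21	34	+	TCAAGACCAGCCTG
MA1963.1	SATB1	0.82693	DEAluS	55	67	+	TCTCTACTAAAAA
MA1464.1	ARNT2	0.82595	DEAluS	2	11	+	ATCACTTGAG
MA1558.1	SNAI1	0.82506	DEAluS	2	11	-	CTCAAGTGAT
MA1558.1	SNAI1	0.80459	DEAluS	12	21	+	GTCAGGAGTT
MA0100.3	MYB	0.8245	DEAluS	2	11	-	CTCAAGTGAT
MA1505.1	HOXC8	0.82307	DEAluS	3	10	-	TCAAGTGA
MA0664.1	MLXIPL	0.8215	DEAluS	2	11	-	CTCAAGTGAT
MA0664.1	MLXIPL	0.80617	DEAluS	2	11	+	ATCACTTGAG
MA0002.1	RUNX1	0.82024	DEAluS	5	15	+	ACTTGAGGTCA
MA0842.1	NRL	0.81706	DEAluS	12	22	-	GAACTCCTGAC
MA0663.1	MLX	0.81579	DEAluS	2	11	-	CTCAAGTGAT
MA0525.1	TP63	0.81575	DEAluS	19	38	+	GTTCAAGACCAGCCTGGCCA
MA0007.2	AR	0.81533	DEAluS	23	37	+	AAGACCAGCCTGGCC
MA0063.2	NKX2-5	0.81522	DEAluS	2	12	+	ATCACTTGAGG
MA0063.2	NKX2-5	0.80188	DEAluS	57	67	+	TCTACTAAAAA
MA1563.1	SOX18	0.81158	DEAluS	39	46	-	CACCATGT
MA1496.1	HOXA4	0.81143	DEAluS	12	19	+	GTCAGGAG
MA1496.1	HOXA4	0.8107	DEAluS	41	48	+	ATGGTGAA
MA1151.1	RORC	0.81043	DEAluS	4	15	+	CACTTGAGGTCA
MA0692.1	TFEB	0.80964	DEAluS	2	11	-	CTCAAGTGAT
MA0692.1	TFEB	0.80394	DEAluS	12	21	-	AACTCCTGAC
MA0692.1	TFEB	0.80321	DEAluS	2	11	+	ATCACTTGAG
MA1570.1	TFAP4	0.80899	DEAluS	36	45	-	ACCATGTTGG
MA1570.1	TFAP4	0.80622	DEAluS	36	45	+	CCAACATGGT
MA0763.1	ETV3	0.80785	DEAluS	4	13	-	ACCTCAAGTG
MA1498.1	HOXA7	0.80731	DEAluS	20	27	-	GTCTTGAA
MA1540.1	NR5A1	0.80706	DEAluS	6	16	+	CTTGAGGTCAG
MA1540.1	NR5A1	0.8025	DEAluS	20	30	+	TTCAAGACCAG
MA0492.1	JUND	0.80596	DEAluS	3	17	+	TCACTTGAGGTCAGG
MA0523.1	TCF7L2	0.805	DEAluS	16	29	+	GGAGTTCAAGACCA
MA0819.2	CLOCK	0.8047	DEAluS	37	46	-	CACCATGTTG
MA0522.2	TCF3	0.8032	DEAluS	12	21	-	AACTCCTGAC
MA0820.1	FIGLA	0.80267	DEAluS	12	21	-	AACTCCTGAC
MA0488.1	JUN	0.80233	DEAluS	4	16	+	CACTTGAGGTCAG
MA1549.1	POU6F1	0.80132	DEAluS	12	21	+	GTCAGGAGTT
MA1541.1	NR6A1	0.8013	DEAluS	14	30	+	CAGGAGTTCAAGACCAG
MA0827.1	OLIG3	0.80016	DEAluS	36	45	+	CCAACATGGT
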