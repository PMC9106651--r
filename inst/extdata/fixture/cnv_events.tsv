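sample	kind	event	chrom	start	end	copy_number	size_bp	syndrome	class	critical_genes
P79	aneuploidy	+18	18	NA	NA	3	NA	Trisomy 18	P	
P102	aneuploidy	+18	18	NA	NA	3	NA	Trisomy 18	P	
P240	aneuploidy	+18	18	NA	NA	3	NA	Trisomy 18	P	
P103	aneuploidy	+18	18	NA	NA	3	NA	Trisomy 18	P	
P350	aneuploidy	+18	18	NA	NA	3	NA	Trisomy 18	P	
P482	aneuploidy	+18	18	NA	NA	3	NA	Trisomy 18	P	
P155	aneuploidy	+13	13	NA	NA	3	NA	Trisomy 13	P	
P351	aneuploidy	+13	13	NA	NA	3	NA	Trisomy 13	P	
P438	aneuploidy	+13	13	NA	NA	3	NA	Trisomy 13	P	
P871	aneuploidy	+13	13	NA	NA	3	NA	Trisomy 13	P	
P747	aneuploidy	+13	13	NA	NA	3	NA	Trisomy 13	P	
P901	aneuploidy	+13	13	NA	NA	3	NA	Trisomy 13	P	
P827	aneuploidy	+21	21	NA	NA	3	NA	Trisomy 21	P	
P1008	aneuploidy	+21	21	NA	NA	3	NA	Trisomy 21	P	
P1142	aneuploidy	+21	21	NA	NA	3	NA	Trisomy 21	P	
P1506	aneuploidy	+21	21	NA	NA	3	NA	Trisomy 21	P	
P112	aneuploidy	45,X	X	NA	NA	1	NA	Turner syndrome	P	
P772	aneuploidy	45,X	X	NA	NA	1	NA	Turner syndrome	P	
P938	cnv	del(1p36.2p36.3).seq(823534-15632453)x1	1	823534	15632453	1	14808920	1p36 deletion syndrome	P	
P864	cnv	dup(2q36.3q37.3).seq(226537458-242997727)x3	2	226537458	242997727	3	16460270	2q36.3q37.3 duplication	P	HDAC4
P864	cnv	del(6q26q27).seq(161507517-170879606)x1	6	161507517	170879606	1	9372090	Terminal 6q deletions	P	
P470	cnv	del(3q12.1q21.2).seq(99540858-125130561)x1	3	99540858	125130561	1	25589704	3q13.31 deletion syndrome region	P	
P244	cnv	del(4q31.3q32.1).seq(153436540-160087839)x1	4	153436540	160087839	1	6651300		P	
P186	cnv	dup(5p14.3p15.3).seq(10429-23273021)x3	5	10429	23273021	3	23262593		P	
P186	cnv	del(18p11.3p11.3).seq(111935-4272634)x1	18	111935	4272634	1	4160700		P	
P116	cnv	del(6q25.3q27).seq(160630268-170879606)x1	6	160630268	170879606	1	10249339	Terminal 6q deletions	P	DLL1
P456	cnv	dup(7p22.1).seq(5029498-6809995)x3	7	5029498	6809995	3	1780498	7p22.1 microduplication syndrome	P	ACTB
P190	cnv	del(7q35q36.3).seq(149299056-159068966)x1	7	149299056	159068966	1	9769911	Currarino syndrome	P	MNX1
P238	cnv	del(7q33q36.3).seq(137529688-159068966)x1	7	137529688	159068966	1	21539279		P	
P422	cnv	del(7q35q36.1).seq(145049787-159068966)x1	7	145049787	159068966	1	14019180		P	
P422	cnv	dup(19q13.42q13.43).seq(55330867-59044235)x3	19	55330867	59044235	3	3713369		P	
P653	small_cnv	del(8p11.21).seq(41835654-41836946)x1	8	41835654	41836946	1	1293	KAT6A exon 6	P	KAT6A
P532	cnv	dup(9p24.1p24.3).seq(10001-6476812)x3	9	10001	6476812	3	6466812		P	
P664	cnv	del(13q22.1q34).seq(74369596-115054392)x1	13	74369596	115054392	1	40684797	13q deletion syndrome	P	ZIC2
P931	cnv	dup(13q31.2q34).seq(89863557-115054392)x3	13	89863557	115054392	3	25190836	Partial 13q trisomy	P	
P931	cnv	del(20p13).seq(60001-2226344)x1	20	60001	2226344	1	2166344	20p13 microdeletion syndrome	P	
P796	cnv	del(17p13.2p13.3).seq(1081133-4774754)x1	17	1081133	4774754	1	3693622	17p13.3 deletion syndrome	P	PAFAH1B1
P882	cnv	dup(17p13.3).seq(1150479-1592862)x3	17	1150479	1592862	3	442384	17p13.3 microduplication syndrome	P	YWHAE
P884	small_cnv	del(17q11.2).seq(29447084-29503935)x1	17	29447084	29503935	1	56852	NF1 microdeletion syndrome, NF1 exon 2-5	P	NF1
P954	small_cnv	del(17q11.2).seq(228230706-228234866)x1	2	228230706	228234866	1	4161	TM4SF20 exon 3	LP	TM4SF20
P810	cnv	del(18p11.2p11.3).seq(111935-15323954)x1	18	111935	15323954	1	15212020		P	
P1004	cnv	del(18p11.2p11.3).seq(111935-15334797)x1	18	111935	15334797	1	15222863		P	
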