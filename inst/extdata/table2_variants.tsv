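disease	gene	variant	rsid	clinvar_id	gold_stars	zygosity	consequence	classification	cases	acmg_rule	prev_study	n_relatives	compound_het_partner
FH	APOB	c.10579C>G (p.Arg3527Gly)	NA	NA	NA	het	missense	LP	1	TRUE	TRUE	0	NA
FH	APOB	c.10580G>A (p.Arg3527Gln)	rs5742904	17890	2	het	missense	P/LP	13	FALSE	TRUE	0	NA
FH	LDLR	c.11G>A (p.Trp4Ter)	rs201016593	250973	2	het	stop gained	P	1	FALSE	TRUE	0	NA
FH	LDLR	c.214del (p.Asp72ThrfsTer134)	rs879254438	251078	2	het	frameshift	P	1	FALSE	FALSE	0	NA
FH	LDLR	c.397G>A (p.Asp133Asn)	rs879254513	251202	1	het	missense	LP	1	TRUE	FALSE	0	NA
FH	LDLR	c.427T>A (p.Cys143Ser)	rs875989901	920596	2	het	missense	P	1	TRUE	TRUE	0	NA
FH	LDLR	c.463T>G (p.Cys155Gly)	rs879254535	251239	2	het	missense	P/LP	1	FALSE	FALSE	0	NA
FH	LDLR	c.504C>A (p.Asp168Glu)	rs777321035	251261	1	het	missense	P	1	TRUE	FALSE	0	NA
FH	LDLR	c.530C>T (p.Ser177Leu)	rs121908026	3686	3	het	missense	P	2	FALSE	TRUE	0	NA
FH	LDLR	c.616A>C (p.Ser206Arg)	rs2077277985	869389	1	het	missense	P	1	TRUE	FALSE	0	NA
FH	LDLR	c.625T>G (p.Cys209Gly)	rs1600711065	684864	1	het	missense	LP	1	TRUE	TRUE	0	NA
FH	LDLR	c.651TGG[1] (p.Gly219del)	rs121908027	226329	3	het	non-frameshift deletion	P	3	FALSE	FALSE	0	NA
FH	LDLR	c.666C>A (p.Cys222Ter)	rs756613387	251364	2	het	stop gained	P	1	FALSE	TRUE	0	NA
FH	LDLR	c.682G>C (p.Glu228Gln)	rs121908029	251393	2	het	missense	P/LP	2	FALSE	FALSE	0	NA
FH	LDLR	c.761A>C (p.Gln254Pro)	rs879254667	251437	2	het	missense	P/LP	1	FALSE	FALSE	0	NA
FH	LDLR	c.798T>A (p.Asp266Glu)	rs139043155	161287	3	het	missense	P	1	FALSE	TRUE	0	NA
FH	LDLR	c.888C>A (p.Cys296Ter)	rs879254708	251504	2	het	stop gained	P	1	TRUE	FALSE	0	NA
FH	LDLR	c.910G>A (p.Asp304Asn)	rs121908030	3692	3	het	missense	P	2	FALSE	TRUE	0	NA
FH	LDLR	c.986G>A (p.Cys329Tyr)	rs761954844	226344	2	het	missense	P/LP	8	FALSE	TRUE	0	NA
FH	LDLR	c.1061-2A>C	NA	NA	NA	het	splice site	LP	1	TRUE	FALSE	0	NA
FH	LDLR	c.1187-10G>A	rs765696008	226349	2	het	splice site	P/LP	1	FALSE	FALSE	0	NA
FH	LDLR	c.1202T>A (p.Leu401His)	rs121908038	3735	1	het	missense	LP	2	TRUE	FALSE	0	NA
FH	LDLR	c.1222G>A (p.Glu408Lys)	rs137943601	36453	3	het	missense	LP	2	FALSE	TRUE	0	NA
FH	LDLR	c.1222_1223insAGGTC (p.Lys411SerfsTer4)	NA	NA	NA	het	frameshift	P	1	TRUE	FALSE	0	NA
FH	LDLR	c.1277T>C (p.Leu426Pro)	rs879254851	251763	2	het	missense	P/LP	2	FALSE	FALSE	0	NA
FH	LDLR	c.1285G>A (p.Val429Met)	rs28942078	3694	3	het	missense	P	2	FALSE	TRUE	0	NA
FH	LDLR	c.1292C>T (p.Ala431Val)	NA	NA	NA	het	missense	LP	2	TRUE	TRUE	0	NA
FH	LDLR	c.1618G>A (p.Ala540Thr)	rs769370816	226363	3	het	missense	P	3	FALSE	FALSE	2	c.2416dup (p.Val806GlyfsTer11)
FH	LDLR	c.1730G>C (p.Trp577Ser)	rs138947766	252003	2	het	missense	P/LP	1	FALSE	FALSE	0	NA
FH	LDLR	c.1756T>C (p.Ser586Pro)	rs2147257524	1334395	1	het	missense	LP	1	TRUE	FALSE	0	NA
FH	LDLR	c.1775G>A (p.Gly592Glu)	rs137929307	161271	3	het	missense	P	5	FALSE	TRUE	0	NA
FH	LDLR	c.1784G>A (p.Arg595Gln)	rs201102492	183126	3	het	missense	P	1	FALSE	FALSE	0	NA
FH	LDLR	c.1846-2A>G	NA	NA	NA	het	splice site	LP	1	TRUE	FALSE	0	NA
FH	LDLR	c.1978C>T (p.Gln660Ter)	rs193922569	36458	2	het	stop gained	P	1	TRUE	TRUE	0	NA
FH	LDLR	c.1998G>A (p.Trp666Ter)	rs752935814	252161	2	het	stop gained	P	3	FALSE	TRUE	0	NA
FH	LDLR	c.2030G>A (p.Cys677Tyr)	rs875989938	252178	2	het	missense	LP	1	TRUE	FALSE	0	NA
FH	LDLR	c.2045T>C (p.Leu682Pro)	rs879255119	252189	1	hom	missense	LP	1	TRUE	FALSE	0	NA
FH	LDLR	c.2180_2184dup (p.Leu729SerfsTer3)	rs1555808044	403646	2	het	frameshift	P	1	TRUE	FALSE	0	NA
FH	LDLR	c.2416dup (p.Val806GlyfsTer11)	rs773618064	252330	3	het	frameshift	P	1	FALSE	FALSE	0	c.1618G>A (p.Ala540Thr)
Other	ABCG5	c.449_450insN[109] (p.Thr151LeufsTer83)	NA	NA	NA	het	frameshift	P	1	TRUE	FALSE	0	NA
Other	ABCG8	c.1083G>A (p.Trp361Ter)	rs137852987	4967	2	het	stop gained	P/LP	3	FALSE	FALSE	0	NA
Other	CYP27A1	c.379C>T (p.Arg127Trp)	rs201114717	65865	2	het	missense	P/LP	1	FALSE	FALSE	0	NA
Other	LIPA	c.894G>A (p.Gln298=)	rs116928232	203361	2	hom	synonymous	P/LP	2	FALSE	FALSE	0	NA
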