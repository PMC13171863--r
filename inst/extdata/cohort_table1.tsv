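family_id	gene	cdna	protein	acmg	maf	reference
ALB20	BLOC1S6	c.205 C > T	p.(Gln69*)	P (PVS1, PM2_sup, PM3)	0	This study
F-ALB7	BLOC1S6	c.205 C > T	p.(Gln69*)	P (PVS1, PM2_sup, PM3)	0	This study
ALB6	HPS1	c.118-104_129del	p.?	P (PVS1, PM2_sup, PM3)	NA	This study
ALB28	HPS4	c.1739delA	p.(Asn580Metfs*7)	P (PVS1, PM2_sup, PM3)	1.10E-05	This study
F-ALB6	HPS4	c.133-570_502-34del	deletion exon 4 - 6	P (PVS1, PM2_sup, PM3)	NA	This study
ALB18	OCA2	c.1045-15 T > G	p.?	LP (PS4, PS3_mod, PM2_sup, PP1_mod)	3.95E-04	[CR32]
ALB19	OCA2	c.1045-15 T > G	p.?	LP (PS4, PS3_mod, PM2_sup, PP1_mod)	3.95E-04	[CR32]
ALB9	OCA2	c.1045-15 T > G	p.?	LP (PS4, PS3_mod, PM2_sup, PP1_mod)	3.95E-04	[CR32]
F-ALB1	OCA2	c.1045-15 T > G	p.?	LP (PS4, PS3_mod, PM2_sup, PP1_mod)	3.95E-04	[CR32]
ALB13	OCA2	c.1456 G > T	p.(Asp486Tyr)	LP (PS4_mod, PM2_sup, PP3_str, PM3)	1.54E-04	[CR32]
F-ALB8	OCA2	c.1456 G > T	p.(Asp486Tyr)	LP (PS4_mod, PM2_sup, PP3_str, PM3)	1.54E-04	[CR32]
ALB21	OCA2	c.408_409delAA	p.(Arg137Ilefs*83)	P (PVS1, PS4_sup, PM2_sup, PM3)	NA	[CR28]
F-ALB3	SLC24A5	c.328 G > C	p.(Gly110Arg)	LP (PM2_sup, PM3, PP1, PP3_mod)	9.88E-05	[CR33]
F-ALB7	SLC24A5	c.598 G > A	p.(Gly200Arg)	VUS (PM2_sup, PM3, PS3_mod)	1.63E-05	[CR34]
F-ALB5	TYR	c.38delT	p.(Phe13Serfs*18)	P (PVS1, PM2_sup, PM3)	NA	This study
ALB14	TYR	c.264dupC	p.(Cys89Leufs*80)	P (PVS1, PM2_sup, PM3)	NA	This study
ALB30	TYR	c.649 C > T	p.(Arg217Trp)	LP (PS4_mod, PM3_str, PM2_sup)	1.32E-03	[CR35]
ALB7	TYR	c.715 C > T	p.(Arg239Trp)	P (PS4_mod, PS3_sup, PM2_sup, PM3_str, PP3_mod)	6.68E-05	[CR36]
ALB5	TYR	c.832 C > T	p.(Arg278*)	P (PVS1, PS4_mod, PM2_sup, PM3)	1.16E-03	[CR37]
F-ALB4	TYR	c.832 C > T	p.(Arg278*)	P (PVS1, PS4_mod, PM2_sup, PM3)	1.16E-03	[CR37]
ALB17	TYR	c.896 G > A	p.(Arg299His)	P (PS4, PM5, PM3_str, PM2_sup, PP3)	4.95E-04	[CR35]
ALB29	TYR	c.1037 G > A	p.(Gly346Glu)	P (PS4, PM2_sup, PM3, PM5, PP3_str)	1.21E-04	[CR38]
ALB16	TYR	c.1255 G > A	p.(Gly419Arg)	P (PS4, PM2_sup, PM3, PP3_str)	5.27E-04	[CR39]
ALB3	TYR	c.1255 G > A	p.(Gly419Arg)	P (PS4, PM2_sup, PM3, PP3_str)	5.27E-04	[CR39]
AR-ALB1	TYR	c.1255 G > A	p.(Gly419Arg)	P (PS4, PM2_sup, PM3, PP3_str)	5.27E-04	[CR39]
KC-ALB1	TYR	c.1255 G > A	p.(Gly419Arg)	P (PS4, PM2_sup, PM3, PP3_str)	5.27E-04	[CR39]
ALB12	TYR	c.1453 G > C	p.(Gly485Arg)	LP (PM5, PM3, PP3_mod, PM2_sup)	1.21E-04	This study
F-ALB2	TYR	c.(1184+1_1185-1)_(1366+1_1367-1)del	deletion exon 4	P (PVS1, PM2_sup, PM3)	NA	This study
ALB2	TYR	c.1366+4629 A > G	Inclusion of pseudoexon	LP (PS3, PM2_sup, PM3)	NA	This study
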