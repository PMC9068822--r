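id	name	compartment	carbons
glc_e	D-glucose	e	6
glc_c	D-glucose	c	6
octa_e	octanoate	e	8
octa_c	octanoate	c	8
lnlc_e	linoleate	e	18
lnlc_c	linoleate	c	18
gln_e	L-glutamine	e	5
gln_c	L-glutamine	c	5
ser_e	L-serine	e	3
ser_c	L-serine	c	3
gly_e	glycine	e	2
gly_c	glycine	c	2
met_e	L-methionine	e	5
met_c	L-methionine	c	5
co2_e	CO2	e	1
co2_c	CO2	c	1
pyr_c	pyruvate	c	3
accoa_c	acetyl-CoA (acetyl moiety)	c	2
coa_c	coenzyme A (carrier)	c	0
thf_c	tetrahydrofolate (carrier)	c	0
mlthf_c	5,10-methylene-THF (C1 unit)	c	1
mthf_c	5-methyl-THF (C1 unit)	c	1
f10thf_c	10-formyl-THF (C1 unit)	c	1
amet_c	S-adenosyl-L-methionine (Met moiety)	c	5
ahcys_c	S-adenosyl-L-homocysteine (Hcy moiety)	c	4
hcys_c	L-homocysteine	c	4
aden_c	adenosyl moiety (carrier)	c	0
sarcs_c	sarcosine	c	3
accoa_n	nuclear acetyl-CoA (acetyl moiety)	n	2
coa_n	nuclear coenzyme A (carrier)	n	0
amet_n	nuclear SAM (Met moiety)	n	5
ahcys_n	nuclear SAH (Hcy moiety)	n	4
hist_n	histone lysine pool (carrier)	n	0
histac_n	acetylated histone (acetyl mark)	n	2
histme_n	methylated histone (methyl mark)	n	1
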