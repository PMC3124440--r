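name	site
EcoRI	GAATTC
BamHI	GGATCC
HindIII	AAGCTT
TaqI	TCGA
MspI	CCGG
AluI	AGCT
HaeIII	GGCC
RsaI	GTAC
Sau3AI	GATC
DdeI	CTNAG
HinfI	GANTC
EcoRV	GATATC
PstI	CTGCAG
SalI	GTCGAC
XbaI	TCTAGA
XhoI	CTCGAG
KpnI	GGTACC
SacI	GAGCTC
SmaI	CCCGGG
ApaI	GGGCCC
NcoI	CCATGG
NdeI	CATATG
NheI	GCTAGC
SpeI	ACTAGT
SphI	GCATGC
StuI	AGGCCT
ScaI	AGTACT
DraI	TTTAAA
SspI	AATATT
AvaI	CYCGRG
BstNI	CCWGG
NlaIII	CATG
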