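set	label
A	AN1
A	anthocyanidin
A	anthocyanin
A	ascorbic acid
A	b-carotene
A	b-carotene hydroxylase
A	bHLH
A	caffeic acid
A	carotene hydroxylase
A	carotenoid
A	CCD
A	chlorogenic acid
A	CHY
A	cyanidin
A	epoxides
A	essential amino acids
A	glycosides
A	lutein
A	lutein-5,6-epoxide
A	malvidin
A	nonepoxide
A	Or
A	pelargonidin
A	peonidin
A	petunidin
A	Pf
A	phenolic
A	phenolic acid
A	phytoene synthase
A	polyphenol
A	recessiveZEP
A	TP
A	tuberigen activation complex
A	violaxanthin
A	violaxanthin-like carotenoid
A	xanthophyll
A	zeaxanthin
A	zeaxanthin epoxidase
B	anthocyanin
B	ascorbic acid
B	b-carotene
B	b-carotene hydroxylase
B	bHLH
B	caffeic acid
B	carotenoid
B	CCD
B	chlorogenic acid
B	CHY
B	Or
B	phenolic
B	TP
B	tuberigen activation complex
B	xanthophyll
B	zeaxanthin
B	zeaxanthin epoxidase
DIFF	AN1
DIFF	anthocyanidin
DIFF	carotene hydroxylase
DIFF	cyanidin
DIFF	epoxides
DIFF	essential amino acids
DIFF	glycosides
DIFF	lutein
DIFF	lutein-5,6-epoxide
DIFF	malvidin
DIFF	nonepoxide
DIFF	pelargonidin
DIFF	peonidin
DIFF	petunidin
DIFF	Pf
DIFF	phenolic acid
DIFF	phytoene synthase
DIFF	polyphenol
DIFF	recessiveZEP
DIFF	violaxanthin
DIFF	violaxanthin-like carotenoid
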