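alias	preferred_label	source
9-CIS-EPOXYCAROTENOID DIOXYGENASE	9-CIS-EPOXYCAROTENOID DIOXYGENASE	fixture
ABSCISIC ACID	ABSCISIC ACID	fixture
AMINOCYCLOPROPANE-1-CARBOXYLIC ACID	AMINOCYCLOPROPANE-1-CARBOXYLIC ACID	fixture
AN1	AN1	fixture
ANTHOCYANIDIN	ANTHOCYANIDIN	fixture
ANTHOCYANIN	ANTHOCYANIN	fixture
ASCORBIC ACID	ASCORBIC ACID	fixture
BETA-CAROTENE	BETA-CAROTENE	fixture
BETA-CAROTENE HYDROXYLASE	BETA-CAROTENE HYDROXYLASE	fixture
BHLH	BHLH	fixture
CAFFEIC ACID	CAFFEIC ACID	fixture
CAROTENE HYDROXYLASE	CAROTENE HYDROXYLASE	fixture
CAROTENOID	CAROTENOID	fixture
CCD	CCD	fixture
CHLOROGENIC ACID	CHLOROGENIC ACID	fixture
CHLOROPHYLL	CHLOROPHYLL	fixture
CHY	CHY	fixture
COLOR	COLOR	fixture
CYANIDIN	CYANIDIN	fixture
DXS	DXS	fixture
EPOXIDES	EPOXIDES	fixture
ESSENTIAL AMINO ACIDS	ESSENTIAL AMINO ACIDS	fixture
ETHYLENE	ETHYLENE	fixture
FLAVONOID	FLAVONOID	fixture
FLAVONOL	FLAVONOL	fixture
FLESH	FLESH	fixture
FLESH COLOR	FLESH COLOR	fixture
FLESH TRAIT	FLESH TRAIT	fixture
GLYCOSIDES	GLYCOSIDES	fixture
HYDROXYCINNAMIC ACID	HYDROXYCINNAMIC ACID	fixture
LUTEIN	LUTEIN	fixture
LUTEIN-5,6-EPOXIDE	LUTEIN-5,6-EPOXIDE	fixture
LYCOPENE	LYCOPENE	fixture
LYCOPENE E-CYCLASE	LYCOPENE E-CYCLASE	fixture
MALVIDIN	MALVIDIN	fixture
NONEPOXIDE	NONEPOXIDE	fixture
OR	OR	fixture
ORANGE FLESH COLOR	ORANGE FLESH COLOR	fixture
PELARGONIDIN	PELARGONIDIN	fixture
PEONIDIN	PEONIDIN	fixture
PETUNIDIN	PETUNIDIN	fixture
PF	PF	fixture
PHENOLIC	PHENOLIC	fixture
PHENOLIC ACID	PHENOLIC ACID	fixture
PHENYLALANINE AMMONIA LYASE	PHENYLALANINE AMMONIA LYASE	fixture
PHYTOENE SYNTHASE	PHYTOENE SYNTHASE	fixture
POLYPHENOL	POLYPHENOL	fixture
PSY	PSY	fixture
TP	TP	fixture
TUBER COLOR	TUBER COLOR	fixture
TUBER FLESH	TUBER FLESH	fixture
TUBER FLESH COLOR	TUBER FLESH COLOR	fixture
TUBERIGEN ACTIVATION COMPLEX	TUBERIGEN ACTIVATION COMPLEX	fixture
VIOLAXANTHIN	VIOLAXANTHIN	fixture
VIOLAXANTHIN-LIKE CAROTENOID	VIOLAXANTHIN-LIKE CAROTENOID	fixture
WHITE FLESH COLOR	WHITE FLESH COLOR	fixture
XANTHOPHYLL	XANTHOPHYLL	fixture
YELLOW-ORANGE FLESH COLOR	YELLOW-ORANGE FLESH COLOR	fixture
ZEAXANTHIN	ZEAXANTHIN	fixture
ZEAXANTHIN EPOXIDASE	ZEAXANTHIN EPOXIDASE	fixture
AN1	AN1	protein-db
ZEP	ZEAXANTHIN EPOXIDASE	protein-db
BCH	BETA-CAROTENE HYDROXYLASE	protein-db
NCED	9-CIS-EPOXYCAROTENOID DIOXYGENASE	protein-db
B-CAROTENE	BETA-CAROTENE	pathway-db
B-CAROTENE HYDROXYLASE	BETA-CAROTENE HYDROXYLASE	protein-db
CAROTENOIDS	CAROTENOID	pathway-db
RECESSIVE ZEP	ZEAXANTHIN EPOXIDASE	protein-db
RECESSIVEZEP	ZEAXANTHIN EPOXIDASE	protein-db
ABA	ABSCISIC ACID	pathway-db
ACC	AMINOCYCLOPROPANE-1-CARBOXYLIC ACID	pathway-db
PAL	PHENYLALANINE AMMONIA LYASE	protein-db
LCY-E	LYCOPENE E-CYCLASE	protein-db
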