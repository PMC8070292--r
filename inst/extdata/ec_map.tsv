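ec_number	enzyme_name
1.14.13.90	ZEAXANTHIN EPOXIDASE
1.14.13.129	BETA-CAROTENE HYDROXYLASE
1.13.11.51	9-CIS-EPOXYCAROTENOID DIOXYGENASE
1.14.11.9	FLAVONOID-3,5-HYDROXYLASE
4.3.1.24	PHENYLALANINE AMMONIA LYASE
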