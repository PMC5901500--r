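snp_id	FAM01	FAM02	FAM03	FAM04	FAM05	FAM06	FAM07	FAM08	FAM09	FAM10	CTRL01	CTRL02	CTRL03	CTRL04	CTRL05	CTRL06	CTRL07	CTRL08	CTRL09	CTRL10	CTRL11	CTRL12	CTRL13	CTRL14	CTRL15	CTRL16	CTRL17	CTRL18
rs10046	AB	AB	AB	AB	AB	AB	AA	AA	AA	AA	AB	AB	AB	AB	AB	AB	AB	AB	AB	AB	AB	AA	AA	BB	BB	BB	BB	BB
rs934634	AB	AB	AB	AB	AA	AA	AA	AA	AA	AA	AB	AB	AB	AB	AB	AB	AB	AB	AB	AA	AA	AA	AA	AA	AA	AA	BB	BB
rs9467075	AB	AB	AB	AB	AB	AA	AA	AA	AA	AA	AB	AB	AB	AB	AB	AB	AB	AB	AA	AA	AA	AA	AA	AA	AA	AA	BB	BB
rs600753	AB	AB	AB	AB	AB	AB	AB	AA	AA	AA	AB	AB	AB	AB	AB	AB	AB	AB	AB	AB	AA	AA	AA	BB	BB	BB	BB	BB
rs555879	AB	AB	AB	AB	AB	AB	AB	AA	AA	AA	AB	AB	AB	AB	AB	AB	AB	AB	AB	AB	AB	AB	AB	AB	AA	BB	BB	BB
rs2143340	AB	AB	AB	AB	AA	AA	AA	AA	AA	AA	AB	AB	AB	AB	AB	AB	AB	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	BB
rs3743205	AB	AB	BB	BB	BB	BB	BB	BB	BB	BB	AB	AB	AB	AB	AB	BB	BB	BB	BB	BB	BB	BB	BB	BB	BB	BB	BB	BB
rs2038137	AB	AA	AA	AA	AA	AA	AA	AA	AA	AA	AB	AB	AB	AB	AB	AB	AB	AB	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA
rs3178	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AB	AB	AB	AB	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA
rs17819126	AB	AB	AA	AA	AA	AA	AA	AA	AA	AA	AB	AB	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA	AA
rs3734972	AB	BB	BB	BB	BB	BB	BB	BB	BB	BB	AB	AB	AB	AB	AB	AB	BB	BB	BB	BB	BB	BB	BB	BB	BB	BB	BB	BB
rs4504469	AB	AB	AA	AA	AA	AA	AA	AA	AA	AA	AB	AB	AB	AB	AB	AB	AB	AB	AB	AA	AA	AA	AA	AA	AA	AA	AA	BB
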