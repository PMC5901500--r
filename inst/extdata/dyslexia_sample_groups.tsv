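sample_id	group
FAM01	affected_family
FAM02	affected_family
FAM03	affected_family
FAM04	affected_family
FAM05	affected_family
FAM06	affected_family
FAM07	affected_family
FAM08	affected_family
FAM09	affected_family
FAM10	affected_family
CTRL01	control
CTRL02	control
CTRL03	control
CTRL04	control
CTRL05	control
CTRL06	control
CTRL07	control
CTRL08	control
CTRL09	control
CTRL10	control
CTRL11	control
CTRL12	control
CTRL13	control
CTRL14	control
CTRL15	control
CTRL16	control
CTRL17	control
CTRL18	control
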