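Gene	Drug
GENE01	drugA
GENE02	drugA
GENE03	drugB
GENE05	drugC
GENE07	drugB
GENE08	drugD
GENE09	drugD
GENE11	drugE
GENE13	drugF
GENE15	drugG
GENE17	drugH
GENE19	drugG
GENE20	drugH
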