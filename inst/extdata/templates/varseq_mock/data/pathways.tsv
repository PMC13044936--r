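Gene	Pathway
GENE01	DNA_repair
GENE02	DNA_repair
GENE03	DNA_repair
GENE04	DNA_repair
GENE05	DNA_repair
GENE06	DNA_repair
GENE07	DNA_repair
GENE08	Signal_transduction
GENE09	Signal_transduction
GENE10	Signal_transduction
GENE11	Signal_transduction
GENE12	Signal_transduction
GENE13	Signal_transduction
GENE14	Signal_transduction
GENE15	Metabolism
GENE16	Metabolism
GENE17	Metabolism
GENE18	Metabolism
GENE19	Metabolism
GENE20	Metabolism
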