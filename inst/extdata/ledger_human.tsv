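# path: LECA > Opisthokonta > Metazoa > Vertebrata > Homo_sapiens
node	kind	family	uncertain
Metazoa	gain	Rab3	TRUE
Metazoa	gain	Rab9	TRUE
Metazoa	gain	Rab10	TRUE
Metazoa	gain	Rab15	TRUE
Metazoa	gain	Rab19	TRUE
Metazoa	gain	Rab20	TRUE
Metazoa	gain	Rab26	TRUE
Metazoa	gain	Rab27	TRUE
Metazoa	gain	Rab30	TRUE
Metazoa	gain	Rab33	TRUE
Metazoa	gain	Rab34	TRUE
Metazoa	gain	Rab35	TRUE
Metazoa	gain	Rab39	TRUE
Metazoa	gain	Rab44	TRUE
Metazoa	gain	Rab45	TRUE
Metazoa	gain	RabX4	TRUE
Metazoa	gain	RabX6	TRUE
Vertebrata	loss	RabX1	FALSE
Vertebrata	loss	Rab29	FALSE
Vertebrata	loss	RabX4	FALSE
Vertebrata	loss	RabX6	FALSE
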