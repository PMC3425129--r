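# path: LECA > SAR > Alveolata > Apicomplexa > Plasmodium_falciparum
node	kind	family	uncertain
Apicomplexa	loss	Rab22	FALSE
Apicomplexa	loss	Rab23	FALSE
Apicomplexa	loss	Rab24	FALSE
Apicomplexa	loss	Rab28	FALSE
Apicomplexa	loss	Rab29	FALSE
Apicomplexa	loss	Rab32	FALSE
Apicomplexa	loss	RabL4	FALSE
Apicomplexa	loss	RabX1	FALSE
Apicomplexa	loss	Rab7L1	FALSE
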